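# Quadratic DVH objective and the projected low-memory quasi-Newton driver
# shared by the fluence optimization and the direct aperture optimization.

#' Per-structure objective specification
#'
#' The objective is
#' `f_s = a_s sum_{i in s} max(dmin_s - D_i, 0)^2 +
#'        b_s sum_{i in s} max(D_i - dmax_s, 0)^2`
#' and `F = sum_s f_s`. Targets use both terms; normal tissue only the
#' maximum term (`a = 0`).
#'
#' @param terms named list; each element a list with fields `a`, `b`
#'   (importance weights, >= 0), `dmin`, `dmax` (Gy; use `-Inf`/`Inf` or
#'   `a = 0`/`b = 0` to disable a term). Names must match structure names.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(terms) {
  for (nm in names(terms)) {
    t <- terms[[nm]]
    t$a <- if (is.null(t$a)) 0 else t$a
    t$b <- if (is.null(t$b)) 0 else t$b
    t$dmin <- if (is.null(t$dmin)) -Inf else t$dmin
    t$dmax <- if (is.null(t$dmax)) Inf else t$dmax
    stopifnot(t$a >= 0, t$b >= 0)
    if (t$a > 0 && t$b > 0 && t$dmin > t$dmax)
      stop("structure ", nm, ": dmin > dmax with both terms active")
    terms[[nm]] <- t
  }
  structure(list(terms = terms), class = "objective_spec")
}

#' Default phantom objective
#'
#' PTV min and max terms at the prescription (max at 105%) with unit
#' importance; body maximum term at the prescription with importance 0.1.
#'
#' @param prescription prescription dose, Gy.
#' @return an [objective_spec()].
#' @export
phantom_objective <- function(prescription) {
  objective_spec(list(
    ptv = list(a = 1, b = 1, dmin = prescription, dmax = 1.05 * prescription),
    body = list(b = 0.1, dmax = prescription)
  ))
}

#' Quadratic DVH objective value and dose gradient
#'
#' @param dose voxel dose vector (Gy).
#' @param structures named list of [roi_structure()].
#' @param spec an [objective_spec()]; every named term must have a matching
#'   structure.
#' @param gradient if `TRUE`, also return dF/dD_i.
#' @return list with `F` (total), `per_structure` (named numeric) and, when
#'   requested, `grad` (length = voxels).
#' @export
dose_objective <- function(dose, structures, spec, gradient = FALSE) {
  total <- 0
  per <- numeric(0)
  g <- if (gradient) numeric(length(dose)) else NULL
  for (nm in names(spec$terms)) {
    tm <- spec$terms[[nm]]
    s <- structures[[nm]]
    if (is.null(s)) stop("objective references unknown structure: ", nm)
    if (!length(s$idx)) stop("structure has an empty mask: ", nm)
    d <- dose[s$idx]
    f <- 0
    if (tm$a > 0 && is.finite(tm$dmin)) {
      under <- pmax(tm$dmin - d, 0)
      f <- f + tm$a * sum(under^2)
      if (gradient) g[s$idx] <- g[s$idx] - 2 * tm$a * under
    }
    if (tm$b > 0 && is.finite(tm$dmax)) {
      over <- pmax(d - tm$dmax, 0)
      f <- f + tm$b * sum(over^2)
      if (gradient) g[s$idx] <- g[s$idx] + 2 * tm$b * over
    }
    per[nm] <- f
    total <- total + f
  }
  out <- list(F = total, per_structure = per)
  if (gradient) out$grad <- g
  out
}

#' Projected low-memory BFGS minimizer
#'
#' Generic driver: L-BFGS two-loop direction, projection onto the feasible
#' set after each trial step, and a backtracking (Armijo) line search that
#' guarantees a non-increasing objective; a failed line search accepts a zero
#' step and continues. Curvature pairs with non-positive curvature after
#' projection are discarded.
#'
#' @param x0 start point (already feasible).
#' @param fn objective function of x.
#' @param gr gradient function of x.
#' @param project projection onto the feasible set (default: none).
#' @param n_iter number of iterations.
#' @param memory number of stored curvature pairs.
#' @param armijo_c sufficient-decrease constant.
#' @param max_backtracks line-search halvings before accepting a zero step.
#' @param callback optional `function(iter, x, F)` called after each accepted
#'   iterate.
#' @return list with `x`, `trace` (objective per iteration, starting with the
#'   initial value), and `n_zero_steps`.
#' @export
plbfgs <- function(x0, fn, gr, project = identity, n_iter = 40, memory = 8,
                   armijo_c = 1e-4, max_backtracks = 30, callback = NULL) {
  x <- project(x0)
  f <- fn(x)
  trace <- numeric(n_iter + 1)
  trace[1] <- f
  S <- list(); Y <- list(); rho <- numeric(0)
  g <- gr(x)
  n_zero <- 0L
  for (it in seq_len(n_iter)) {
    # two-loop recursion
    q <- g
    m <- length(S)
    if (m > 0) {
      al <- numeric(m)
      for (i in m:1) {
        al[i] <- rho[i] * sum(S[[i]] * q)
        q <- q - al[i] * Y[[i]]
      }
      gam <- sum(S[[m]] * Y[[m]]) / sum(Y[[m]] * Y[[m]])
      q <- gam * q
      for (i in 1:m) {
        be <- rho[i] * sum(Y[[i]] * q)
        q <- q + (al[i] - be) * S[[i]]
      }
      p <- q
      alpha <- 1
    } else {
      gn <- sqrt(sum(g * g))
      p <- g
      alpha <- if (gn > 0) 1 / gn else 0
    }
    # backtracking on the projected step
    accepted <- FALSE
    x_new <- x; f_new <- f
    if (alpha > 0) {
      for (bt in seq_len(max_backtracks)) {
        cand <- project(x - alpha * p)
        fc <- fn(cand)
        if (fc <= f - armijo_c * sum(g * (x - cand)) + 1e-12 && fc <= f) {
          x_new <- cand; f_new <- fc; accepted <- TRUE
          break
        }
        alpha <- alpha / 2
      }
    }
    if (!accepted) n_zero <- n_zero + 1L
    g_new <- if (accepted) gr(x_new) else g
    if (accepted) {
      s <- x_new - x
      y <- g_new - g
      sy <- sum(s * y)
      if (sy > 1e-12 * sqrt(sum(s * s)) * sqrt(sum(y * y))) {
        S <- c(S, list(s)); Y <- c(Y, list(y)); rho <- c(rho, 1 / sy)
        if (length(S) > memory) {
          S <- S[-1]; Y <- Y[-1]; rho <- rho[-1]
        }
      }
    }
    x <- x_new; f <- f_new; g <- g_new
    trace[it + 1] <- f
    if (!is.null(callback)) callback(it, x, f)
  }
  list(x = x, trace = trace, n_zero_steps = n_zero)
}

#' Fluence-map optimization
#'
#' Minimizes the quadratic DVH objective over non-negative beamlet weights by
#' projected L-BFGS (40 iterations by default).
#'
#' @param influence list of per-node influence matrices (voxels x beamlets).
#' @param structures named list of [roi_structure()].
#' @param spec an [objective_spec()].
#' @param n_iter iterations (>= 1).
#' @param w0 optional list of initial weight vectors; default: uniform
#'   weights on beamlets whose dose column is non-empty, scaled so the mean
#'   dose over the first objective structure with a min-dose term matches its
#'   `dmin` (or unit weights if none).
#' @param memory L-BFGS history length.
#' @return list with `weights` (list of per-node vectors), `dose`, `trace`,
#'   and `state` (the raw optimizer return).
#' @export
optimize_fluence <- function(influence, structures, spec, n_iter = 40,
                             w0 = NULL, memory = 8) {
  stopifnot(n_iter >= 1)
  nb <- vapply(influence, ncol, integer(1))
  off <- c(0L, cumsum(nb))
  Dall <- do.call(cbind, influence)
  split_w <- function(x) lapply(seq_along(nb),
                                function(k) x[(off[k] + 1):off[k + 1]])
  if (is.null(w0)) {
    active <- Matrix::colSums(Dall) > 0
    x0 <- as.numeric(active)
    target <- NULL
    for (nm in names(spec$terms)) {
      tm <- spec$terms[[nm]]
      if (tm$a > 0 && is.finite(tm$dmin)) { target <- c(nm, tm$dmin); break }
    }
    if (!is.null(target)) {
      d1 <- as.numeric(Dall %*% x0)
      m <- mean(d1[structures[[target[1]]]$idx])
      if (m > 0) x0 <- x0 * as.numeric(target[2]) / m
    }
  } else {
    x0 <- unlist(w0)
  }
  fn <- function(w) dose_objective(as.numeric(Dall %*% w), structures, spec)$F
  gr <- function(w) {
    gd <- dose_objective(as.numeric(Dall %*% w), structures, spec,
                         gradient = TRUE)$grad
    as.numeric(Matrix::crossprod(Dall, gd))
  }
  st <- plbfgs(x0, fn, gr, project = function(x) pmax(x, 0),
               n_iter = n_iter, memory = memory)
  list(weights = split_w(st$x),
       dose = as.numeric(Dall %*% st$x),
       trace = st$trace, state = st)
}
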