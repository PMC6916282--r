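# Effective-fluence model of MLC motion between control points, and the
# direct aperture optimizer that uses it.
#
# During one node-node interval each leaf moves at constant speed from its
# initial to its final position while the beam delivers the open-field
# fluence Phi. A point x is exposed while it lies between the left and right
# leaf tips; its effective fluence is Phi times the fraction of the interval
# for which that holds. For leaves moving in the opening direction this is
# the ramp form
#   phi(x) = Phi * clip[ (x - L_init)/(L_fin - L_init)
#                        - (x - R_init)/(R_fin - R_init) ]
# (each ramp clipped to [0,1]); the implementation uses the equivalent
# exposure-interval intersection, which also covers leaves moving in either
# direction and the stationary (step-function) limit.

# exposure time-interval of the left leaf: {t in [0,1]: L(t) <= x}
#' @keywords internal
.left_interval <- function(a, b, x) {
  if (abs(b - a) < 1e-12) {
    lo <- ifelse(x >= a - 1e-12, 0, 1)   # empty interval encoded lo=1,hi=0
    hi <- ifelse(x >= a - 1e-12, 1, 0)
  } else {
    t <- pmin(pmax((x - a) / (b - a), 0), 1)
    if (b > a) { lo <- 0 * t; hi <- t } else { lo <- t; hi <- rep(1, length(t)) }
  }
  list(lo = lo, hi = hi)
}

# exposure time-interval of the right leaf: {t in [0,1]: R(t) >= x}
#' @keywords internal
.right_interval <- function(cc, d, x) {
  if (abs(d - cc) < 1e-12) {
    lo <- ifelse(x <= cc + 1e-12, 0, 1)
    hi <- ifelse(x <= cc + 1e-12, 1, 0)
  } else {
    t <- pmin(pmax((x - cc) / (d - cc), 0), 1)
    if (d > cc) { lo <- t; hi <- rep(1, length(t)) } else { lo <- 0 * t; hi <- t }
  }
  list(lo = lo, hi = hi)
}

#' Effective fluence of a moving leaf pair at a point
#'
#' Fraction of a constant-speed leaf transition for which the point `x` is
#' exposed, times the open-field fluence `Phi`. Stationary leaves reduce to
#' the static step function; the result always satisfies `0 <= phi <= Phi`.
#'
#' @param l_init,l_fin left-leaf tip at interval start/end (mm).
#' @param r_init,r_fin right-leaf tip at interval start/end (mm).
#' @param Phi open-field fluence weight of the interval (>= 0).
#' @param x position(s) along leaf travel, mm (vectorized).
#' @return effective fluence phi at each `x`.
#' @export
effective_fluence <- function(l_init, l_fin, r_init, r_fin, Phi, x) {
  stopifnot(Phi >= 0)
  L <- .left_interval(l_init, l_fin, x)
  R <- .right_interval(r_init, r_fin, x)
  Phi * pmax(pmin(L$hi, R$hi) - pmax(L$lo, R$lo), 0)
}

# Bixel-averaged effective fluence for one row. phi(x) is piecewise linear
# with kinks at the four leaf endpoints, at the crossing of the two leaf-time
# lines, and where the pre-clip exposure length changes sign; integration by
# the midpoint rule on segments refined at all of these is exact.
#' @keywords internal
.row_interval_avg <- function(a, b, cc, d, Phi, edges) {
  nb <- length(edges) - 1L
  if (Phi <= 0) return(numeric(nb))
  bps <- c(a, b, cc, d)
  den <- (b - a) - (d - cc)
  if (abs(b - a) > 1e-12 && abs(d - cc) > 1e-12 && abs(den) > 1e-12)
    bps <- c(bps, (a * (d - cc) - cc * (b - a)) / -den)
  lo <- edges[1]; hi <- edges[nb + 1]
  bps <- bps[bps > lo + 1e-12 & bps < hi - 1e-12]
  pts <- sort(unique(c(edges, bps)))
  # refine at zero crossings of the pre-clip exposure length
  raw <- function(x) {
    L <- .left_interval(a, b, x); R <- .right_interval(cc, d, x)
    pmin(L$hi, R$hi) - pmax(L$lo, R$lo)
  }
  rv <- raw(pts)
  cross <- which(rv[-length(rv)] * rv[-1] < 0)
  if (length(cross)) {
    x0 <- pts[cross]; x1 <- pts[cross + 1]
    r0 <- rv[cross]; r1 <- rv[cross + 1]
    pts <- sort(unique(c(pts, x0 - r0 * (x1 - x0) / (r1 - r0))))
  }
  mids <- (pts[-length(pts)] + pts[-1]) / 2
  lens <- diff(pts)
  phi <- Phi * pmax(raw(mids), 0)
  bix <- findInterval(mids, edges, rightmost.closed = TRUE)
  out <- numeric(nb)
  acc <- tapply(phi * lens, bix, sum)
  out[as.integer(names(acc))] <- acc / diff(edges)[as.integer(names(acc))]
  out
}

#' Effective fluence map of one node-node interval
#'
#' Per-bixel (bixel-averaged) effective fluence delivered while the MLC moves
#' from `prev` to `nxt` with open-field fluence proportional to the interval
#' MU. With `prev == nxt` this equals the static partial-bixel aperture
#' fluence. The map is attributed to the terminal node's beam orientation.
#'
#' @param prev,nxt apertures at the interval start and end (same row count).
#' @param mu monitor units delivered over the interval (Phi = MU).
#' @param bgrid the [bixel_grid()].
#' @return numeric matrix (rows x columns) of effective fluence.
#' @export
interval_fluence_map <- function(prev, nxt, mu, bgrid) {
  if (length(prev$left) != length(nxt$left))
    stop("leaf-pair count mismatch between apertures")
  stopifnot(length(prev$left) == bgrid$n_rows)
  edges <- c(bgrid$xc - bgrid$w / 2, bgrid$xc[bgrid$n_cols] + bgrid$w / 2)
  out <- matrix(0, bgrid$n_rows, bgrid$n_cols)
  if (mu <= 0) return(out)
  for (r in seq_len(bgrid$n_rows)) {
    out[r, ] <- .row_interval_avg(prev$left[r], nxt$left[r],
                                  prev$right[r], nxt$right[r], mu, edges)
  }
  out
}

#' Static partial-bixel aperture fluence
#'
#' Each bixel receives the open-field fluence times the fraction of the
#' bixel (along leaf travel) exposed by the aperture: a leaf tip halfway
#' across a bixel gives half of the open-field fluence.
#'
#' @param ap an [aperture()] at fluence-row resolution.
#' @param mu monitor units (Phi = MU); defaults to the aperture's own MU.
#' @param bgrid the [bixel_grid()].
#' @return numeric matrix (rows x columns).
#' @export
static_aperture_fluence <- function(ap, mu = ap$mu, bgrid) {
  stopifnot(length(ap$left) == bgrid$n_rows)
  out <- matrix(0, bgrid$n_rows, bgrid$n_cols)
  if (mu <= 0) return(out)
  xl <- bgrid$xc - bgrid$w / 2; xr <- bgrid$xc + bgrid$w / 2
  for (r in seq_len(bgrid$n_rows)) {
    if (ap$right[r] - ap$left[r] <= 1e-12) next
    out[r, ] <- mu *
      pmax(pmin(ap$right[r], xr) - pmax(ap$left[r], xl), 0) / bgrid$w
  }
  out
}

# --- direct aperture optimization ------------------------------------------

# decode/encode the DAO variable vector for a dynamic-arc plan
#' @keywords internal
.dao_decode <- function(x, n_nodes, n_rows) {
  nl <- n_nodes * n_rows
  list(L = matrix(x[1:nl], n_rows, n_nodes),
       R = matrix(x[nl + (1:nl)], n_rows, n_nodes),
       mu = x[2 * nl + (1:n_nodes)])
}

#' @keywords internal
.dao_apertures <- function(dec) {
  lapply(seq_len(ncol(dec$L)), function(n)
    aperture(pmin(dec$L[, n], dec$R[, n]), pmax(dec$L[, n], dec$R[, n]),
             max(dec$mu[n], 0)))
}

# per-node effective (or static) fluence vectors for a dense arc plan
#' @keywords internal
.dao_phi <- function(aps, bgrid, motion_model) {
  n <- length(aps)
  phi <- vector("list", n)
  phi[[1]] <- as.numeric(static_aperture_fluence(aps[[1]], aps[[1]]$mu, bgrid))
  if (n >= 2) {
    for (k in 2:n) {
      phi[[k]] <- if (motion_model == "effective") {
        as.numeric(interval_fluence_map(aps[[k - 1]], aps[[k]],
                                        aps[[k]]$mu, bgrid))
      } else {
        as.numeric(static_aperture_fluence(aps[[k]], aps[[k]]$mu, bgrid))
      }
    }
  }
  phi
}

#' Direct aperture optimization
#'
#' Optimizes leaf positions and segment MU of a sequenced plan with the same
#' projected L-BFGS driver as the fluence stage. Dose is evaluated through
#' the static partial-bixel fluence (`motion_model = "discrete"`, and always
#' for static plans) or through the effective fluence of the moving aperture
#' between control points (`"effective"`); machine constraints are applied
#' (projected) at every iteration, including the per-interval leaf travel
#' limit in arc mode. The final plan is renormalized so that the PTV D95
#' equals the prescription.
#'
#' @param plan a sequenced [plan_new()] (dense over the trajectory for
#'   dynamic mode).
#' @param influence list of per-node influence matrices matching
#'   `plan$geometries`.
#' @param structures named list of [roi_structure()].
#' @param objective an [objective_spec()].
#' @param motion_model `"effective"` or `"discrete"` (ignored for static
#'   plans, which are always discrete).
#' @param n_iter iterations; 0 returns the renormalized input plan.
#' @param constraints a [delivery_constraints()].
#' @param mlc an [mlc_spec()].
#' @param bgrid the [bixel_grid()].
#' @param renormalize if `TRUE` (default) rescale MU so PTV D95 equals the
#'   prescription. The structure named `ptv` is used.
#' @param fd_step finite-difference step (mm) for the leaf-position chain
#'   rule at the fluence level.
#' @param callback optional `function(iter, apertures, F)` called on every
#'   accepted iterate (after projection).
#' @return list with `plan` (optimized), `dose` (its model dose after
#'   renormalization), `trace`, `state`.
#' @export
optimize_apertures <- function(plan, influence, structures, objective,
                               motion_model = c("effective", "discrete"),
                               n_iter = 40,
                               constraints = delivery_constraints(),
                               mlc = mlc_spec(), bgrid,
                               renormalize = TRUE, fd_step = 0.05,
                               callback = NULL) {
  motion_model <- match.arg(motion_model)
  if (plan$mode != "dynamic_arc")
    return(.optimize_segments(plan, influence, structures, objective, n_iter,
                              constraints, mlc, bgrid, renormalize, fd_step,
                              callback))
  n_nodes <- length(plan$apertures)
  n_rows <- bgrid$n_rows
  Dall <- do.call(cbind, influence)
  nb <- bgrid$n
  row_idx <- lapply(seq_len(n_rows), function(r)
    seq.int(r, by = n_rows, length.out = bgrid$n_cols))
  edges <- c(bgrid$xc - bgrid$w / 2, bgrid$xc[bgrid$n_cols] + bgrid$w / 2)

  encode <- function(aps) {
    c(unlist(lapply(aps, `[[`, "left")),
      unlist(lapply(aps, `[[`, "right")),
      vapply(aps, `[[`, numeric(1), "mu"))
  }
  project <- function(x) {
    dec <- .dao_decode(x, n_nodes, n_rows)
    aps <- .dao_apertures(dec)
    prev <- NULL
    for (nn in seq_len(n_nodes)) {
      aps[[nn]] <- apply_mlc_constraints(aps[[nn]], prev, constraints, mlc,
                                         mode = "arc")
      prev <- aps[[nn]]
    }
    encode(aps)
  }
  phi_of <- function(x) {
    dec <- .dao_decode(x, n_nodes, n_rows)
    .dao_phi(.dao_apertures(dec), bgrid, motion_model)
  }
  fn <- function(x) {
    dose <- as.numeric(Dall %*% unlist(phi_of(x)))
    dose_objective(dose, structures, objective)$F
  }
  xl_e <- bgrid$xc - bgrid$w / 2; xr_e <- bgrid$xc + bgrid$w / 2
  row_phi_static <- function(ap, mu, r) {
    if (ap$right[r] - ap$left[r] <= 1e-12 || mu <= 0)
      return(numeric(bgrid$n_cols))
    mu * pmax(pmin(ap$right[r], xr_e) - pmax(ap$left[r], xl_e), 0) / bgrid$w
  }
  # one row of the fluence attributed to node k, given the interval apertures
  row_phi <- function(k, apA, apB, r) {
    if (motion_model != "effective" || k == 1) {
      row_phi_static(apB, apB$mu, r)
    } else {
      .row_interval_avg(apA$left[r], apB$left[r], apA$right[r], apB$right[r],
                        apB$mu, edges)
    }
  }
  gr <- function(x) {
    dec <- .dao_decode(x, n_nodes, n_rows)
    aps <- .dao_apertures(dec)
    phi <- .dao_phi(aps, bgrid, motion_model)
    dose <- as.numeric(Dall %*% unlist(phi))
    gdose <- dose_objective(dose, structures, objective,
                            gradient = TRUE)$grad
    gphi_all <- as.numeric(Matrix::crossprod(Dall, gdose))
    gphi <- lapply(seq_len(n_nodes), function(k)
      gphi_all[(k - 1) * nb + seq_len(nb)])
    gL <- matrix(0, n_rows, n_nodes); gR <- gL; gmu <- numeric(n_nodes)
    # intervals touching node nn (as start or end aperture)
    ivals_of <- function(nn) {
      if (motion_model != "effective") return(list(list(k = nn, role = "end")))
      iv <- list()
      if (nn == 1) iv <- c(iv, list(list(k = 1, role = "end")))
      if (nn >= 2) iv <- c(iv, list(list(k = nn, role = "end")))
      if (nn < n_nodes) iv <- c(iv, list(list(k = nn + 1, role = "start")))
      iv
    }
    for (nn in seq_len(n_nodes)) {
      # MU gradient: phi of the node's own interval is linear in mu
      mu_n <- aps[[nn]]$mu
      unit <- if (mu_n > 1e-9) {
        phi[[nn]] / mu_n
      } else {
        tmp <- aps[[nn]]; tmp$mu <- 1
        if (motion_model == "effective" && nn >= 2)
          as.numeric(interval_fluence_map(aps[[nn - 1]], tmp, 1, bgrid))
        else as.numeric(static_aperture_fluence(tmp, 1, bgrid))
      }
      gmu[nn] <- sum(gphi[[nn]] * unit)
      for (iv in ivals_of(nn)) {
        k <- iv$k
        apA <- if (k >= 2) aps[[k - 1]] else NULL
        apB <- aps[[k]]
        if (apB$mu <= 0) next
        for (r in seq_len(n_rows)) {
          gp <- gphi[[k]][row_idx[[r]]]
          if (all(gp == 0)) next
          for (side in c("left", "right")) {
            ap_hi <- apA; bp_hi <- apB
            ap_lo <- apA; bp_lo <- apB
            if (iv$role == "start") {
              ap_hi[[side]][r] <- ap_hi[[side]][r] + fd_step
              ap_lo[[side]][r] <- ap_lo[[side]][r] - fd_step
            } else {
              bp_hi[[side]][r] <- bp_hi[[side]][r] + fd_step
              bp_lo[[side]][r] <- bp_lo[[side]][r] - fd_step
            }
            dphi <- (row_phi(k, ap_hi, bp_hi, r) -
                       row_phi(k, ap_lo, bp_lo, r)) / (2 * fd_step)
            gval <- sum(gp * dphi)
            if (side == "left") gL[r, nn] <- gL[r, nn] + gval
            else gR[r, nn] <- gR[r, nn] + gval
          }
        }
      }
    }
    c(as.numeric(gL), as.numeric(gR), gmu)
  }
  cb <- if (is.null(callback)) NULL else function(it, x, f) {
    callback(it, .dao_apertures(.dao_decode(x, n_nodes, n_rows)), f)
  }
  if (n_iter > 0) {
    x0 <- project(encode(plan$apertures))
    st <- plbfgs(x0, fn, gr, project = project, n_iter = n_iter,
                 callback = cb)
  } else {
    x0 <- encode(plan$apertures)   # n_iter = 0: renormalize only
    st <- list(x = x0, trace = fn(x0), n_zero_steps = 0L)
  }
  aps <- .dao_apertures(.dao_decode(st$x, n_nodes, n_rows))
  plan$apertures <- aps
  dose <- as.numeric(Dall %*% unlist(.dao_phi(aps, bgrid, motion_model)))
  if (renormalize) {
    d95 <- dose_at_volume(dose[structures$ptv$idx], 0.95)
    if (d95 > 0) {
      sc <- plan$prescription / d95
      plan <- plan_scale_mu(plan, sc)
      dose <- dose * sc
    }
  }
  list(plan = plan, dose = dose, trace = st$trace, state = st)
}

# Step-and-shoot DAO: same driver, variables are all segments' leaves + MU,
# static fluence only, no inter-segment travel limit.
#' @keywords internal
.optimize_segments <- function(plan, influence, structures, objective, n_iter,
                               constraints, mlc, bgrid, renormalize, fd_step,
                               callback) {
  n_rows <- bgrid$n_rows
  segs <- plan$segments
  node_of <- unlist(lapply(seq_along(segs), function(k)
    rep(k, length(segs[[k]]))))
  flat <- unlist(segs, recursive = FALSE)
  ns <- length(flat)
  if (ns == 0) stop("static plan has no segments")
  Dall <- do.call(cbind, influence[node_of])
  nb <- bgrid$n
  encode <- function(aps) c(unlist(lapply(aps, `[[`, "left")),
                            unlist(lapply(aps, `[[`, "right")),
                            vapply(aps, `[[`, numeric(1), "mu"))
  decode <- function(x) .dao_apertures(.dao_decode(x, ns, n_rows))
  project <- function(x) {
    aps <- decode(x)
    aps <- lapply(aps, apply_mlc_constraints, previous = NULL,
                  constraints = constraints, spec = mlc, mode = "static")
    encode(aps)
  }
  phi_of <- function(aps) unlist(lapply(aps, function(a)
    as.numeric(static_aperture_fluence(a, a$mu, bgrid))))
  fn <- function(x) {
    dose <- as.numeric(Dall %*% phi_of(decode(x)))
    dose_objective(dose, structures, objective)$F
  }
  row_idx <- lapply(seq_len(n_rows), function(r)
    seq.int(r, by = n_rows, length.out = bgrid$n_cols))
  xl <- bgrid$xc - bgrid$w / 2; xr <- bgrid$xc + bgrid$w / 2
  gr <- function(x) {
    aps <- decode(x)
    dose <- as.numeric(Dall %*% phi_of(aps))
    gdose <- dose_objective(dose, structures, objective, gradient = TRUE)$grad
    gphi_all <- as.numeric(Matrix::crossprod(Dall, gdose))
    gL <- matrix(0, n_rows, ns); gR <- gL; gmu <- numeric(ns)
    for (k in seq_len(ns)) {
      gphi <- gphi_all[(k - 1) * nb + seq_len(nb)]
      a <- aps[[k]]
      unitphi <- as.numeric(static_aperture_fluence(a, 1, bgrid))
      gmu[k] <- sum(gphi * unitphi)
      if (a$mu <= 0) next
      for (r in seq_len(n_rows)) {
        gp <- gphi[row_idx[[r]]]
        if (all(gp == 0) || a$right[r] - a$left[r] <= 1e-12) next
        # analytic: d(exposed fraction)/dL = -1/w inside the tip's bixel
        inL <- pmax(pmin(xr, a$right[r]) - pmax(xl, a$left[r]), 0) > 0
        dL <- -(a$left[r] >= xl & a$left[r] < xr) / bgrid$w
        dR <- (a$right[r] > xl & a$right[r] <= xr) / bgrid$w
        gL[r, k] <- a$mu * sum(gp * dL * inL)
        gR[r, k] <- a$mu * sum(gp * dR * inL)
      }
    }
    c(as.numeric(gL), as.numeric(gR), gmu)
  }
  x0 <- project(encode(flat))
  cb <- if (is.null(callback)) NULL else function(it, x, f)
    callback(it, decode(x), f)
  st <- if (n_iter > 0) {
    plbfgs(x0, fn, gr, project = project, n_iter = n_iter, callback = cb)
  } else list(x = x0, trace = fn(x0), n_zero_steps = 0L)
  aps <- decode(st$x)
  plan$segments <- lapply(seq_along(segs), function(k)
    unname(aps[node_of == k]))
  dose <- as.numeric(Dall %*% phi_of(aps))
  if (renormalize) {
    d95 <- dose_at_volume(dose[structures$ptv$idx], 0.95)
    if (d95 > 0) {
      sc <- plan$prescription / d95
      plan <- plan_scale_mu(plan, sc)
      dose <- dose * sc
    }
  }
  list(plan = plan, dose = dose, trace = st$trace, state = st)
}
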