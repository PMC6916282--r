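# Leaf sequencing: reducing-level (Xia-Verhey) decomposition of fluence maps
# into deliverable apertures, the arc-specific three-aperture redistribution,
# and the globally capped step-and-shoot allocation.

# One reducing-level step: delivery level is the largest max0/2^k that does
# not exceed the residual maximum; the open region per row is the longest
# (leftmost on ties) run of columns with residual >= level.
#' @keywords internal
.xv_step <- function(resid, max0) {
  mr <- max(resid)
  k <- max(0, ceiling(log2(max0 / mr) - 1e-12))
  level <- max0 / 2^k
  if (level > mr * (1 + 1e-12)) level <- level / 2
  n_rows <- nrow(resid)
  runs <- matrix(NA_integer_, n_rows, 2)
  opened <- matrix(FALSE, n_rows, ncol(resid))
  for (r in seq_len(n_rows)) {
    above <- resid[r, ] >= level - 1e-12 * max0
    if (!any(above)) next
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    cand <- which(rl$values)
    best <- cand[which.max(rl$lengths[cand])]   # longest run, leftmost tie
    runs[r, ] <- c(starts[best], ends[best])
    opened[r, starts[best]:ends[best]] <- TRUE
  }
  list(level = level, runs = runs, opened = opened)
}

# Convert row runs (bixel column indices) into an aperture in mm
#' @keywords internal
.runs_to_aperture <- function(runs, bgrid, mu) {
  open <- !is.na(runs[, 1])
  park <- if (any(open))
    mean((bgrid$xc[runs[open, 1]] + bgrid$xc[runs[open, 2]]) / 2) else 0
  l <- rep(park, nrow(runs)); r <- rep(park, nrow(runs))
  l[open] <- bgrid$xc[runs[open, 1]] - bgrid$w / 2
  r[open] <- bgrid$xc[runs[open, 2]] + bgrid$w / 2
  aperture(l, r, mu)
}

#' Xia-Verhey reducing-level sequencing
#'
#' Decomposes a non-negative fluence map into at most `max_segments` MLC
#' apertures. At each step the delivery level is the largest power-of-2
#' fraction of the initial maximum not exceeding the residual maximum; the
#' open region is rectified to one interval per leaf row (longest
#' above-level run, leftmost on ties) and the level is subtracted there.
#'
#' @param fmap numeric matrix (fluence rows x columns), >= 0, laid out as the
#'   [bixel_grid()].
#' @param max_segments maximum number of segments (>= 1).
#' @param bgrid the [bixel_grid()] giving the column geometry.
#' @return list of segments, each `list(aperture, weight)`; empty for an
#'   all-zero map. Aperture MU equals the segment weight.
#' @export
xia_verhey <- function(fmap, max_segments, bgrid) {
  stopifnot(max_segments >= 1, all(fmap >= 0),
            nrow(fmap) == bgrid$n_rows, ncol(fmap) == bgrid$n_cols)
  max0 <- max(fmap)
  if (max0 <= 0) return(list())
  resid <- fmap
  segs <- list()
  while (length(segs) < max_segments && max(resid) > 1e-9 * max0) {
    st <- .xv_step(resid, max0)
    if (all(is.na(st$runs[, 1]))) break
    resid[st$opened] <- pmax(resid[st$opened] - st$level, 0)
    segs[[length(segs) + 1L]] <-
      list(aperture = .runs_to_aperture(st$runs, bgrid, st$level),
           weight = st$level)
  }
  segs
}

#' Reconstruct a fluence map from segments
#'
#' Sums segment weights over the bixels each aperture exposes (exposure by
#' fractional bixel coverage), for checking sequencing fidelity.
#'
#' @param segments as returned by [xia_verhey()].
#' @param bgrid the [bixel_grid()].
#' @return numeric matrix (rows x columns).
#' @export
reconstruct_fluence <- function(segments, bgrid) {
  out <- matrix(0, bgrid$n_rows, bgrid$n_cols)
  for (sg in segments) {
    ap <- sg$aperture
    for (r in seq_len(bgrid$n_rows)) {
      if (ap$right[r] - ap$left[r] <= 1e-9) next
      xl <- bgrid$xc - bgrid$w / 2; xr <- bgrid$xc + bgrid$w / 2
      frac <- pmax(pmin(ap$right[r], xr) - pmax(ap$left[r], xl), 0) / bgrid$w
      out[r, ] <- out[r, ] + sg$weight * frac
    }
  }
  out
}

# summed leaf travel between consecutive apertures
#' @keywords internal
.ap_travel <- function(a, b) sum(abs(a$left - b$left) + abs(a$right - b$right))

#' Arc sequencing with three-aperture redistribution
#'
#' Fluence maps exist at every third trajectory node (15 degree spacing).
#' Each map is sequenced into (up to) three apertures; the middle-weight
#' aperture stays at the fluence node and the remaining two are assigned to
#' the -5 and +5 degree neighbours, in the order that minimizes summed leaf
#' travel across the three consecutive nodes. Nodes receiving no aperture get
#' a closed aperture with 0 MU. Total MU is conserved.
#'
#' @param fmaps list of fluence matrices, one per fluence node.
#' @param fluence_idx integer node indices of the fluence nodes (each must
#'   have both neighbours inside the trajectory).
#' @param n_nodes total number of trajectory nodes.
#' @param bgrid the [bixel_grid()].
#' @param constraints a [delivery_constraints()]; static shape rules are
#'   applied to every emitted aperture.
#' @param spec an [mlc_spec()].
#' @return list of `n_nodes` apertures (one per node, MU set).
#' @export
arc_distribute <- function(fmaps, fluence_idx, n_nodes, bgrid,
                           constraints = delivery_constraints(),
                           spec = mlc_spec()) {
  stopifnot(length(fmaps) == length(fluence_idx),
            all(fluence_idx > 1), all(fluence_idx < n_nodes))
  out <- vector("list", n_nodes)
  for (k in seq_along(fmaps)) {
    f <- fluence_idx[k]
    segs <- xia_verhey(fmaps[[k]], 3L, bgrid)
    segs <- lapply(segs, function(sg) {
      sg$aperture <- apply_mlc_constraints(sg$aperture, NULL, constraints,
                                           spec, mode = "static")
      sg
    })
    n_rows <- bgrid$n_rows
    if (length(segs) == 0) next
    ord <- order(vapply(segs, function(sg) sg$weight, numeric(1)))
    if (length(segs) == 1) {
      out[[f]] <- segs[[1]]$aperture
    } else if (length(segs) == 2) {
      # heavier stays at the fluence node, lighter to the nearer neighbour
      mid <- segs[[ord[2]]]$aperture; other <- segs[[ord[1]]]$aperture
      out[[f]] <- mid
      out[[f - 1]] <- other
    } else {
      mid <- segs[[ord[2]]]$aperture
      a1 <- segs[[ord[1]]]$aperture; a3 <- segs[[ord[3]]]$aperture
      c_a <- .ap_travel(a1, mid) + .ap_travel(mid, a3)
      c_b <- .ap_travel(a3, mid) + .ap_travel(mid, a1)
      out[[f]] <- mid
      if (c_a <= c_b) {
        out[[f - 1]] <- a1; out[[f + 1]] <- a3
      } else {
        out[[f - 1]] <- a3; out[[f + 1]] <- a1
      }
    }
  }
  # fill unassigned nodes with closed 0-MU apertures parked near the nearest
  # assigned aperture
  assigned <- which(!vapply(out, is.null, logical(1)))
  if (!length(assigned)) stop("no apertures produced (all fluence maps zero)")
  for (i in seq_len(n_nodes)) {
    if (is.null(out[[i]])) {
      j <- assigned[which.min(abs(assigned - i))]
      park <- (out[[j]]$left + out[[j]]$right) / 2
      out[[i]] <- closed_aperture(bgrid$n_rows, park = park, mu = 0)
    }
  }
  out
}

#' Step-and-shoot sequencing under a global aperture budget
#'
#' Greedy allocation: repeatedly gives the next reducing-level segment to the
#' node whose step removes the most residual fluence (level x opened area),
#' until the budget is exhausted or all maps are fully sequenced. A node may
#' receive zero, one, or several segments.
#'
#' @param fmaps list of fluence matrices, one per node.
#' @param max_total global aperture budget (>= 1).
#' @param bgrid the [bixel_grid()].
#' @param constraints,spec machine model; static shape rules applied to every
#'   emitted aperture.
#' @return list (length = nodes) of lists of apertures (possibly empty), MU
#'   set to segment weights.
#' @export
static_distribute <- function(fmaps, max_total = 110L, bgrid,
                              constraints = delivery_constraints(),
                              spec = mlc_spec()) {
  if (max_total < 1) stop("max_total must be >= 1")
  n <- length(fmaps)
  resid <- lapply(fmaps, function(f) f)
  max0 <- vapply(fmaps, max, numeric(1))
  nxt <- vector("list", n)
  gain <- rep(-Inf, n)
  refresh <- function(k) {
    if (max0[k] <= 0 || max(resid[[k]]) <= 1e-9 * max0[k]) {
      nxt[k] <<- list(NULL); gain[k] <<- -Inf
    } else {
      st <- .xv_step(resid[[k]], max0[k])
      nxt[[k]] <<- st
      gain[k] <<- st$level * sum(st$opened)
    }
  }
  for (k in seq_len(n)) refresh(k)
  out <- replicate(n, list(), simplify = FALSE)
  used <- 0L
  while (used < max_total && any(is.finite(gain))) {
    k <- which.max(gain)
    st <- nxt[[k]]
    resid[[k]][st$opened] <- pmax(resid[[k]][st$opened] - st$level, 0)
    ap <- apply_mlc_constraints(.runs_to_aperture(st$runs, bgrid, st$level),
                                NULL, constraints, spec, mode = "static")
    out[[k]] <- c(out[[k]], list(ap))
    used <- used + 1L
    refresh(k)
  }
  out
}
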