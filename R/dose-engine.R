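# Simplified divergent pencil-beam dose engine. Each beamlet (bixel) column
# d_ij is inverse-square x depth dose (build-up + exponential attenuation) x
# a lateral profile formed by Gaussian-blurred bixel edges, evaluated in
# back-projected beam's-eye-view coordinates at the nominal plane. Columns
# are truncated at a fraction of their own maximum and stored sparsely.

#' Bixel (fluence) grid at the nominal plane
#'
#' Rows are aligned to the paired MLC leaves (height = two leaf widths,
#' 7.7 mm by default); columns run along leaf travel. The grid is centred on
#' the beam axis.
#'
#' @param spec an [mlc_spec()].
#' @param half_width half-extent of the column range in mm; columns cover
#'   `[-half_width, half_width]`.
#' @param bixel_width column width along leaf travel, mm.
#' @param n_rows number of fluence rows (default: all paired rows).
#' @return object of class `bixel_grid` with column centres `xc`, row centres
#'   `yc`, sizes `w`/`h`, and the beamlet enumeration order (row-fastest).
#' @export
bixel_grid <- function(spec = mlc_spec(), half_width = 40, bixel_width = 5,
                       n_rows = NULL) {
  h <- spec$paired_leaf_width
  if (is.null(n_rows)) n_rows <- spec$n_rows
  stopifnot(n_rows >= 1, n_rows <= spec$n_rows, half_width > 0,
            bixel_width > 0)
  yc <- (seq_len(n_rows) - (n_rows + 1) / 2) * h
  n_cols <- max(1L, as.integer(floor(2 * half_width / bixel_width)))
  xc <- (seq_len(n_cols) - (n_cols + 1) / 2) * bixel_width
  if (max(abs(xc)) + bixel_width / 2 > spec$travel_range + 1e-9)
    stop("bixel grid exceeds the MLC travel range")
  structure(list(xc = xc, yc = yc, w = bixel_width, h = h,
                 n_rows = n_rows, n_cols = n_cols, n = n_rows * n_cols),
            class = "bixel_grid")
}

# beamlet j  <->  (row, col): row varies fastest
#' @keywords internal
bixel_index <- function(bgrid, row, col) (col - 1L) * bgrid$n_rows + row

#' Dose-kernel parameters
#'
#' Depth dose `D(d) = (1 - exp(-beta d)) exp(-mu d)` (6 MV-like build-up and
#' attenuation), lateral penumbra sigma in mm at the nominal plane, and the
#' MU calibration: `calibration` Gy per MU at the build-up maximum of a broad
#' open field at the nominal plane.
#'
#' @param mu attenuation coefficient, 1/mm.
#' @param beta build-up coefficient, 1/mm.
#' @param sigma penumbra sigma at the nominal plane, mm.
#' @param calibration Gy per MU at the reference point.
#' @param truncation column truncation fraction: entries below
#'   `truncation * max(column)` are dropped (default 1.5e-4, i.e. 0.015%).
#' @param ref_dist source distance of the calibration point, mm; the
#'   inverse-square factor is `(ref_dist / r)^2` so dose falls off from the
#'   source independently of the plan's nominal SAD.
#' @return object of class `beam_kernel`.
#' @export
beam_kernel <- function(mu = 0.005, beta = 0.14, sigma = 2.5,
                        calibration = 0.01, truncation = 1.5e-4,
                        ref_dist = 800) {
  stopifnot(mu > 0, beta > 0, sigma > 0, calibration > 0,
            truncation >= 0, truncation < 1, ref_dist > 0)
  dmax <- log((beta + mu) / mu) / beta    # build-up maximum depth
  peak <- (1 - exp(-beta * dmax)) * exp(-mu * dmax)
  structure(list(mu = mu, beta = beta, sigma = sigma,
                 calibration = calibration, truncation = truncation,
                 ref_dist = ref_dist, dmax = dmax,
                 norm = calibration / peak),
            class = "beam_kernel")
}

# Shared per-orientation voxel quantities: BEV coordinates back-projected to
# the nominal plane, radiological depth, inverse-square factor.
#' @keywords internal
.beam_projection <- function(geom, phantom, kernel) {
  P <- phantom$centers
  if (is.null(P)) P <- voxel_centers(phantom$grid)
  S <- geom$source
  dx <- P[, 1] - S[1]; dy <- P[, 2] - S[2]; dz <- P[, 3] - S[3]
  rlen <- sqrt(dx * dx + dy * dy + dz * dz)
  t_axis <- dx * geom$direction[1] + dy * geom$direction[2] +
    dz * geom$direction[3]
  sc <- geom$sad / t_axis
  xb <- (dx * geom$u[1] + dy * geom$u[2] + dz * geom$u[3]) * sc
  yb <- (dx * geom$v[1] + dy * geom$v[2] + dz * geom$v[3]) * sc
  # slab-method entry distance of each voxel ray into the phantom box
  lo <- phantom$grid$origin
  hi <- lo + phantom$grid$dims * phantom$grid$spacing
  t_entry <- rep(-Inf, length(rlen))
  e <- list(dx, dy, dz)
  for (a in 1:3) {
    ea <- e[[a]] / rlen
    ea[abs(ea) < 1e-12] <- 1e-12
    t1 <- (lo[a] - S[a]) / ea
    t2 <- (hi[a] - S[a]) / ea
    t_entry <- pmax(t_entry, pmin(t1, t2))
  }
  depth <- pmax(rlen - t_entry, 0)
  list(xb = xb, yb = yb,
       ddose = (1 - exp(-kernel$beta * depth)) * exp(-kernel$mu * depth),
       invsq = (kernel$ref_dist / rlen)^2)
}

#' Dose-influence matrix of one beam orientation
#'
#' Computes the sparse matrix of beamlet dose columns d_ij (voxels x bixels,
#' Gy per MU of beamlet weight) for one control-point orientation. Every
#' column is truncated at `kernel$truncation` of its own maximum.
#'
#' @param geom a [cp_geometry()].
#' @param bgrid a [bixel_grid()].
#' @param phantom list with `grid` (and optionally cached `centers`), as from
#'   [make_water_phantom()].
#' @param kernel a [beam_kernel()].
#' @param bixels optional integer subset of beamlet indices to compute.
#' @return a `dgCMatrix` (n voxels x `bgrid$n`); columns not in `bixels` are
#'   empty.
#' @export
beam_influence <- function(geom, bgrid, phantom, kernel = beam_kernel(),
                           bixels = NULL) {
  pr <- .beam_projection(geom, phantom, kernel)
  nvox <- length(pr$xb)
  sig <- kernel$sigma
  reach <- 4 * sig
  base <- kernel$norm * pr$invsq * pr$ddose
  if (is.null(bixels)) bixels <- seq_len(bgrid$n)
  rows_wanted <- sort(unique((bixels - 1L) %% bgrid$n_rows + 1L))
  ii <- vector("list", length(bixels)); jj <- ii; vv <- ii; k <- 0L
  for (r in rows_wanted) {
    ylo <- bgrid$yc[r] - bgrid$h / 2; yhi <- bgrid$yc[r] + bgrid$h / 2
    rs <- which(pr$yb >= ylo - reach & pr$yb <= yhi + reach)
    if (!length(rs)) next
    fy <- pnorm((pr$yb[rs] - ylo) / sig) - pnorm((pr$yb[rs] - yhi) / sig)
    xb_r <- pr$xb[rs]; base_r <- base[rs]
    cols <- sort(unique((bixels[(bixels - 1L) %% bgrid$n_rows + 1L == r] - 1L) %/%
                          bgrid$n_rows + 1L))
    for (cc in cols) {
      xlo <- bgrid$xc[cc] - bgrid$w / 2; xhi <- bgrid$xc[cc] + bgrid$w / 2
      cs <- which(xb_r >= xlo - reach & xb_r <= xhi + reach)
      if (!length(cs)) next
      fx <- pnorm((xb_r[cs] - xlo) / sig) - pnorm((xb_r[cs] - xhi) / sig)
      val <- base_r[cs] * fx * fy[cs]
      keep <- val >= kernel$truncation * max(val) & val > 0
      if (!any(keep)) next
      k <- k + 1L
      ii[[k]] <- rs[cs[keep]]
      jj[[k]] <- rep.int(bixel_index(bgrid, r, cc), sum(keep))
      vv[[k]] <- val[keep]
    }
  }
  if (k == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nvox, bgrid$n)))
  Matrix::sparseMatrix(i = unlist(ii[seq_len(k)]), j = unlist(jj[seq_len(k)]),
                       x = unlist(vv[seq_len(k)]), dims = c(nvox, bgrid$n))
}

#' Single beamlet dose column
#'
#' @inheritParams beam_influence
#' @param j beamlet index in the [bixel_grid()] enumeration.
#' @return sparse one-column matrix of d_ij (Gy per MU).
#' @export
compute_beamlet_column <- function(geom, j, bgrid, phantom,
                                   kernel = beam_kernel()) {
  stopifnot(j >= 1, j <= bgrid$n)
  beam_influence(geom, bgrid, phantom, kernel, bixels = as.integer(j))[, j,
                                                                       drop = FALSE]
}

#' Assemble dose-influence matrices for a set of nodes
#'
#' @param geoms list of [cp_geometry()] (e.g. `trajectory$control_points`).
#' @inheritParams beam_influence
#' @return list of `dgCMatrix`, one per node, with attribute `bytes` giving
#'   the approximate memory footprint.
#' @export
assemble_influence <- function(geoms, bgrid, phantom, kernel = beam_kernel()) {
  if (!length(geoms)) stop("no nodes supplied")
  if (bgrid$n < 1) stop("empty bixel grid")
  if (is.null(phantom$centers)) phantom$centers <- voxel_centers(phantom$grid)
  infl <- lapply(geoms, beam_influence, bgrid = bgrid, phantom = phantom,
                 kernel = kernel)
  attr(infl, "bytes") <- sum(vapply(infl, function(m) length(m@x) * 12,
                                    numeric(1)))
  infl
}

#' Accumulate dose from beamlet weights
#'
#' Computes `D_i = sum_j d_ij w_j` over all supplied beams.
#'
#' @param influence list of per-node influence matrices.
#' @param weights list (or matrix with one column per node) of non-negative
#'   beamlet weight vectors aligned with the influence beamlet enumeration.
#' @return numeric vector of voxel doses (Gy).
#' @export
accumulate_dose <- function(influence, weights) {
  if (is.matrix(weights)) weights <- asplit(weights, 2)
  if (length(influence) != length(weights))
    stop("influence/weights length mismatch")
  dose <- numeric(nrow(influence[[1]]))
  for (k in seq_along(influence)) {
    w <- as.numeric(weights[[k]])
    if (length(w) != ncol(influence[[k]]))
      stop("weight vector ", k, " does not match the beamlet enumeration")
    if (any(w != 0)) dose <- dose + as.numeric(influence[[k]] %*% w)
  }
  dose
}
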