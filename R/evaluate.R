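# Post-optimization recalculation with interpolated nodes and apertures,
# DVH and conformity-index computation, clinical-goal checks, and delivery
# time estimation.

#' Interpolate a dynamic-arc plan for recalculation
#'
#' Each node-node interval is replaced by `n_nodes` interpolated orientations
#' (geodesic interpolation of the beam frames, the last one being the
#' original terminal node) and `n_apertures` interpolated aperture shapes
#' between consecutive interpolated nodes, coalesced onto the following
#' interpolated node. Leaf positions interpolate linearly (constant-speed
#' motion); the interval MU is divided equally among the
#' `n_nodes * n_apertures` interpolated apertures. The first original node
#' delivers copies of its own shape at its own orientation.
#'
#' @param plan a dynamic-arc [plan_new()] with at least 2 control points.
#' @param n_nodes interpolated orientations per interval (default 5).
#' @param n_apertures interpolated shapes per interpolated-node step
#'   (default 20).
#' @return object of class `interp_plan`: list of expanded control points,
#'   each `list(geometry, apertures)` where every aperture carries its share
#'   of MU.
#' @export
interpolate_plan <- function(plan, n_nodes = 5L, n_apertures = 20L) {
  stopifnot(plan$mode == "dynamic_arc", length(plan$geometries) >= 2,
            n_nodes >= 1, n_apertures >= 1)
  out <- list()
  lerp_ap <- function(a, b, s, mu) {
    l <- a$left + s * (b$left - a$left)
    r <- a$right + s * (b$right - a$right)
    # guard against rounding of the convex combination at closed rows
    aperture(pmin(l, r), pmax(l, r), mu)
  }
  # first node: its own MU with its own static shape
  out[[1]] <- list(geometry = plan$geometries[[1]],
                   apertures = list(plan$apertures[[1]]))
  idx <- 1L
  n_cp <- length(plan$geometries)
  for (i in 2:n_cp) {
    gA <- plan$geometries[[i - 1]]; gB <- plan$geometries[[i]]
    apA <- plan$apertures[[i - 1]]; apB <- plan$apertures[[i]]
    mu_each <- apB$mu / (n_nodes * n_apertures)
    for (k in seq_len(n_nodes)) {
      idx <- idx + 1L
      gk <- slerp_geometry(gA, gB, k / n_nodes, index = idx)
      aps <- lapply(seq_len(n_apertures), function(j) {
        # midpoint sampling of the continuous leaf motion over this step
        s <- ((k - 1) * n_apertures + j - 0.5) / (n_nodes * n_apertures)
        lerp_ap(apA, apB, s, mu_each)
      })
      out[[idx]] <- list(geometry = gk, apertures = aps)
    }
  }
  structure(list(nodes = out, prescription = plan$prescription,
                 scheme = plan$scheme,
                 n_nodes = n_nodes, n_apertures = n_apertures),
            class = "interp_plan")
}

#' Total MU of an interpolated plan
#' @param iplan an `interp_plan`.
#' @export
interp_plan_total_mu <- function(iplan) {
  sum(vapply(iplan$nodes, function(nd)
    sum(vapply(nd$apertures, `[[`, numeric(1), "mu")), numeric(1)))
}

#' Evaluate the dose of a plan
#'
#' Computes the voxel dose of a plan under one of the dose-calculation
#' models:
#' * `"discrete"`: static partial-bixel aperture fluence at each control
#'   point (no motion modeling);
#' * `"effective"`: effective fluence of the moving aperture over each
#'   interval, attributed to the terminal node's orientation (first node
#'   static);
#' * an `interp_plan` is evaluated by summing the static fluence of its
#'   interpolated apertures at each interpolated orientation.
#'
#' Influence matrices for orientations not supplied in `influence` are
#' computed on the fly.
#'
#' @param plan a `plan` or an `interp_plan`.
#' @param phantom phantom list (`grid`, `structures`).
#' @param bgrid the [bixel_grid()].
#' @param kernel a [beam_kernel()].
#' @param model `"discrete"` or `"effective"` (ignored for `interp_plan`).
#' @param influence optional list of precomputed influence matrices aligned
#'   with the plan's control points (plain `plan` only).
#' @return numeric voxel-dose vector (Gy).
#' @export
evaluate_plan_dose <- function(plan, phantom, bgrid, kernel = beam_kernel(),
                               model = c("discrete", "effective"),
                               influence = NULL) {
  if (is.null(phantom$centers)) phantom$centers <- voxel_centers(phantom$grid)
  nvox <- prod(phantom$grid$dims)
  dose <- numeric(nvox)
  if (inherits(plan, "interp_plan")) {
    for (nd in plan$nodes) {
      fl <- matrix(0, bgrid$n_rows, bgrid$n_cols)
      for (ap in nd$apertures)
        fl <- fl + static_aperture_fluence(ap, ap$mu, bgrid)
      if (all(fl == 0)) next
      Dm <- beam_influence(nd$geometry, bgrid, phantom, kernel)
      dose <- dose + as.numeric(Dm %*% as.numeric(fl))
    }
    return(dose)
  }
  model <- match.arg(model)
  if (plan$mode == "dynamic_arc") {
    phi <- .dao_phi(plan$apertures, bgrid,
                    if (model == "effective") "effective" else "discrete")
    for (k in seq_along(phi)) {
      if (all(phi[[k]] == 0)) next
      Dm <- if (!is.null(influence)) influence[[k]] else
        beam_influence(plan$geometries[[k]], bgrid, phantom, kernel)
      dose <- dose + as.numeric(Dm %*% phi[[k]])
    }
  } else {
    for (k in seq_along(plan$segments)) {
      segs <- plan$segments[[k]]
      if (!length(segs)) next
      fl <- matrix(0, bgrid$n_rows, bgrid$n_cols)
      for (ap in segs) fl <- fl + static_aperture_fluence(ap, ap$mu, bgrid)
      if (all(fl == 0)) next
      Dm <- if (!is.null(influence)) influence[[k]] else
        beam_influence(plan$geometries[[k]], bgrid, phantom, kernel)
      dose <- dose + as.numeric(Dm %*% as.numeric(fl))
    }
  }
  dose
}

#' Cumulative dose-volume histogram
#'
#' @param dose voxel dose vector (full grid).
#' @param structure a [roi_structure()].
#' @param bin_width histogram bin width in Gy (default 0.05).
#' @return object of class `dvh_curve`: `dose` (bin edges, starting at 0) and
#'   `volume` (fraction of the structure receiving at least that dose).
#' @export
dvh <- function(dose, structure, bin_width = 0.05) {
  if (!length(structure$idx)) stop("empty structure: ", structure$name)
  d <- dose[structure$idx]
  edges <- seq(0, max(d) + 2 * bin_width, by = bin_width)
  vol <- vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(list(name = structure$name, dose = edges, volume = vol,
                 bin_width = bin_width), class = "dvh_curve")
}

#' Dose at a volume fraction (direct percentile)
#'
#' `dose_at_volume(d, 0.95)` is the D95: the dose received by at least 95%
#' of the voxels.
#'
#' @param d dose values of the structure's voxels.
#' @param v volume fraction in (0, 1].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(d, v) {
  stopifnot(v > 0, v <= 1)
  as.numeric(stats::quantile(d, probs = 1 - v, type = 7))
}

#' DVH point metrics from a curve
#'
#' Supported metrics: `"D95"`-style `D<x>` (dose at x% volume, linear
#' interpolation on the curve), `"V<x>"` (volume fraction at x Gy),
#' `"Dmax"`, `"Dmean"` is not stored on the curve and unsupported.
#'
#' @param curve a `dvh_curve`.
#' @param metric metric string.
#' @return numeric value (Gy for D-metrics, fraction for V-metrics).
#' @export
dvh_metric <- function(curve, metric) {
  if (metric == "Dmax") return(max(curve$dose[curve$volume > 0]))
  if (grepl("^D[0-9.]+$", metric)) {
    v <- as.numeric(sub("^D", "", metric)) / 100
    vol <- curve$volume; dd <- curve$dose
    # dose at which the cumulative volume crosses v (curve non-increasing)
    if (v >= vol[1]) return(dd[1])
    i <- max(which(vol >= v))
    if (i == length(vol) || vol[i] == v) return(dd[i])
    dd[i] + (vol[i] - v) / (vol[i] - vol[i + 1]) * (dd[i + 1] - dd[i])
  } else if (grepl("^V[0-9.]+$", metric)) {
    x <- as.numeric(sub("^V", "", metric))
    stats::approx(curve$dose, curve$volume, xout = x, yleft = 1,
                  yright = 0)$y
  } else {
    stop("unknown DVH metric: ", metric)
  }
}

#' Conformity index
#'
#' `CI = (PTV_pres / PTV) * (PTV_pres / V_pres)`: the product of PTV
#' coverage and prescription-volume selectivity; at the SBRT planning level
#' of 95% PTV coverage the maximum attainable value is 0.95.
#'
#' @param dose full-grid voxel dose vector.
#' @param ptv the PTV [roi_structure()].
#' @param grid the [voxel_grid()] (for voxel volumes).
#' @param prescription prescription dose, Gy.
#' @return object of class `conformity_result` with volumes in cm^3 and `ci`.
#' @export
conformity_index <- function(dose, ptv, grid, prescription) {
  stopifnot(prescription > 0)
  vv <- prod(grid$spacing) / 1000
  ptv_pres <- sum(dose[ptv$idx] >= prescription) * vv
  v_pres <- sum(dose >= prescription) * vv
  ptv_vol <- length(ptv$idx) * vv
  ci <- if (v_pres <= 0) 0 else (ptv_pres / ptv_vol) * (ptv_pres / v_pres)
  structure(list(ptv_pres_cc = ptv_pres, ptv_cc = ptv_vol,
                 v_pres_cc = v_pres, ci = ci), class = "conformity_result")
}

#' Time-model parameters
#'
#' @param dose_rate MU/min.
#' @param t_interval dynamic per-interval robot traversal time T_R, s.
#' @param t_mlc static per-segment MLC positioning time, s.
#' @param t_robot static per-node robot move time (no dose), s.
#' @export
time_model_params <- function(dose_rate = 1000, t_interval = 1.5,
                              t_mlc = 3.5, t_robot = 1.5) {
  stopifnot(dose_rate > 0, t_interval > 0, t_mlc > 0, t_robot > 0)
  structure(list(dose_rate = dose_rate, t_interval = t_interval,
                 t_mlc = t_mlc, t_robot = t_robot),
            class = "time_model_params")
}

#' Delivery-time estimate for dynamic-arc plans
#'
#' Each interval takes `t = max(60 M / D, T_R)` seconds, where `M` is the MU
#' delivered at the interval's terminal node and `D` the dose rate in
#' MU/min; the first node is charged the same way.
#'
#' @param plan a dynamic-arc `plan`.
#' @param params a [time_model_params()].
#' @return list with `total` (s) and `per_interval` (one entry per node).
#' @export
estimate_time_dynamic <- function(plan, params = time_model_params()) {
  stopifnot(plan$mode == "dynamic_arc")
  mu <- vapply(plan$apertures, `[[`, numeric(1), "mu")
  per <- pmax(60 * mu / params$dose_rate, params$t_interval)
  list(total = sum(per), per_interval = per)
}

#' Delivery-time estimate for step-and-shoot plans
#'
#' Each segment costs the MLC positioning time plus its beam-on time; a
#' visited node with no monitor units costs the robot move time only.
#'
#' @param plan a static `plan`.
#' @param params a [time_model_params()].
#' @return list with `total` (s) and `per_node`.
#' @export
estimate_time_static <- function(plan, params = time_model_params()) {
  stopifnot(plan$mode == "static")
  per <- vapply(plan$segments, function(segs) {
    mu <- if (length(segs)) vapply(segs, `[[`, numeric(1), "mu") else numeric(0)
    live <- mu > 0
    if (!any(live)) return(params$t_robot)
    sum(params$t_mlc + 60 * mu[live] / params$dose_rate)
  }, numeric(1))
  list(total = sum(per), per_node = per)
}

#' Check clinical goals against DVH curves
#'
#' @param dvhs named list of `dvh_curve` (by structure name).
#' @param goals data.frame with columns `structure`, `metric` (e.g. `D95`,
#'   `V20`, `Dmax`), `bound` (Gy or volume fraction) and `type`
#'   (`"min"`: value must be >= bound; `"max"`: value must be <= bound).
#' @return data.frame with the achieved `value`, signed `margin` (positive =
#'   goal met by that amount) and `pass`; goals on missing structures get
#'   `pass = NA` and an error note.
#' @export
check_goals <- function(dvhs, goals) {
  if (nrow(goals) == 0)
    return(data.frame(structure = character(0), metric = character(0),
                      bound = numeric(0), type = character(0),
                      value = numeric(0), margin = numeric(0),
                      pass = logical(0), note = character(0)))
  out <- goals
  out$value <- NA_real_; out$margin <- NA_real_; out$pass <- NA
  out$note <- ""
  for (i in seq_len(nrow(goals))) {
    cv <- dvhs[[goals$structure[i]]]
    if (is.null(cv)) {
      out$note[i] <- "structure not found"
      next
    }
    val <- dvh_metric(cv, goals$metric[i])
    out$value[i] <- val
    m <- if (goals$type[i] == "min") val - goals$bound[i]
    else goals$bound[i] - val
    out$margin[i] <- m
    out$pass[i] <- m >= -1e-9
  }
  out
}
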