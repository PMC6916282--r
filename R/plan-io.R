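# Serialization: versioned JSON plan schema, plain-JSON volume format,
# YAML/JSON machine configuration, and the end-to-end pipeline driver.

PLAN_SCHEMA_VERSION <- "1.0"
SCHEME_TAGS <- c("CKA1", "CKA2", "CKA3", "CKA4", "CKA5", "CKSB")

#' @keywords internal
.geom_to_list <- function(g) {
  list(index = g$index, direction = g$direction, u = g$u, v = g$v,
       sad = g$sad)
}

#' @keywords internal
.geom_from_list <- function(l) {
  cp_geometry(l$direction, l$u, l$v, sad = l$sad, index = l$index)
}

#' @keywords internal
.ap_to_list <- function(a) list(left = a$left, right = a$right, mu = a$mu)

#' Write a plan to JSON
#'
#' The schema stores apertures at fluence-row resolution (leaves are paired),
#' all positions in mm at the nominal plane, and provenance metadata.
#'
#' @param plan a [plan_new()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    schema_version = PLAN_SCHEMA_VERSION,
    mode = plan$mode,
    scheme = plan$scheme,
    prescription = plan$prescription,
    meta = plan$meta,
    trajectory = lapply(plan$geometries, .geom_to_list)
  )
  if (plan$mode == "dynamic_arc") {
    obj$control_points <- lapply(seq_along(plan$apertures), function(i)
      c(list(node = i), .ap_to_list(plan$apertures[[i]])))
  } else {
    obj$segments <- lapply(seq_along(plan$segments), function(i)
      list(node = i, apertures = lapply(plan$segments[[i]], .ap_to_list)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @keywords internal
.ap_from_list <- function(l, where) {
  if (is.null(l$mu) || l$mu < 0)
    stop("invalid plan: ", where, ".mu must be >= 0")
  if (any(l$left > l$right + 1e-9))
    stop("invalid plan: ", where, " has left > right")
  aperture(l$left, l$right, l$mu)
}

#' Read a plan from JSON
#'
#' Validates the schema and reports the offending field on failure.
#'
#' @param path JSON file written by [write_plan()].
#' @return a `plan`.
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(obj$mode) || !obj$mode %in% c("dynamic_arc", "static"))
    stop("invalid plan: mode must be dynamic_arc or static")
  if (is.null(obj$scheme) || !obj$scheme %in% SCHEME_TAGS)
    stop("invalid plan: scheme must be one of ", paste(SCHEME_TAGS,
                                                       collapse = ", "))
  if (is.null(obj$prescription) || obj$prescription <= 0)
    stop("invalid plan: prescription must be positive")
  geoms <- lapply(obj$trajectory, .geom_from_list)
  if (obj$mode == "dynamic_arc") {
    aps <- lapply(seq_along(obj$control_points), function(i)
      .ap_from_list(obj$control_points[[i]],
                    sprintf("control_points[%d]", i)))
    plan_new("dynamic_arc", geoms, apertures = aps,
             prescription = obj$prescription, scheme = obj$scheme,
             meta = obj$meta)
  } else {
    segs <- lapply(seq_along(obj$segments), function(i)
      lapply(seq_along(obj$segments[[i]]$apertures), function(j)
        .ap_from_list(obj$segments[[i]]$apertures[[j]],
                      sprintf("segments[%d].apertures[%d]", i, j))))
    plan_new("static", geoms, segments = segs,
             prescription = obj$prescription, scheme = obj$scheme,
             meta = obj$meta)
  }
}

#' Write / read a voxel volume as plain JSON
#'
#' Substitute for a binary medical-image format: origin (mm), spacing (mm),
#' dims, and the flattened (column-major) value vector.
#'
#' @param grid a [voxel_grid()].
#' @param path file path.
#' @return `path` invisibly (write); a `voxel_grid` (read).
#' @export
write_volume <- function(grid, path) {
  jsonlite::write_json(list(origin = grid$origin, spacing = grid$spacing,
                            dims = grid$dims,
                            values = as.numeric(grid$values)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  voxel_grid(o$origin, o$spacing, o$dims,
             array(o$values, o$dims))
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' @param path config file; `.yaml`/`.yml` parsed with yaml, otherwise JSON.
#' @return named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @keywords internal
.cfg <- function(cfg, name, default) {
  v <- cfg[[name]]
  if (is.null(v)) default else v
}

#' Run the full planning pipeline from a configuration
#'
#' Executes fluence optimization, sequencing, direct aperture optimization
#' and (scheme-dependent) interpolated recalculation and evaluation, writing
#' all artifacts to `out_dir`: `plan.json`, `dose.json` (volume),
#' `dvh.csv`, `report.json` and `log.txt`. Fully deterministic given the
#' configuration and seed.
#'
#' Scheme semantics: CKA1-CKA3 optimize with discrete control-point dose
#' (recalculating with 5 interpolated nodes for CKA2, plus 20 interpolated
#' apertures for CKA3); CKA4/CKA5 optimize with the effective-fluence motion
#' model (CKA5 recalculates at 5 nodes x 20 apertures); CKSB is step-and-
#' shoot on the body path under a global segment budget.
#'
#' @param config path to a YAML/JSON config, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the plan, final dose, report and paths.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  lg <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                          append = TRUE)
  cat("", file = logf)
  seed <- .cfg(cfg, "seed", 1L)
  set.seed(seed)
  cfg_hash <- digest::digest(cfg)
  scheme <- .cfg(cfg, "scheme", "CKA4")
  if (!scheme %in% SCHEME_TAGS) stop("unknown scheme: ", scheme)
  lg("pipeline start: scheme=%s seed=%d config=%s", scheme, seed, cfg_hash)

  stage <- function(name, expr) {
    lg("stage %s", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ph_cfg <- .cfg(cfg, "phantom", list())
  phantom <- stage("phantom", make_water_phantom(
    width = .cfg(ph_cfg, "width", 300), length = .cfg(ph_cfg, "length", 300),
    height = .cfg(ph_cfg, "height", 200),
    spacing = .cfg(ph_cfg, "spacing", 2.5),
    ptv_diameter = .cfg(ph_cfg, "ptv_diameter", 60)))
  phantom$centers <- voxel_centers(phantom$grid)

  mlc <- mlc_spec()
  constraints <- delivery_constraints()
  kernel <- beam_kernel()
  bx_cfg <- .cfg(cfg, "bixel", list())
  bgrid <- bixel_grid(mlc, half_width = .cfg(bx_cfg, "half_width", 40),
                      bixel_width = .cfg(bx_cfg, "bixel_width", 5))
  prescription <- .cfg(cfg, "prescription", 40)
  objective <- phantom_objective(prescription)
  it_cfg <- .cfg(cfg, "iterations", list())
  n_fl <- .cfg(it_cfg, "fluence", 40)
  n_dao <- .cfg(it_cfg, "dao", 40)
  tr_cfg <- .cfg(cfg, "trajectory", list())

  if (scheme == "CKSB") {
    traj <- stage("trajectory",
                  build_body_path(.cfg(tr_cfg, "n_nodes", 110)))
    geoms <- traj$control_points
    infl <- stage("influence",
                  assemble_influence(geoms, bgrid, phantom, kernel))
    fl <- stage("fluence_optimization",
                optimize_fluence(infl, phantom$structures, objective,
                                 n_iter = n_fl))
    fmaps <- lapply(fl$weights, matrix, nrow = bgrid$n_rows)
    segs <- stage("sequencing",
                  static_distribute(fmaps, .cfg(cfg, "max_segments", 110),
                                    bgrid, constraints, mlc))
    plan <- plan_new("static", geoms, segments = segs,
                     prescription = prescription, scheme = scheme,
                     meta = list(seed = seed, config_hash = cfg_hash))
    dao <- stage("aperture_optimization",
                 optimize_apertures(plan, infl, phantom$structures,
                                    objective, n_iter = n_dao,
                                    constraints = constraints, mlc = mlc,
                                    bgrid = bgrid))
    plan <- dao$plan
    final_dose <- dao$dose
    tm <- estimate_time_static(plan)
  } else {
    traj <- stage("trajectory", build_arc_trajectory(
      n_arcs = .cfg(tr_cfg, "n_arcs", 8),
      nodes_per_arc = .cfg(tr_cfg, "nodes_per_arc", 13),
      spacing = .cfg(tr_cfg, "spacing", 5)))
    geoms <- traj$control_points
    n_nodes <- length(geoms)
    fl_idx <- seq(2, n_nodes - 1, by = 3)
    infl_fl <- stage("influence_fluence",
                     assemble_influence(geoms[fl_idx], bgrid, phantom,
                                        kernel))
    fl <- stage("fluence_optimization",
                optimize_fluence(infl_fl, phantom$structures, objective,
                                 n_iter = n_fl))
    fmaps <- lapply(fl$weights, matrix, nrow = bgrid$n_rows)
    aps <- stage("sequencing",
                 arc_distribute(fmaps, fl_idx, n_nodes, bgrid, constraints,
                                mlc))
    plan <- plan_new("dynamic_arc", geoms, apertures = aps,
                     prescription = prescription, scheme = scheme,
                     meta = list(seed = seed, config_hash = cfg_hash))
    infl <- stage("influence_full",
                  assemble_influence(geoms, bgrid, phantom, kernel))
    motion <- if (scheme %in% c("CKA4", "CKA5")) "effective" else "discrete"
    dao <- stage("aperture_optimization",
                 optimize_apertures(plan, infl, phantom$structures,
                                    objective, motion_model = motion,
                                    n_iter = n_dao,
                                    constraints = constraints, mlc = mlc,
                                    bgrid = bgrid))
    plan <- dao$plan
    final_dose <- dao$dose
    recalc <- switch(scheme,
                     CKA2 = c(5L, 1L), CKA3 = c(5L, 20L), CKA5 = c(5L, 20L),
                     NULL)
    if (!is.null(recalc)) {
      ip <- stage("recalculation",
                  interpolate_plan(plan, recalc[1], recalc[2]))
      final_dose <- stage("recalculation_dose",
                          evaluate_plan_dose(ip, phantom, bgrid, kernel))
    }
    tm <- estimate_time_dynamic(plan)
  }

  report <- stage("evaluation", {
    dvhs <- lapply(phantom$structures, function(s) dvh(final_dose, s))
    ci <- conformity_index(final_dose, phantom$structures$ptv, phantom$grid,
                           prescription)
    goals <- .cfg(cfg, "goals", NULL)
    goal_tab <- if (!is.null(goals))
      check_goals(dvhs, as.data.frame(goals)) else NULL
    list(scheme = scheme, seed = seed, config_hash = cfg_hash,
         prescription = prescription,
         total_mu = plan_total_mu(plan),
         ptv_d95 = dose_at_volume(final_dose[phantom$structures$ptv$idx],
                                  0.95),
         ci = ci$ci, delivery_time_s = tm$total,
         goals = goal_tab, dvhs = dvhs)
  })

  stage("artifacts", {
    write_plan(plan, file.path(out_dir, "plan.json"))
    dose_grid <- voxel_grid(phantom$grid$origin, phantom$grid$spacing,
                            phantom$grid$dims,
                            array(final_dose, phantom$grid$dims))
    write_volume(dose_grid, file.path(out_dir, "dose.json"))
    dvh_df <- do.call(rbind, lapply(report$dvhs, function(cv)
      data.frame(structure = cv$name, dose = cv$dose, volume = cv$volume)))
    utils::write.csv(dvh_df, file.path(out_dir, "dvh.csv"),
                     row.names = FALSE)
    rep_out <- report[c("scheme", "seed", "config_hash", "prescription",
                        "total_mu", "ptv_d95", "ci", "delivery_time_s")]
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  lg("pipeline done")
  invisible(list(plan = plan, dose = final_dose, report = report,
                 out_dir = out_dir))
}
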