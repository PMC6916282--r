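# Treatment-plan container shared by the sequencer, the direct aperture
# optimizer and the evaluation machinery.

#' Treatment plan
#'
#' @param mode `"dynamic_arc"` (one aperture per trajectory node, delivered
#'   while the robot moves) or `"static"` (a list of step-and-shoot segments
#'   per node).
#' @param geometries list of [cp_geometry()], one per node, in delivery order.
#' @param apertures dynamic mode: list of [aperture()] (MU inside), one per
#'   node.
#' @param segments static mode: list (per node) of lists of apertures.
#' @param prescription prescription dose in Gy.
#' @param scheme dose-calculation scheme tag (`CKA1`..`CKA5`, `CKSB`).
#' @param meta named list of provenance (seed, config hash, ...).
#' @return object of class `plan`.
#' @export
plan_new <- function(mode = c("dynamic_arc", "static"), geometries,
                     apertures = NULL, segments = NULL, prescription,
                     scheme = "CKA4", meta = list()) {
  mode <- match.arg(mode)
  stopifnot(prescription > 0)
  if (!scheme %in% c("CKA1", "CKA2", "CKA3", "CKA4", "CKA5", "CKSB"))
    stop("unknown scheme tag: ", scheme)
  if (mode == "dynamic_arc") {
    stopifnot(!is.null(apertures), length(apertures) == length(geometries))
    for (ap in apertures) stopifnot(inherits(ap, "aperture"), ap$mu >= 0)
  } else {
    stopifnot(!is.null(segments), length(segments) == length(geometries))
  }
  structure(list(mode = mode, geometries = geometries, apertures = apertures,
                 segments = segments, prescription = prescription,
                 scheme = scheme, meta = meta), class = "plan")
}

#' Total monitor units of a plan
#' @param plan a `plan`.
#' @return total MU per fraction.
#' @export
plan_total_mu <- function(plan) {
  if (plan$mode == "dynamic_arc") {
    sum(vapply(plan$apertures, function(a) a$mu, numeric(1)))
  } else {
    sum(vapply(plan$segments, function(sl)
      sum(vapply(sl, function(a) a$mu, numeric(1))), numeric(1)))
  }
}

#' Scale all plan MU by a factor
#' @param plan a `plan`.
#' @param factor non-negative scale.
#' @return the rescaled plan.
#' @export
plan_scale_mu <- function(plan, factor) {
  stopifnot(factor >= 0)
  if (plan$mode == "dynamic_arc") {
    plan$apertures <- lapply(plan$apertures, function(a) {
      a$mu <- a$mu * factor; a
    })
  } else {
    plan$segments <- lapply(plan$segments, function(sl)
      lapply(sl, function(a) { a$mu <- a$mu * factor; a }))
  }
  plan
}
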