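# Synthetic voxel phantoms and the two-control-point demonstration plans.

#' Regular voxel grid
#'
#' @param origin corner of the grid (mm, 3-vector); voxel centres sit at
#'   `origin + (index - 0.5) * spacing`.
#' @param spacing voxel size per axis (mm, recycled to length 3).
#' @param dims integer voxel counts per axis.
#' @param values array of `dims` (relative electron density, or Gy for dose).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, dims, values = NULL) {
  spacing <- rep_len(spacing, 3)
  dims <- as.integer(rep_len(dims, 3))
  stopifnot(all(spacing > 0), all(dims >= 1))
  if (is.null(values)) values <- array(0, dims)
  stopifnot(all(dim(values) == dims))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, values = values), class = "voxel_grid")
}

#' Voxel-centre coordinates of a grid
#' @param grid a [voxel_grid()].
#' @return matrix (n voxels x 3), rows in array (column-major) order.
#' @export
voxel_centers <- function(grid) {
  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$spacing[3]
  cbind(rep(cx, times = grid$dims[2] * grid$dims[3]),
        rep(rep(cy, each = grid$dims[1]), times = grid$dims[3]),
        rep(cz, each = grid$dims[1] * grid$dims[2]))
}

#' Labeled structure on a voxel grid
#'
#' @param name structure name.
#' @param idx integer voxel indices (into the flattened grid array).
#' @param grid the [voxel_grid()] the indices refer to.
#' @return object of class `roi_structure` with derived `volume_cc`.
#' @export
roi_structure <- function(name, idx, grid) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1), all(idx <= prod(grid$dims)))
  structure(list(name = name, idx = idx,
                 volume_cc = length(idx) * prod(grid$spacing) / 1000),
            class = "roi_structure")
}

#' Water phantom with a central spherical PTV
#'
#' A uniform unit-density box (default 300 x 300 x 200 mm) centred on the
#' target point, with a spherical planning target volume (default 60 mm
#' diameter) at its centre and a `body` structure equal to the whole box.
#'
#' @param width,length,height box dimensions in mm (x, y, z).
#' @param spacing isotropic voxel size in mm.
#' @param ptv_diameter PTV diameter in mm; the sphere must fit in the box.
#' @return list with `grid` ([voxel_grid()]) and `structures`
#'   (named list of [roi_structure()]: `body`, `ptv`).
#' @export
make_water_phantom <- function(width = 300, length = 300, height = 200,
                               spacing = 2.5, ptv_diameter = 60) {
  stopifnot(width > 0, length > 0, height > 0, spacing > 0, ptv_diameter > 0)
  if (ptv_diameter > min(width, length, height))
    stop("PTV sphere does not fit inside the phantom box")
  dims <- as.integer(round(c(width, length, height) / spacing))
  grid <- voxel_grid(origin = -dims * spacing / 2, spacing = spacing,
                     dims = dims, values = array(1, dims))
  ctr <- voxel_centers(grid)
  r2 <- rowSums(ctr^2)
  ptv_idx <- which(r2 <= (ptv_diameter / 2)^2)
  structures <- list(
    body = roi_structure("body", seq_len(prod(dims)), grid),
    ptv = roi_structure("ptv", ptv_idx, grid)
  )
  list(grid = grid, structures = structures)
}

# Half-chords of the PTV disc per fluence row, NA where the row misses it
#' @keywords internal
.ptv_row_chords <- function(bgrid, radius) {
  yc <- bgrid$yc
  ifelse(abs(yc) < radius, sqrt(pmax(radius^2 - yc^2, 0)), NA_real_)
}

#' Two-control-point demonstration plans
#'
#' Builds the moving-aperture illustration plans: two control points, the
#' first beam vertical and the second 5 degrees away, apertures shaped on the
#' PTV's beam's-eye-view disc.
#'
#' * `semicircle_pair`: complementary semicircular openings covering the two
#'   halves of the PTV disc, 1000 MU each.
#' * `crescent_pair`: 10 mm wide crescents of leaf openings along opposite
#'   sides of the PTV, 500 MU then 5500 MU.
#'
#' @param kind `"semicircle_pair"` or `"crescent_pair"`.
#' @param bgrid a [bixel_grid()] giving the fluence-row layout.
#' @param ptv_radius PTV radius in mm.
#' @param separation angular separation of the two beams, degrees.
#' @param flip if `TRUE`, swap which half/side each control point covers.
#' @param crescent_width width of the crescent openings along leaf travel, mm.
#' @param sad source-axis distance, mm.
#' @return a `plan` (see [plan_new()]) in dynamic-arc mode.
#' @export
make_two_cp_demo <- function(kind = c("semicircle_pair", "crescent_pair"),
                             bgrid, ptv_radius = 30, separation = 5,
                             flip = FALSE, crescent_width = 10, sad = 800) {
  kind <- match.arg(kind)
  ref <- reference_frame()
  g1 <- cp_geometry(ref$d, ref$u, ref$v, sad = sad, index = 1L)
  axis <- c(0, 1, 0)   # tilt in the x-z plane: motion along leaf travel
  a <- separation * pi / 180
  g2 <- cp_geometry(rotate_about(ref$d, axis, a),
                    rotate_about(ref$u, axis, a),
                    rotate_about(ref$v, axis, a), sad = sad, index = 2L)
  ch <- .ptv_row_chords(bgrid, ptv_radius)
  n_rows <- length(bgrid$yc)
  l1 <- r1 <- l2 <- r2 <- numeric(n_rows)
  if (kind == "semicircle_pair") {
    for (i in seq_len(n_rows)) {
      if (is.na(ch[i])) next
      l1[i] <- -ch[i]; r1[i] <- 0
      l2[i] <- 0; r2[i] <- ch[i]
    }
    mu <- c(1000, 1000)
  } else {
    for (i in seq_len(n_rows)) {
      if (is.na(ch[i])) next
      if (2 * ch[i] <= crescent_width) {
        l1[i] <- -ch[i]; r1[i] <- ch[i]
        l2[i] <- -ch[i]; r2[i] <- ch[i]
      } else {
        l1[i] <- -ch[i]; r1[i] <- -ch[i] + crescent_width
        l2[i] <- ch[i] - crescent_width; r2[i] <- ch[i]
      }
    }
    mu <- c(500, 5500)
  }
  if (flip) { tmp <- list(l1, r1); l1 <- l2; r1 <- r2; l2 <- tmp[[1]]; r2 <- tmp[[2]] }
  plan_new(mode = "dynamic_arc",
           geometries = list(g1, g2),
           apertures = list(aperture(l1, r1, mu[1]), aperture(l2, r2, mu[2])),
           prescription = 10,
           scheme = if (kind == "semicircle_pair") "CKA1" else "CKA4")
}
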