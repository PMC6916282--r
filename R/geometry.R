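# Room-frame geometry helpers: right-handed frame, +z vertical, target point
# at the origin. Beam directions are unit vectors pointing from source to
# target; sources lie on the sphere of radius SAD (800 mm nominal).

#' @keywords internal
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of vector v about unit axis by angle (radians)
#' @keywords internal
rotate_about <- function(v, axis, angle) {
  axis <- unit3(axis)
  ca <- cos(angle); sa <- sin(angle)
  v * ca + cross3(axis, v) * sa + axis * sum(axis * v) * (1 - ca)
}

#' Control-point geometry
#'
#' A single beam orientation: source position at the nominal source-axis
#' distance from the target point (the origin), unit beam direction, and an
#' orthonormal beam's-eye-view basis (`u` along leaf travel, `v` along the
#' leaf-pair stack).
#'
#' @param direction unit 3-vector from source toward the target point.
#' @param u,v orthonormal basis of the plane perpendicular to `direction`.
#' @param sad source-axis distance in mm.
#' @param index ordinal position along a trajectory.
#' @return an object of class `cp_geometry`.
#' @export
cp_geometry <- function(direction, u, v, sad = 800, index = 1L) {
  direction <- unit3(direction)
  stopifnot(abs(sum(direction * u)) < 1e-8,
            abs(sum(direction * v)) < 1e-8,
            abs(sum(u * v)) < 1e-8,
            abs(sqrt(sum(u^2)) - 1) < 1e-8,
            abs(sqrt(sum(v^2)) - 1) < 1e-8,
            sad > 0)
  src <- -sad * direction
  structure(list(
    index = as.integer(index),
    source = src,
    direction = direction,
    u = u, v = v, sad = sad,
    polar = acos(max(-1, min(1, -direction[3]))) * 180 / pi,
    azimuth = atan2(src[2], src[1]) * 180 / pi
  ), class = "cp_geometry")
}

# Frame for a vertically-downward beam: leaves travel along +x.
#' @keywords internal
reference_frame <- function() {
  list(d = c(0, 0, -1), u = c(1, 0, 0), v = c(0, -1, 0))
}

# Geodesic interpolation between two control points: the full relative
# rotation carrying frame a onto frame b (including the in-plane collimator
# twist) is interpolated by the fraction `t` of its axis-angle, so t = 1
# reproduces b's frame exactly.
#' @keywords internal
slerp_geometry <- function(a, b, t, index = 1L) {
  A <- cbind(a$u, a$v, a$direction)
  B <- cbind(b$u, b$v, b$direction)
  R <- B %*% t(A)                      # relative rotation, frame a -> b
  # axis-angle of R
  ca <- (sum(diag(R)) - 1) / 2
  ang <- acos(max(-1, min(1, ca)))
  if (ang < 1e-12)
    return(cp_geometry(a$direction, a$u, a$v, sad = a$sad, index = index))
  if (pi - ang < 1e-9) stop("antipodal control points cannot be interpolated")
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  cp_geometry(rotate_about(a$direction, axis, ang * t),
              rotate_about(a$u, axis, ang * t),
              rotate_about(a$v, axis, ang * t),
              sad = a$sad, index = index)
}

# Angle in degrees between two unit directions
#' @keywords internal
angle_between <- function(d1, d2) {
  acos(max(-1, min(1, sum(d1 * d2)))) * 180 / pi
}
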