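# Machine model: MLC geometry, delivery constraints, and the fixed arc /
# body-path trajectories.
#
# Apertures are represented at fluence-row resolution: the MLC leaves are
# paired two-by-two, so one row of the 7.7 mm fluence grid corresponds to two
# physical leaf pairs that move together. All leaf positions are expressed in
# mm at the nominal (SAD) plane, leaves travelling along the beam's-eye-view
# x axis.

#' MLC specification
#'
#' @param leaf_width physical width of a single leaf (mm, across travel).
#' @param n_leaf_pairs number of physical leaf pairs (must be even so leaves
#'   can be paired into fluence rows).
#' @param travel_range maximum |tip position| in mm at the nominal plane.
#' @return object of class `mlc_spec`; `paired_leaf_width` (two leaf widths)
#'   is the fluence-row height and `n_rows` the number of paired rows.
#' @export
mlc_spec <- function(leaf_width = 3.85, n_leaf_pairs = 20L, travel_range = 55) {
  n_leaf_pairs <- as.integer(n_leaf_pairs)
  stopifnot(leaf_width > 0, n_leaf_pairs >= 2, n_leaf_pairs %% 2 == 0,
            travel_range > 0)
  structure(list(
    leaf_width = leaf_width,
    n_leaf_pairs = n_leaf_pairs,
    travel_range = travel_range,
    paired_leaf_width = 2 * leaf_width,
    n_rows = n_leaf_pairs %/% 2L
  ), class = "mlc_spec")
}

#' Delivery constraints (machine limits)
#'
#' Defaults follow the machine limits used throughout: minimum open field
#' 7.6 mm wide by 7.7 mm long (one paired row), a 5 mm minimum gap to the
#' opposing leaf of the adjacent pair, 60 mm/s robot speed giving a 1.5 s
#' traversal per 5 degrees of arc, and a 33 mm/s MLC speed from which the
#' per-interval leaf travel limit is derived by rounding
#' `max_mlc_speed * interval_time` to the nearest mm (50 mm).
#'
#' @param min_field_width minimum open gap per row, mm.
#' @param min_field_length minimum open field length, mm (one paired row).
#' @param min_opposing_gap minimum distance to the opposing leaf of an
#'   adjacent pair, mm.
#' @param max_robot_speed mm/s.
#' @param interval_time seconds to traverse one node-node interval (T_R).
#' @param max_mlc_speed mm/s.
#' @param min_mu,max_mu monitor-unit bounds per segment.
#' @return object of class `delivery_constraints` including the derived
#'   `max_leaf_travel` per interval.
#' @export
delivery_constraints <- function(min_field_width = 7.6, min_field_length = 7.7,
                                 min_opposing_gap = 5, max_robot_speed = 60,
                                 interval_time = 1.5, max_mlc_speed = 33,
                                 min_mu = 0, max_mu = Inf) {
  stopifnot(max_robot_speed > 0, interval_time > 0, max_mlc_speed > 0,
            min_field_width > 0, min_field_length > 0, min_opposing_gap >= 0)
  structure(list(
    min_field_width = min_field_width,
    min_field_length = min_field_length,
    min_opposing_gap = min_opposing_gap,
    max_robot_speed = max_robot_speed,
    interval_time = interval_time,
    max_mlc_speed = max_mlc_speed,
    max_leaf_travel = round(max_mlc_speed * interval_time),
    min_mu = min_mu,
    max_mu = max_mu
  ), class = "delivery_constraints")
}

#' MLC aperture at fluence-row resolution
#'
#' @param left,right leaf-tip positions per paired row, mm at the nominal
#'   plane. A row with `left == right` is closed (parked); open rows must have
#'   `left < right`.
#' @param mu segment monitor units (>= 0).
#' @return object of class `aperture`.
#' @export
aperture <- function(left, right, mu = 0) {
  stopifnot(length(left) == length(right), mu >= 0, all(left <= right))
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 mu = as.numeric(mu)), class = "aperture")
}

#' @rdname aperture
#' @param ap an `aperture`.
#' @return logical vector: which rows are open.
#' @export
aperture_open <- function(ap) ap$right - ap$left > 1e-9

#' Closed aperture parked at given positions
#' @keywords internal
closed_aperture <- function(n_rows, park = 0, mu = 0) {
  park <- rep_len(park, n_rows)
  aperture(park, park, mu)
}

#' Build the fixed arc trajectory
#'
#' Eight connected great-circle arcs (by default) about horizontal axes at
#' evenly spaced azimuths, nodes spaced exactly `spacing` degrees apart in
#' beam direction, all sources in the upper hemisphere at the nominal SAD
#' from the target point. The default fixture has 104 control points on eight
#' arcs of 13 nodes.
#'
#' @param n_arcs number of arcs.
#' @param nodes_per_arc integer vector (recycled) of node counts per arc.
#' @param spacing angular node spacing in degrees.
#' @param sad source-axis distance, mm.
#' @return object of class `trajectory` with `$mode = "arc"` and
#'   `$control_points`, a list of [cp_geometry()].
#' @export
build_arc_trajectory <- function(n_arcs = 8L, nodes_per_arc = 13L,
                                 spacing = 5, sad = 800) {
  n_arcs <- as.integer(n_arcs)
  nodes_per_arc <- rep_len(as.integer(nodes_per_arc), n_arcs)
  if (spacing <= 0) stop("spacing must be positive")
  if (n_arcs < 1 || any(nodes_per_arc < 1)) stop("empty arcs are not allowed")
  ref <- reference_frame()
  cps <- list(); idx <- 0L
  for (k in seq_len(n_arcs)) {
    azim <- (k - 1) * pi / n_arcs        # axis azimuth
    axis <- c(cos(azim), sin(azim), 0)
    n <- nodes_per_arc[k]
    # alternate tilt bands on either side of vertical, avoiding duplicate
    # vertical nodes between arcs
    if (k %% 2 == 1) {
      tilts <- -spacing / 2 - spacing * ((n - 1):0)
    } else {
      tilts <- spacing / 2 + spacing * (0:(n - 1))
    }
    for (tl in tilts) {
      idx <- idx + 1L
      a <- tl * pi / 180
      cps[[idx]] <- cp_geometry(rotate_about(ref$d, axis, a),
                                rotate_about(ref$u, axis, a),
                                rotate_about(ref$v, axis, a),
                                sad = sad, index = idx)
    }
  }
  structure(list(mode = "arc", control_points = cps,
                 angular_spacing = spacing, n_arcs = n_arcs,
                 nodes_per_arc = nodes_per_arc, sad = sad),
            class = "trajectory")
}

#' Build the static body-path node set
#'
#' Quasi-uniform (Fibonacci-lattice) source positions over a spherical cap of
#' the upper hemisphere (sources within `max_polar` degrees of vertical), so
#' no beam enters from below the couch. Deterministic given `n_nodes`.
#'
#' @param n_nodes number of nodes (the standard body path has 110).
#' @param max_polar largest source polar angle from vertical, degrees.
#' @param sad source-axis distance, mm.
#' @return a `trajectory` with `$mode = "body_path"`.
#' @export
build_body_path <- function(n_nodes = 110L, max_polar = 75, sad = 800) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1) stop("n_nodes must be >= 1")
  golden <- pi * (3 - sqrt(5))
  cmax <- cos(max_polar * pi / 180)
  cps <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    u <- if (n_nodes == 1) 0 else (i - 0.5) / n_nodes
    th <- acos(1 - u * (1 - cmax))       # source polar angle from +z
    ph <- (i - 1) * golden
    src_dir <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    d <- -src_dir
    # degenerate-safe BEV basis for static beams
    uax <- if (abs(d[3]) > 0.999) c(1, 0, 0) else unit3(cross3(d, c(0, 0, 1)))
    vax <- cross3(d, uax)
    cps[[i]] <- cp_geometry(d, uax, vax, sad = sad, index = i)
  }
  structure(list(mode = "body_path", control_points = cps,
                 angular_spacing = NA_real_, sad = sad),
            class = "trajectory")
}

# One sweep of the static shape rules (1)-(3). Returns modified left/right.
#' @keywords internal
.mlc_shape_sweep <- function(left, right, constraints, row_pitch = 7.7) {
  n <- length(left)
  wmin <- constraints$min_field_width
  gmin <- constraints$min_opposing_gap
  # (1) close malformed or undersized rows (park at midpoint)
  width <- right - left
  bad <- width < wmin - 1e-9 & width > 1e-9
  if (any(bad)) {
    mid <- (left[bad] + right[bad]) / 2
    left[bad] <- mid; right[bad] <- mid
  }
  open <- right - left > 1e-9
  # (2) opposing-leaf rule between adjacent open rows
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      j <- i + 1
      if (!(open[i] && open[j])) next
      # right leaf of row i vs left leaf of row j
      for (ord in list(c(i, j), c(j, i))) {
        a <- ord[1]; b <- ord[2]
        gap <- right[[a]] - left[[b]]
        if (gap < -1e-9) {
          # interdigitating: close the narrower of the two rows
          k <- if (right[a] - left[a] <= right[b] - left[b]) a else b
          mid <- (left[k] + right[k]) / 2
          left[k] <- mid; right[k] <- mid
          open[k] <- FALSE
        } else if (gap < gmin - 1e-9) {
          # open the offending left leaf out to the minimum gap
          left[b] <- right[a] - gmin
        }
      }
    }
  }
  # (3) min field length: every open row must reach min_field_length of
  # contiguous opening; at row resolution one row (7.7 mm) suffices, but a
  # longer requirement closes isolated runs that are too short.
  rows_needed <- ceiling(constraints$min_field_length / row_pitch - 1e-9)
  if (rows_needed > 1) {
    open <- right - left > 1e-9
    r <- rle(open)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] < rows_needed) {
        ii <- pos[k]:(pos[k] + r$lengths[k] - 1L)
        mid <- (left[ii] + right[ii]) / 2
        left[ii] <- mid; right[ii] <- mid
      }
    }
  }
  list(left = left, right = right)
}

#' Project an aperture onto the deliverable set
#'
#' Applies the machine shape rules (minimum field width and length, the
#' opposing-leaf / interdigitation rule) and, in arc mode, clips every leaf to
#' within the per-interval travel limit of its position in `previous`. The
#' rules are iterated to a fixed point so the operation is idempotent.
#'
#' @param ap an [aperture()].
#' @param previous the aperture at the preceding control point, or `NULL`.
#' @param constraints a [delivery_constraints()].
#' @param spec an [mlc_spec()].
#' @param mode `"arc"` (travel limit enforced against `previous`) or
#'   `"static"`.
#' @return a constraint-satisfying `aperture` (MU unchanged).
#' @export
apply_mlc_constraints <- function(ap, previous = NULL, constraints,
                                  spec = mlc_spec(), mode = c("arc", "static")) {
  mode <- match.arg(mode)
  if (any(ap$left > ap$right + 1e-9)) stop("malformed aperture: left > right")
  left <- pmin(pmax(ap$left, -spec$travel_range), spec$travel_range)
  right <- pmin(pmax(ap$right, -spec$travel_range), spec$travel_range)
  tmax <- constraints$max_leaf_travel
  wmin <- constraints$min_field_width
  for (sweep in 1:6) {
    l0 <- left; r0 <- right
    s <- .mlc_shape_sweep(left, right, constraints, spec$paired_leaf_width)
    left <- s$left; right <- s$right
    if (mode == "arc" && !is.null(previous)) {
      lo_l <- previous$left - tmax; hi_l <- previous$left + tmax
      lo_r <- previous$right - tmax; hi_r <- previous$right + tmax
      lc <- pmin(pmax(left, lo_l), hi_l)
      rc <- pmin(pmax(right, lo_r), hi_r)
      # rows whose clipped opening is undersized must close; park at a point
      # reachable by both leaves when feasible
      for (i in seq_along(lc)) {
        if (rc[i] - lc[i] > 1e-9 && rc[i] - lc[i] < wmin - 1e-9) {
          lo <- max(lo_l[i], lo_r[i]); hi <- min(hi_l[i], hi_r[i])
          if (lo <= hi) {
            p <- min(max((lc[i] + rc[i]) / 2, lo), hi)
            lc[i] <- p; rc[i] <- p
          } # else: infeasible to close fully; keep the clipped sliver open
        }
      }
      left <- lc; right <- rc
    }
    left <- pmin(pmax(left, -spec$travel_range), spec$travel_range)
    right <- pmin(pmax(right, -spec$travel_range), spec$travel_range)
    if (max(abs(left - l0), abs(right - r0)) < 1e-10) break
  }
  aperture(left, right, ap$mu)
}

#' Export a trajectory as a data frame
#'
#' @param traj a `trajectory`.
#' @return data.frame with node index, polar/azimuth angles (degrees) and
#'   source coordinates (mm).
#' @export
trajectory_table <- function(traj) {
  cps <- traj$control_points
  data.frame(
    index = vapply(cps, function(g) g$index, integer(1)),
    polar_deg = vapply(cps, function(g) g$polar, numeric(1)),
    azimuth_deg = vapply(cps, function(g) g$azimuth, numeric(1)),
    source_x = vapply(cps, function(g) g$source[1], numeric(1)),
    source_y = vapply(cps, function(g) g$source[2], numeric(1)),
    source_z = vapply(cps, function(g) g$source[3], numeric(1))
  )
}
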