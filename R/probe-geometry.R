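#' Construct a probe trajectory
#'
#' A straight-line insertion described by its brain-surface entry point and a
#' unit direction vector. Coordinates are (AP, ML, DV) in um in a single
#' declared atlas-style frame in which the brain surface is the plane DV = 0
#' and DV increases with depth.
#'
#' @param entry numeric length-3 (AP, ML, DV) entry point, um.
#' @param direction numeric length-3 direction; normalized internally, and
#'   oriented so its DV component is positive.
#' @param source one of `"planned"`, `"micromanipulator"`, `"histology"`.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(entry, direction, source = "planned") {
  if (length(entry) != 3L || length(direction) != 3L)
    stop_invalid("entry and direction must be length 3")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop_invalid("direction must be non-zero")
  direction <- direction / nrm
  if (direction[3L] < 0) direction <- -direction
  structure(list(entry = as.numeric(entry), direction = direction,
                 source = source), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: entry (%.0f, %.0f, %.0f) um, direction (%.3f, %.3f, %.3f)\n",
              x$source, x$entry[1], x$entry[2], x$entry[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' The planned repeated-site trajectory
#'
#' Entry at AP 2000 um, ML -2240 um on the brain surface, inserted at a 15
#' degree angle from vertical in the ML plane to 4 mm depth.
#'
#' @return a `trajectory` object with source `"planned"`.
#' @export
planned_repeated_site <- function() {
  ang <- 15 * pi / 180
  trajectory(entry = c(2000, -2240, 0),
             direction = c(0, sin(ang), cos(ang)),
             source = "planned")
}

#' Fit a straight-line trajectory to traced track points
#'
#' Total-least-squares 3D line: the first principal axis of the point cloud
#' through its centroid. The brain-surface entry point is the intersection of
#' the fitted line with an injectable surface; by default the plane DV = 0.
#'
#' @param track_points numeric matrix (n x 3) of (AP, ML, DV) points, um;
#'   n >= 2, not all coincident.
#' @param source source tag for the result.
#' @param surface_dv function mapping (AP, ML) to surface DV; default
#'   `function(ap, ml) 0`.
#' @return a `trajectory` object.
#' @export
fit_trajectory <- function(track_points, source = "histology",
                           surface_dv = function(ap, ml) 0) {
  pts <- as.matrix(track_points)
  if (ncol(pts) != 3L) stop_invalid("track_points must have 3 columns")
  if (nrow(pts) < 2L) stop_invalid("need >= 2 track points")
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2L, centroid)
  if (all(abs(centered) < .Machine$double.eps^0.5))
    stop_invalid("track points are coincident")
  dir <- svd(centered, nu = 0, nv = 1)$v[, 1L]
  if (dir[3L] < 0) dir <- -dir
  if (abs(dir[3L]) < 1e-12)
    stop_invalid("trajectory is parallel to the brain surface")
  # walk along the line to the surface (one Newton step suffices for a plane)
  t0 <- (surface_dv(centroid[1L], centroid[2L]) - centroid[3L]) / dir[3L]
  entry <- centroid + t0 * dir
  trajectory(entry = entry, direction = dir, source = source)
}

#' Surface displacement between a trajectory and the planned one
#'
#' @param traj,planned `trajectory` objects sharing the surface convention.
#' @return named numeric: `d_ap`, `d_ml` (componentwise, um) and `distance`
#'   (Euclidean in the surface plane, um).
#' @examples
#' p <- planned_repeated_site()
#' t2 <- trajectory(p$entry + c(0, 100, 0), p$direction, "histology")
#' surface_displacement(t2, p)  # (0, 100, 100)
#' @export
surface_displacement <- function(traj, planned) {
  d <- traj$entry - planned$entry
  c(d_ap = d[1L], d_ml = d[2L],
    distance = sqrt(d[1L]^2 + d[2L]^2))
}

#' Angle between a trajectory and the planned one
#'
#' The 3D angle is `acos(|d1 . d2|)`, using the absolute dot product because
#' traced directions carry a sign ambiguity. Per-plane components are the
#' angles between the projections onto the sagittal (AP-DV) and coronal
#' (ML-DV) planes.
#'
#' @param traj,planned `trajectory` objects.
#' @return named numeric, degrees: `angle`, `angle_ap`, `angle_ml`.
#' @export
angle_difference <- function(traj, planned) {
  d1 <- traj$direction
  d2 <- planned$direction
  ang <- function(u, v) {
    cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
    acos(min(1, cosang)) * 180 / pi
  }
  c(angle = ang(d1, d2),
    angle_ap = ang(d1[c(1L, 3L)], d2[c(1L, 3L)]),
    angle_ml = ang(d1[c(2L, 3L)], d2[c(2L, 3L)]))
}

#' Per-insertion targeting-variability table
#'
#' Computes surface displacement (micromanipulator and histology vs planned)
#' and histology angle deviation for a set of sessions, one row per
#' insertion, ready to feed [permutation_test()] per lab.
#'
#' @param sessions list of [session_record()] objects carrying trajectories.
#' @param min_insertions labs with fewer insertions are dropped (default 4).
#' @return data.frame with columns `lab_id`, `subject_id`, `session_id`,
#'   `micro_distance`, `histology_distance`, `angle`.
#' @export
targeting_table <- function(sessions, min_insertions = 4L) {
  rows <- lapply(sessions, function(s) {
    data.frame(
      lab_id = s$lab_id, subject_id = s$subject_id,
      session_id = s$session_id,
      micro_distance = if (is.null(s$micro_traj)) NA_real_ else
        surface_displacement(s$micro_traj, s$planned_traj)[["distance"]],
      histology_distance = if (is.null(s$histology_traj)) NA_real_ else
        surface_displacement(s$histology_traj, s$planned_traj)[["distance"]],
      angle = if (is.null(s$histology_traj)) NA_real_ else
        angle_difference(s$histology_traj, s$planned_traj)[["angle"]],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  keep_labs <- names(which(table(tab$lab_id) >= min_insertions))
  tab[tab$lab_id %in% keep_labs, , drop = FALSE]
}
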