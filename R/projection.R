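#' View angles of a world point
#'
#' Azimuth/elevation of a 3D point in the observer frame (eye at origin,
#' Y forward along the road, X across, Z up): azimuth = atan2(x, y),
#' elevation = atan2(z, hypot(x, y)), both in degrees.
#'
#' @param point numeric length-3 vector or n x 3 matrix (m).
#' @return A matrix with columns `azimuth`, `elevation` (deg).
#' @export
world_to_view_angles <- function(point) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  if (any(rowSums(p^2) == 0)) stop("zero vector has no view direction")
  az <- atan2(p[, 1], p[, 2]) * DEG
  el <- atan2(p[, 3], sqrt(p[, 1]^2 + p[, 2]^2)) * DEG
  cbind(azimuth = az, elevation = el)
}

#' Visual angle subtended by a width at a distance
#'
#' @param width object extent in m.
#' @param distance viewing distance in m.
#' @return Angle in degrees, `2 atan(width / (2 distance))`.
#' @export
angular_size <- function(width, distance) {
  if (any(width <= 0) || any(distance <= 0))
    stop("angular_size: width and distance must be positive")
  2 * atan(width / (2 * distance)) * DEG
}

camera_focal_px <- function(scene) {
  (scene$screen_resolution[2] / 2) / tan(deg2rad(scene$camera_vertical_fov / 2))
}

screen_metrics <- function(scene) {
  w_m <- 2 * scene$viewing_distance * tan(deg2rad(scene$screen_extent[1] / 2))
  h_m <- 2 * scene$viewing_distance * tan(deg2rad(scene$screen_extent[2] / 2))
  list(px_x = w_m / scene$screen_resolution[1],
       px_y = h_m / scene$screen_resolution[2])
}

#' Project view angles onto the display, in screen visual degrees
#'
#' Pinhole projection with the camera's vertical field of view onto the
#' rendered image plane, followed by conversion of the image position to
#' visual degrees for a flat screen of `screen_extent` viewed at
#' `viewing_distance`. The map is odd and monotone in each coordinate.
#' Angles beyond the camera frame return NA (out-of-frame marker).
#'
#' @param angles length-2 vector or n x 2 matrix `(azimuth, elevation)` in
#'   view degrees.
#' @param scene a [scene_config()].
#' @return Matrix with columns `x`, `y` in screen degrees.
#' @export
view_to_screen <- function(angles, scene = scene_config()) {
  a <- if (is.matrix(angles)) angles else matrix(angles, ncol = 2)
  f <- camera_focal_px(scene)
  sm <- screen_metrics(scene)
  az <- deg2rad(a[, 1]); el <- deg2rad(a[, 2])
  # camera forward = +Y; u along +X, v along +Z
  u <- f * tan(az)
  v <- f * tan(el) / cos(az)
  oob <- abs(a[, 1]) >= 90 |
    abs(u) > scene$screen_resolution[1] / 2 |
    abs(v) > scene$screen_resolution[2] / 2
  x <- atan2(u * sm$px_x, scene$viewing_distance) * DEG
  y <- atan2(v * sm$px_y, scene$viewing_distance) * DEG
  x[oob] <- NA_real_; y[oob] <- NA_real_
  cbind(x = x, y = y)
}

#' Invert the screen projection back to view angles
#'
#' @param screen length-2 vector or n x 2 matrix `(x, y)` in screen deg.
#' @param scene a [scene_config()].
#' @return Matrix with columns `azimuth`, `elevation` in view degrees.
#' @export
screen_to_view <- function(screen, scene = scene_config()) {
  s <- if (is.matrix(screen)) screen else matrix(screen, ncol = 2)
  f <- camera_focal_px(scene)
  sm <- screen_metrics(scene)
  u <- scene$viewing_distance * tan(deg2rad(s[, 1])) / sm$px_x
  v <- scene$viewing_distance * tan(deg2rad(s[, 2])) / sm$px_y
  az <- atan(u / f)
  el <- atan(v * cos(az) / f)
  cbind(azimuth = rad2deg(az), elevation = rad2deg(el))
}

#' Back-project screen-degree gaze samples to 3D direction vectors
#'
#' Unit direction vectors (observer frame) for points on the screen, used
#' by the 3D angular-velocity computation.
#'
#' @param screen n x 2 matrix `(x, y)` in screen degrees.
#' @param scene a [scene_config()].
#' @return n x 3 matrix of unit vectors.
#' @export
screen_to_direction <- function(screen, scene = scene_config()) {
  va <- screen_to_view(screen, scene)
  az <- deg2rad(va[, 1]); el <- deg2rad(va[, 2])
  d <- cbind(x = cos(el) * sin(az), y = cos(el) * cos(az), z = sin(el))
  d
}

#' Eye-frame direction vectors of screen positions
#'
#' Unit vectors from the observer's eye to points on the physical screen
#' (flat plane at `viewing_distance`). Angles between these directions are
#' eye rotations in visual degrees, the unit in which saccade amplitudes
#' are reported; contrast [screen_to_direction()], which back-projects
#' through the rendering camera into the virtual world.
#'
#' @param screen n x 2 matrix `(x, y)` in screen degrees.
#' @param scene a [scene_config()].
#' @return n x 3 matrix of unit vectors.
#' @export
screen_eye_direction <- function(screen, scene = scene_config()) {
  s <- if (is.matrix(screen)) screen else matrix(screen, ncol = 2)
  d <- cbind(tan(deg2rad(s[, 1])), 1, tan(deg2rad(s[, 2])))
  d / sqrt(rowSums(d^2))
}

#' Calibrate the camera field of view from an on-screen span
#'
#' Solves for the vertical camera FOV under which a world extent `width`
#' at distance `distance` spans `target_span` visual degrees on the screen.
#' Useful when the rendering camera's FOV is unknown but an on-screen span
#' has been measured.
#'
#' @param width,distance world extent and distance in m.
#' @param target_span measured on-screen span in visual degrees.
#' @param scene a [scene_config()] providing screen geometry.
#' @return Vertical FOV in degrees.
#' @export
calibrate_fov <- function(width = 1.82, distance = 50, target_span = 0.95,
                          scene = scene_config()) {
  span_at <- function(fov) {
    sc <- scene
    sc$camera_vertical_fov <- fov
    half <- angular_size(width, distance) / 2
    p <- view_to_screen(rbind(c(-half, 0), c(half, 0)), sc)
    p[2, 1] - p[1, 1]
  }
  uniroot(function(fov) span_at(fov) - target_span,
          interval = c(15, 115), tol = 1e-8)$root
}

#' Dynamic vehicle area of interest
#'
#' Projected bounding rectangle of the vehicle front plane at time `t`,
#' expanded by `aoi_margin` on every side; the AOI center is the projected
#' front-plane center. Because the vehicle looms, the box area is
#' non-decreasing during the approach.
#'
#' @param trial one-row trial spec, or NULL with `traj` given.
#' @param t time from interval onset in s (scalar or vector).
#' @param scene a [scene_config()].
#' @param traj optional precomputed [trajectory()].
#' @return A list of class `aoi_box` with `center` (n x 2), `half_w`,
#'   `half_h` (deg) and `kind = "vehicle"`; NA rows after vehicle offset.
#' @export
vehicle_aoi <- function(trial = NULL, t, scene = scene_config(),
                        traj = NULL) {
  if (is.null(traj)) traj <- trajectory(trial, scene, sample_rate = 1000)
  v <- traj$speed_ms
  d0 <- traj$distance[1]
  d <- d0 - v * t
  off <- t >= scene$display_duration | d <= 0
  sgn <- if (identical(traj$approach_side, "left")) -1 else 1
  hw <- scene$vehicle_width / 2
  zb <- -scene$eye_height
  zt <- scene$vehicle_height - scene$eye_height
  n <- length(t)
  center <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  half_w <- half_h <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (off[i]) next
    corners <- rbind(
      c(sgn * (scene$lane_offset - hw), d[i], zb),
      c(sgn * (scene$lane_offset + hw), d[i], zb),
      c(sgn * (scene$lane_offset - hw), d[i], zt),
      c(sgn * (scene$lane_offset + hw), d[i], zt))
    sc <- view_to_screen(world_to_view_angles(corners), scene)
    cc <- view_to_screen(world_to_view_angles(
      c(sgn * scene$lane_offset, d[i], (zb + zt) / 2)), scene)
    center[i, ] <- cc
    half_w[i] <- (max(sc[, 1]) - min(sc[, 1])) / 2 + scene$aoi_margin
    half_h[i] <- (max(sc[, 2]) - min(sc[, 2])) / 2 + scene$aoi_margin
  }
  structure(list(center = center, half_w = half_w, half_h = half_h,
                 kind = "vehicle", t = t),
            class = "aoi_box")
}

#' Screen path of the vehicle AOI center over a trajectory
#'
#' @param traj a [trajectory()].
#' @param scene a [scene_config()].
#' @return n x 2 matrix of screen degrees; after vehicle offset the last
#'   visible position is held (the scene stays on without the vehicle).
#' @export
aoi_center_path <- function(traj, scene = scene_config()) {
  sgn <- if (identical(traj$approach_side, "left")) -1 else 1
  zc <- scene$vehicle_height / 2 - scene$eye_height
  world <- cbind(sgn * scene$lane_offset, traj$distance, zc)
  p <- view_to_screen(world_to_view_angles(world), scene)
  if (any(!traj$visible)) {
    last <- max(which(traj$visible))
    p[!traj$visible, 1] <- p[last, 1]
    p[!traj$visible, 2] <- p[last, 2]
  }
  p
}

#' Road-crossing area of interest
#'
#' Static screen rectangle covering the crossing area, mirrored in x for
#' left-side approaches.
#'
#' @param scene a [scene_config()].
#' @param approach_side `"right"` or `"left"`.
#' @return An `aoi_box` with scalar geometry.
#' @export
crossing_aoi <- function(scene = scene_config(), approach_side = "right") {
  sgn <- if (identical(approach_side, "left")) -1 else 1
  box <- scene$crossing_aoi
  structure(list(center = matrix(c(sgn * box[1], box[2]), 1, 2,
                                 dimnames = list(NULL, c("x", "y"))),
                 half_w = box[3], half_h = box[4], kind = "crossing"),
            class = "aoi_box")
}

point_in_aoi <- function(x, y, aoi, i = 1) {
  !is.na(aoi$center[i, 1]) &&
    abs(x - aoi$center[i, 1]) <= aoi$half_w[min(i, length(aoi$half_w))] &&
    abs(y - aoi$center[i, 2]) <= aoi$half_h[min(i, length(aoi$half_h))]
}
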