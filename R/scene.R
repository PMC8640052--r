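#' Scene configuration for the virtual road-crossing
#'
#' Geometry of the simulated roadside scene: a single-lane road crossed by
#' the observer's line of travel, a vehicle approaching at constant speed,
#' and the display that renders the scene. The coordinate convention puts
#' the observer's eye at the origin, Z up, Y along the road pointing in the
#' direction the vehicle comes from, and X across the road; the stopping
#' line is abeam of the observer (Y = 0). The road centerline then lies at
#' lateral offset `curb_gap + road_width / 2`.
#'
#' @param road_width road width in m.
#' @param vehicle_length,vehicle_width,vehicle_height vehicle dimensions in m.
#' @param eye_height simulated eye height in m.
#' @param curb_gap distance from the observer to the curb in m.
#' @param display_duration visible approach duration in s.
#' @param post_offset_duration time the scene stays on after the vehicle
#'   disappears, in s.
#' @param viewing_distance eye-to-screen distance in m.
#' @param screen_extent c(horizontal, vertical) screen extent in visual deg.
#' @param screen_resolution c(width, height) in pixels.
#' @param camera_vertical_fov vertical field of view of the rendering
#'   camera in deg; see [calibrate_fov()].
#' @param aoi_margin margin added on every side of the projected vehicle
#'   bounding box, in deg.
#' @param crossing_aoi screen rectangle of the road-crossing area,
#'   `c(cx, cy, half_w, half_h)` in screen deg for a right-side approach
#'   (x mirrored for left approaches).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(road_width = 3.36,
                         vehicle_length = 4.53,
                         vehicle_width = 1.82,
                         vehicle_height = 1.47,
                         eye_height = 1.6,
                         curb_gap = 0.64,
                         display_duration = 3.0,
                         post_offset_duration = 2.0,
                         viewing_distance = 0.66,
                         screen_extent = c(30, 25),
                         screen_resolution = c(1280, 1024),
                         camera_vertical_fov = 55,
                         aoi_margin = 0.25,
                         crossing_aoi = c(8, -10, 6, 4)) {
  lengths <- c(road_width, vehicle_length, vehicle_width, vehicle_height,
               eye_height, curb_gap, viewing_distance)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all scene lengths must be strictly positive")
  if (display_duration <= 0) stop("display_duration must be > 0")
  if (camera_vertical_fov <= 10 || camera_vertical_fov >= 120)
    stop("camera_vertical_fov must lie in (10, 120) degrees")
  structure(list(
    road_width = road_width,
    vehicle_length = vehicle_length,
    vehicle_width = vehicle_width,
    vehicle_height = vehicle_height,
    eye_height = eye_height,
    curb_gap = curb_gap,
    display_duration = display_duration,
    post_offset_duration = post_offset_duration,
    viewing_distance = viewing_distance,
    screen_extent = screen_extent,
    screen_resolution = screen_resolution,
    camera_vertical_fov = camera_vertical_fov,
    aoi_margin = aoi_margin,
    crossing_aoi = crossing_aoi,
    lane_offset = curb_gap + road_width / 2
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  road %.2f m wide, curb gap %.2f m, lane offset %.2f m\n",
              x$road_width, x$curb_gap, x$lane_offset))
  cat(sprintf("  vehicle %.2f x %.2f x %.2f m, eye height %.2f m\n",
              x$vehicle_length, x$vehicle_width, x$vehicle_height,
              x$eye_height))
  cat(sprintf("  display %.1f s + %.1f s post-offset; camera FOV %.1f deg\n",
              x$display_duration, x$post_offset_duration,
              x$camera_vertical_fov))
  invisible(x)
}

#' Experimental design grid
#'
#' The 9 x 9 factorial grid of comparison-vehicle speeds and
#' times-to-arrival, plus the standard stimulus and the number of blocks
#' per session.
#'
#' @param speed_levels comparison speeds in km/h.
#' @param tta_levels comparison times-to-arrival in s.
#' @param standard_speed,standard_tta the standard stimulus.
#' @param n_blocks blocks per session; each block shows every grid cell once.
#' @return An object of class `design_grid`.
#' @export
design_grid <- function(speed_levels = seq(10, 90, by = 10),
                        tta_levels = seq(1.44, 4.64, by = 0.4),
                        standard_speed = 50,
                        standard_tta = 3.04,
                        n_blocks = 3) {
  if (!isTRUE(any(abs(speed_levels - standard_speed) < 1e-9)))
    stop("standard_speed must be a member of speed_levels")
  if (!isTRUE(any(abs(tta_levels - standard_tta) < 1e-9)))
    stop("standard_tta must be a member of tta_levels")
  structure(list(
    speed_levels = speed_levels,
    tta_levels = tta_levels,
    standard_speed = standard_speed,
    standard_tta = standard_tta,
    n_blocks = n_blocks
  ), class = "design_grid")
}

kmh_to_ms <- function(v) v / 3.6

#' Start distance of the approach
#'
#' With a fixed display interval, the distance (front edge to stopping
#' line) at which the vehicle must appear so that it still has
#' `remaining_tta` seconds to go when it disappears is
#' `speed * (display_duration + remaining_tta)`.
#'
#' @param speed vehicle speed in m/s.
#' @param remaining_tta time-to-arrival at display offset, in s.
#' @param display_duration visible interval, in s.
#' @return Start distance in m.
#' @export
start_distance <- function(speed, remaining_tta, display_duration = 3) {
  if (any(speed <= 0) || any(remaining_tta <= 0) || any(display_duration <= 0))
    stop("start_distance: all arguments must be positive")
  speed * (display_duration + remaining_tta)
}

#' Constant-speed approach trajectory
#'
#' Front-edge distance to the stopping line d(t) = d_start - v t over the
#' visible interval, together with the 3D world point of the vehicle
#' front-plane center in the observer frame (eye at the origin).
#'
#' @param trial one-row trial specification (see [make_design()]); needs
#'   `comparison_speed` (km/h), `comparison_tta` (s) and `approach_side`
#'   (or pass `speed_kmh`/`tta_s` directly).
#' @param scene a [scene_config()].
#' @param sample_rate sampling rate in Hz (>= 1).
#' @param speed_kmh,tta_s,approach_side scalar overrides for use without a
#'   trial row.
#' @return A list of class `trajectory` with `times` (s), `distance` (m),
#'   `world` (n x 3 matrix), `visible` (logical), `speed_ms`.
#' @export
trajectory <- function(trial = NULL, scene = scene_config(),
                       sample_rate = 1000,
                       speed_kmh = NULL, tta_s = NULL,
                       approach_side = NULL) {
  if (sample_rate < 1) stop("sample_rate must be >= 1 Hz")
  if (!is.null(trial)) {
    speed_kmh <- speed_kmh %||% trial$comparison_speed
    tta_s <- tta_s %||% trial$comparison_tta
    approach_side <- approach_side %||% as.character(trial$approach_side)
  }
  approach_side <- approach_side %||% "right"
  v <- kmh_to_ms(speed_kmh)
  d0 <- start_distance(v, tta_s, scene$display_duration)
  if (d0 - v * scene$display_duration <= 0)
    stop("infeasible trial: vehicle would cross the stopping line before ",
         "display offset")
  dur <- scene$display_duration + scene$post_offset_duration
  times <- seq(0, dur - 1 / sample_rate, by = 1 / sample_rate)
  d <- d0 - v * times
  visible <- times < scene$display_duration
  sgn <- if (identical(approach_side, "left")) -1 else 1
  world <- cbind(
    x = rep(sgn * scene$lane_offset, length(times)),
    y = d,
    z = rep(scene$vehicle_height / 2 - scene$eye_height, length(times))
  )
  structure(list(times = times, distance = d, world = world,
                 visible = visible, speed_ms = v,
                 approach_side = approach_side,
                 sample_rate = sample_rate),
            class = "trajectory")
}

#' Randomized trial list for one session
#'
#' Three (by default) test blocks, each displaying all 81 speed x TTA
#' combinations of the comparison stimulus in seeded-random order. The
#' order of the standard and comparison interval is randomized per trial;
#' the approach side alternates between trials but is identical for the two
#' intervals of a trial.
#'
#' @param grid a [design_grid()].
#' @param participant_id participant label.
#' @param task `"speed"` or `"tta"`.
#' @param seed integer seed for the randomization.
#' @return A tibble with one row per trial (class `trial_spec` columns).
#' @export
make_design <- function(grid = design_grid(), participant_id = "P01",
                        task = c("speed", "tta"), seed = 1) {
  task <- match.arg(task)
  set.seed(seed)
  cells <- expand.grid(comparison_speed = grid$speed_levels,
                       comparison_tta = grid$tta_levels,
                       KEEP.OUT.ATTRS = FALSE)
  blocks <- lapply(seq_len(grid$n_blocks), function(b) {
    ord <- sample.int(nrow(cells))
    cbind(block = b, cells[ord, , drop = FALSE])
  })
  out <- do.call(rbind, blocks)
  n <- nrow(out)
  out$participant_id <- participant_id
  out$task <- task
  out$trial_index <- seq_len(n)
  out$standard_first <- sample(c(TRUE, FALSE), n, replace = TRUE)
  out$approach_side <- rep_len(c("right", "left"), n)
  rownames(out) <- NULL
  tibble::as_tibble(out[, c("participant_id", "task", "block", "trial_index",
                            "comparison_speed", "comparison_tta",
                            "standard_first", "approach_side")])
}
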