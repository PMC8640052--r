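#' Saccade detector configuration
#'
#' Velocity/acceleration threshold detector with a pursuit-adaptive
#' velocity criterion: a trailing moving average of (non-saccadic) gaze
#' speed over `pursuit_window` ms is added to the velocity threshold, the
#' sum being capped at `fixup_limit`.
#'
#' @param velocity_threshold deg/s.
#' @param acceleration_threshold deg/s^2.
#' @param pursuit_window trailing-average window, ms.
#' @param fixup_limit cap on the adaptive velocity criterion, deg/s.
#' @param min_duration_ms minimum saccade duration retained.
#' @param max_duration_ms candidates longer than this are reclassified as
#'   pursuit.
#' @param merge_gap_ms events closer than this are merged.
#' @return `detector_config` object.
#' @export
detector_config <- function(velocity_threshold = 22,
                            acceleration_threshold = 5000,
                            pursuit_window = 40,
                            fixup_limit = 60,
                            min_duration_ms = 6,
                            max_duration_ms = 150,
                            merge_gap_ms = 20) {
  stopifnot(velocity_threshold > 0, acceleration_threshold > 0,
            pursuit_window > 0, fixup_limit >= velocity_threshold)
  structure(as.list(environment()), class = "detector_config")
}

gaze_speed <- function(x, y, fs) {
  n <- length(x)
  vx <- vy <- numeric(n)
  idx <- 2:(n - 1)
  vx[idx] <- (x[idx + 1] - x[idx - 1]) * fs / 2
  vy[idx] <- (y[idx + 1] - y[idx - 1]) * fs / 2
  vx[1] <- (x[2] - x[1]) * fs; vy[1] <- (y[2] - y[1]) * fs
  vx[n] <- (x[n] - x[n - 1]) * fs; vy[n] <- (y[n] - y[n - 1]) * fs
  list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

#' Detect saccades by velocity and acceleration thresholds
#'
#' A sample opens a saccade when the instantaneous 2D gaze speed exceeds
#' `velocity_threshold` plus the (capped) trailing mean speed over the
#' pursuit window, or when the acceleration magnitude exceeds
#' `acceleration_threshold`; the saccade closes when both fall back below.
#' The trailing average is taken over non-saccadic samples only. Events
#' shorter than `min_duration_ms` are dropped, longer than
#' `max_duration_ms` are reclassified as pursuit, and events separated by
#' less than `merge_gap_ms` are merged. Amplitude is the great-circle
#' angle between onset and offset gaze directions.
#'
#' @param trace a `gaze_trace` (needs uniform `t_ms` sampling).
#' @param cfg a [detector_config()].
#' @param scene a [scene_config()] used to back-project screen positions.
#' @return List of class `event_labels` with data frames `saccades`
#'   (onset_ms, offset_ms, amplitude, direction) and `blinks`.
#' @export
detect_saccades <- function(trace, cfg = detector_config(),
                            scene = scene_config()) {
  s <- trace$samples
  t <- s$t_ms
  dts <- diff(t)
  if (length(dts) < 2 || max(abs(dts - dts[1])) > 1e-6 * max(1, dts[1]))
    stop("detect_saccades: non-uniform timestamps")
  fs <- 1000 / dts[1]
  if (length(t) * dts[1] < 50) stop("detect_saccades: need >= 50 ms of data")
  gs <- gaze_speed(s$gaze_x, s$gaze_y, fs)
  n <- length(t)
  ax <- c(0, diff(gs$vx)) * fs
  ay <- c(0, diff(gs$vy)) * fs
  accel <- sqrt(ax^2 + ay^2)
  w <- max(1L, as.integer(round(cfg$pursuit_window / 1000 * fs)))

  insac <- logical(n)
  open <- FALSE; onset <- 0L
  events <- list()
  for (i in seq_len(n)) {
    lo <- max(1L, i - w); hi <- i - 1L
    trail <- if (hi >= lo) {
      sp <- gs$speed[lo:hi][!insac[lo:hi]]
      if (length(sp)) mean(sp) else 0
    } else 0
    vthr <- cfg$velocity_threshold +
      min(cfg$fixup_limit - cfg$velocity_threshold, trail)
    hit <- gs$speed[i] > vthr || accel[i] > cfg$acceleration_threshold
    if (!open && hit) {
      open <- TRUE; onset <- i; insac[i] <- TRUE
    } else if (open && hit) {
      insac[i] <- TRUE
      if ((i - onset) / fs * 1000 > cfg$max_duration_ms) {
        insac[onset:i] <- FALSE   # too long: pursuit, not a saccade
        open <- FALSE
      }
    } else if (open && !hit) {
      open <- FALSE
      events[[length(events) + 1]] <- c(onset, i - 1L)
    }
  }
  if (open) events[[length(events) + 1]] <- c(onset, n)

  if (length(events)) {
    ev <- do.call(rbind, events)
    # merge events separated by < merge_gap_ms
    merged <- list(ev[1, ])
    if (nrow(ev) > 1) for (k in 2:nrow(ev)) {
      last <- merged[[length(merged)]]
      if ((ev[k, 1] - last[2]) / fs * 1000 < cfg$merge_gap_ms)
        merged[[length(merged)]] <- c(last[1], ev[k, 2])
      else merged[[length(merged) + 1]] <- ev[k, ]
    }
    ev <- do.call(rbind, merged)
    dur_ms <- (ev[, 2] - ev[, 1]) / fs * 1000
    keep <- dur_ms >= cfg$min_duration_ms & dur_ms <= cfg$max_duration_ms
    ev <- ev[keep, , drop = FALSE]
  } else ev <- matrix(integer(0), 0, 2)

  if (nrow(ev)) {
    dirs <- screen_eye_direction(cbind(s$gaze_x, s$gaze_y), scene)
    amp <- dir <- numeric(nrow(ev))
    for (k in seq_len(nrow(ev))) {
      i0 <- ev[k, 1]; i1 <- ev[k, 2]
      cosang <- sum(dirs[i0, ] * dirs[i1, ])
      amp[k] <- acos(pmin(1, pmax(-1, cosang))) * DEG
      dir[k] <- atan2(s$gaze_y[i1] - s$gaze_y[i0],
                      s$gaze_x[i1] - s$gaze_x[i0]) * DEG
    }
    sac <- data.frame(onset_ms = t[ev[, 1]], offset_ms = t[ev[, 2]],
                      amplitude = amp, direction = dir)
  } else {
    sac <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude = numeric(0), direction = numeric(0))
  }
  structure(list(saccades = sac,
                 blinks = data.frame(onset_ms = numeric(0),
                                     offset_ms = numeric(0))),
            class = "event_labels")
}

#' Detect blinks from pupil validity
#'
#' Maximal runs of invalid pupil samples, padded by `pad_ms` on each side;
#' runs whose padded windows touch are merged.
#'
#' @param trace a `gaze_trace`.
#' @param pad_ms padding in ms.
#' @return `event_labels` with the `blinks` data frame filled.
#' @export
detect_blinks <- function(trace, pad_ms = 20) {
  s <- trace$samples
  r <- rle(!s$pupil_valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- starts[r$values]; off <- ends[r$values]
  if (length(on)) {
    t0 <- pmax(s$t_ms[1], s$t_ms[on] - pad_ms)
    t1 <- pmin(s$t_ms[length(s$t_ms)], s$t_ms[off] + pad_ms)
    # merge overlapping padded runs
    keep_on <- t0[1]; keep_off <- t1[1]
    if (length(on) > 1) for (k in 2:length(on)) {
      if (t0[k] <= keep_off[length(keep_off)]) {
        keep_off[length(keep_off)] <- max(keep_off[length(keep_off)], t1[k])
      } else {
        keep_on <- c(keep_on, t0[k]); keep_off <- c(keep_off, t1[k])
      }
    }
    bl <- data.frame(onset_ms = keep_on, offset_ms = keep_off)
  } else bl <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0))
  structure(list(saccades = data.frame(onset_ms = numeric(0),
                                       offset_ms = numeric(0),
                                       amplitude = numeric(0),
                                       direction = numeric(0)),
                 blinks = bl),
            class = "event_labels")
}

#' Merge two event-label sets
#' @param a,b `event_labels`.
#' @return Combined `event_labels`.
#' @export
merge_events <- function(a, b) {
  structure(list(saccades = rbind(a$saccades, b$saccades),
                 blinks = rbind(a$blinks, b$blinks)),
            class = "event_labels")
}

#' Remove saccade/blink samples and interpolate linearly
#'
#' Samples inside any saccade or blink window are replaced by linear
#' interpolation between the flanking valid samples; leading/trailing gaps
#' are filled with the nearest valid value. The operation is idempotent.
#'
#' @param trace a `gaze_trace`.
#' @param events `event_labels` detected on the same trace.
#' @return List with the cleaned `trace` and the `interpolated_fraction`.
#' @export
clean_trace <- function(trace, events) {
  s <- trace$samples
  bad <- rep(FALSE, nrow(s))
  win <- rbind(events$saccades[, c("onset_ms", "offset_ms")],
               events$blinks[, c("onset_ms", "offset_ms")])
  if (nrow(win)) for (k in seq_len(nrow(win)))
    bad <- bad | (s$t_ms >= win$onset_ms[k] & s$t_ms <= win$offset_ms[k])
  if (all(bad)) stop("clean_trace: no valid samples left")
  frac <- mean(bad)
  if (any(bad)) {
    good_t <- s$t_ms[!bad]
    for (col in c("gaze_x", "gaze_y")) {
      s[[col]][bad] <- approx(good_t, s[[col]][!bad], xout = s$t_ms[bad],
                              rule = 2)$y
    }
  }
  out <- trace
  out$samples <- s
  out$cleaned <- TRUE
  out$interpolated <- bad
  list(trace = out, interpolated_fraction = frac)
}

#' Apply the trial and participant exclusion rules
#'
#' Drops trials whose interpolated fraction exceeds `trial_threshold` in
#' either interval, then drops a participant from a task condition when
#' the excluded trials exceed `participant_threshold` of that condition's
#' trials.
#'
#' @param fractions data frame with columns `participant_id`, `task`,
#'   `trial_id`, `interval`, `interpolated_fraction`.
#' @param trial_threshold,participant_threshold exclusion fractions.
#' @return List: `kept` (trial ids), `report` (class `cleaning_report`
#'   with `excluded_trials` and `excluded_participants`).
#' @export
apply_exclusions <- function(fractions, trial_threshold = 0.5,
                             participant_threshold = 0.5) {
  stopifnot(all(fractions$interpolated_fraction >= 0),
            all(fractions$interpolated_fraction <= 1))
  by_trial <- aggregate(interpolated_fraction ~ participant_id + task +
                          trial_id, data = fractions, FUN = max)
  drop <- by_trial$interpolated_fraction > trial_threshold
  excluded_trials <- by_trial$trial_id[drop]
  excl_part <- character(0)
  for (pt in unique(paste(by_trial$participant_id, by_trial$task))) {
    sel <- paste(by_trial$participant_id, by_trial$task) == pt
    if (mean(drop[sel]) > participant_threshold)
      excl_part <- c(excl_part, pt)
  }
  kept <- by_trial$trial_id[!drop &
    !(paste(by_trial$participant_id, by_trial$task) %in% excl_part)]
  report <- structure(list(
    excluded_trials = data.frame(
      trial_id = excluded_trials,
      reason = rep("interpolated_fraction > threshold",
                   length(excluded_trials))),
    excluded_participants = excl_part,
    n_trials = nrow(by_trial),
    n_excluded = sum(drop)), class = "cleaning_report")
  list(kept = kept, report = report)
}
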