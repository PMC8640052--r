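#' Gaze-metric configuration
#'
#' @param gain_window averaging window (s from interval onset) for pursuit
#'   gain and position deviations used in descriptive/classification
#'   analyses; the last second before vehicle offset.
#' @param full_window full visible interval, used for the performance
#'   model's predictors.
#' @param butterworth_order,butterworth_cutoff low-pass filter applied to
#'   the angular-velocity series (zero-phase), cutoff in Hz.
#' @return `metrics_config` object.
#' @export
metrics_config <- function(gain_window = c(2, 3),
                           full_window = c(0, 3),
                           butterworth_order = 2,
                           butterworth_cutoff = 10) {
  structure(as.list(environment()), class = "metrics_config")
}

#' 3D angular velocity of a direction series
#'
#' Instantaneous rotation rate from the cross product of consecutive unit
#' direction vectors: `asin(||u_i x u_{i+1}||) / dt`, in deg/s. The last
#' value is repeated so the series has the input length.
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param dt sample interval in s.
#' @return Numeric vector of deg/s.
#' @export
angular_velocity_3d <- function(dirs, dt) {
  if (any(rowSums(dirs^2) == 0)) stop("zero direction vector")
  n <- nrow(dirs)
  a <- dirs[-n, , drop = FALSE]
  b <- dirs[-1, , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  s <- pmin(1, sqrt(cx^2 + cy^2 + cz^2))
  w <- asin(s) / dt * DEG
  c(w, w[length(w)])
}

butter_lp <- function(x, fs, order, cutoff) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# rotation-rate vector between consecutive unit directions (deg/s, n x 3);
# filtering its signed components before taking magnitudes lets zero-mean
# measurement noise cancel instead of rectifying into the speed estimate
angular_velocity_vec <- function(dirs, dt) {
  n <- nrow(dirs)
  a <- dirs[-n, , drop = FALSE]
  b <- dirs[-1, , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  s <- pmin(1, sqrt(rowSums(cr^2)))
  scale <- ifelse(s > 0, asin(s) / pmax(s, 1e-300), 1) / dt * DEG
  w <- cr * scale
  rbind(w, w[nrow(w), , drop = FALSE])
}

#' Pursuit gain over an averaging window
#'
#' Gaze and target screen paths are back-projected to 3D direction
#' vectors; angular velocity comes from the cross product of consecutive
#' directions. The signed rotation-rate components are low-pass filtered
#' (zero-phase Butterworth) before the speed magnitudes are formed, and
#' gain is the ratio of the window means (robust to near-zero
#' instantaneous target velocity).
#'
#' @param trace a cleaned `gaze_trace` (saccades interpolated out).
#' @param target n x 2 target screen path (defaults to the trace's own).
#' @param cfg a [metrics_config()].
#' @param scene a [scene_config()].
#' @param window override averaging window (s).
#' @param min_target_speed deg/s; below this window-mean target speed the
#'   gain is undefined and NA is returned.
#' @param exclude_pad_s interpolated (saccade/blink) samples, padded by
#'   this many seconds to absorb filter smearing, are excluded from the
#'   window averages so interpolation ramps do not masquerade as pursuit.
#' @return Scalar gain, or NA (undefined-gain marker).
#' @export
pursuit_gain <- function(trace, target = trace$target,
                         cfg = metrics_config(), scene = scene_config(),
                         window = cfg$gain_window,
                         min_target_speed = 0.1,
                         exclude_pad_s = 0.06) {
  s <- trace$samples
  fs <- trace$fs
  gdir <- screen_to_direction(cbind(s$gaze_x, s$gaze_y), scene)
  tdir <- screen_to_direction(target, scene)
  wg <- apply(angular_velocity_vec(gdir, 1 / fs), 2, butter_lp, fs = fs,
              order = cfg$butterworth_order,
              cutoff = cfg$butterworth_cutoff)
  wt <- apply(angular_velocity_vec(tdir, 1 / fs), 2, butter_lp, fs = fs,
              order = cfg$butterworth_order,
              cutoff = cfg$butterworth_cutoff)
  t_s <- s$t_ms / 1000
  idx <- t_s >= window[1] & t_s < window[2]
  if (!is.null(trace$interpolated)) {
    bad <- trace$interpolated
    w <- max(1L, as.integer(round(exclude_pad_s * fs)))
    bad <- as.logical(stats::filter(as.numeric(bad), rep(1, 2 * w + 1),
                                    sides = 2))
    bad[is.na(bad)] <- TRUE
    idx <- idx & !bad
  }
  if (!any(idx)) return(NA_real_)
  wt_i <- wt[idx, , drop = FALSE]
  wg_i <- wg[idx, , drop = FALSE]
  tspeed <- sqrt(rowSums(wt_i^2))
  mt <- mean(tspeed)
  if (!is.finite(mt) || mt < min_target_speed) return(NA_real_)
  # signed gaze speed: component of the gaze rotation rate along the
  # target's instantaneous rotation axis, so zero-mean tracker noise
  # averages out instead of rectifying into the numerator
  axis <- wt_i / pmax(tspeed, 1e-12)
  mean(rowSums(wg_i * axis)) / mt
}

#' Gaze position deviation from the vehicle AOI center
#'
#' Relative deviations keep the sign (horizontal sign flipped for
#' leftward-moving vehicles so that positive always means "ahead of the
#' AOI center, in the motion direction"; positive vertical means above);
#' absolute deviations average the magnitudes.
#'
#' @param trace a `gaze_trace`.
#' @param target n x 2 AOI-center screen path.
#' @param window averaging window in s.
#' @return Named vector `rel_h, rel_v, abs_h, abs_v` (deg).
#' @export
position_deviation <- function(trace, target = trace$target,
                               window = c(2, 3)) {
  s <- trace$samples
  t_s <- s$t_ms / 1000
  idx <- which(t_s >= window[1] & t_s < window[2])
  if (!length(idx)) stop("position_deviation: empty window")
  dx <- s$gaze_x[idx] - target[idx, 1]
  dy <- s$gaze_y[idx] - target[idx, 2]
  # horizontal motion direction of the target on screen within the window
  tx <- target[idx, 1]
  motion_sign <- sign(tx[length(tx)] - tx[1])
  if (motion_sign == 0) motion_sign <- 1
  c(rel_h = mean(dx) * motion_sign, rel_v = mean(dy),
    abs_h = mean(abs(dx)), abs_v = mean(abs(dy)))
}

#' Saccade counts and mean amplitude for one interval
#'
#' The first saccade after vehicle onset is removed before counting and
#' averaging. Saccades whose endpoint lands inside the crossing AOI are
#' counted separately before and after vehicle offset.
#'
#' @param events `event_labels` for the interval.
#' @param trace the `gaze_trace` (for landing positions).
#' @param crossing an `aoi_box` from [crossing_aoi()].
#' @param vehicle_offset_time s; split point for the crossing counts.
#' @return Named vector `n_saccades, mean_amplitude, n_sacc_crossing_before,
#'   n_sacc_crossing_after`.
#' @export
saccade_stats <- function(events, trace = NULL, crossing = NULL,
                          vehicle_offset_time = 3) {
  sac <- events$saccades
  sac <- sac[order(sac$onset_ms), , drop = FALSE]
  counted <- if (nrow(sac) >= 1) sac[-1, , drop = FALSE] else sac
  n_cross_before <- n_cross_after <- 0L
  if (!is.null(crossing) && !is.null(trace) && nrow(sac)) {
    s <- trace$samples
    for (k in seq_len(nrow(sac))) {
      i1 <- which.min(abs(s$t_ms - sac$offset_ms[k]))
      inside <- abs(s$gaze_x[i1] - crossing$center[1, 1]) <= crossing$half_w &&
        abs(s$gaze_y[i1] - crossing$center[1, 2]) <= crossing$half_h
      if (inside) {
        if (sac$offset_ms[k] / 1000 < vehicle_offset_time)
          n_cross_before <- n_cross_before + 1L
        else n_cross_after <- n_cross_after + 1L
      }
    }
  }
  c(n_saccades = nrow(counted),
    mean_amplitude = if (nrow(counted)) mean(counted$amplitude) else NA_real_,
    n_sacc_crossing_before = n_cross_before,
    n_sacc_crossing_after = n_cross_after)
}

#' MAD / double-MAD outlier filter
#'
#' Symmetric criterion: flag `|x - median| / (c * MAD) > symmetric_cutoff`
#' with consistency constant c = 1.4826. Asymmetric (double-MAD, for
#' skewed metrics such as saccade counts and amplitudes): separate MADs
#' for values below and above the median, each side flagged beyond
#' `asymmetric_cutoff`. A zero MAD on a side disables removals there (with
#' a warning).
#'
#' @param values numeric vector (>= 3 finite values).
#' @param asymmetric use the double-MAD criterion?
#' @param symmetric_cutoff,asymmetric_cutoff flag thresholds.
#' @param mad_constant consistency constant.
#' @return Logical keep-mask (TRUE = keep).
#' @export
mad_outlier_filter <- function(values, asymmetric = FALSE,
                               symmetric_cutoff = 3.5,
                               asymmetric_cutoff = 4.5,
                               mad_constant = 1.4826) {
  x <- values
  fin <- is.finite(x)
  if (sum(fin) < 3) stop("mad_outlier_filter: need >= 3 finite values")
  med <- median(x[fin])
  keep <- rep(TRUE, length(x))
  if (!asymmetric) {
    m <- median(abs(x[fin] - med))
    if (m == 0) {
      warning("MAD is zero; no outliers flagged")
      return(keep)
    }
    keep[fin] <- abs(x[fin] - med) / (mad_constant * m) <= symmetric_cutoff
  } else {
    lo <- x[fin][x[fin] <= med]; hi <- x[fin][x[fin] >= med]
    m_lo <- median(abs(lo - med)); m_hi <- median(abs(hi - med))
    score <- rep(0, length(x))
    below <- fin & x < med; above <- fin & x > med
    if (m_lo == 0 && any(below)) warning("lower MAD is zero; side skipped")
    else score[below] <- abs(x[below] - med) / (mad_constant * m_lo)
    if (m_hi == 0 && any(above)) warning("upper MAD is zero; side skipped")
    else score[above] <- abs(x[above] - med) / (mad_constant * m_hi)
    keep <- score <= asymmetric_cutoff
    keep[!fin] <- TRUE
  }
  keep
}

#' Per-trial gaze metrics for one interval
#'
#' Runs detection, cleaning and the nine feature computations (pursuit
#' gain, relative/absolute horizontal and vertical deviations, saccade
#' count and mean amplitude, crossing-AOI saccade counts) for a single
#' gaze trace, for one or both averaging windows.
#'
#' @param trace a `gaze_trace`.
#' @param scene a [scene_config()].
#' @param cfg a [metrics_config()].
#' @param det a [detector_config()].
#' @param windows named list of averaging windows.
#' @return A tibble with one row per window and the feature columns, plus
#'   `interpolated_fraction`.
#' @export
trial_gaze_metrics <- function(trace, scene = scene_config(),
                               cfg = metrics_config(),
                               det = detector_config(),
                               windows = list(feature = cfg$gain_window,
                                              full = cfg$full_window)) {
  ev <- merge_events(detect_saccades(trace, det, scene),
                     detect_blinks(trace))
  cl <- clean_trace(trace, ev)
  cross <- crossing_aoi(scene, trace$approach_side %||% "right")
  sstats <- saccade_stats(ev, trace, cross,
                          vehicle_offset_time = scene$display_duration)
  rows <- lapply(names(windows), function(wname) {
    w <- windows[[wname]]
    g <- pursuit_gain(cl$trace, trace$target, cfg, scene, window = w)
    dev <- position_deviation(cl$trace, trace$target, window = w)
    tibble::tibble(
      trial_id = trace$trial_id, interval = trace$interval,
      participant_id = trace$participant_id,
      task = trace$task %||% NA_character_,
      window = wname,
      gain = g, rel_dev_h = dev[["rel_h"]], rel_dev_v = dev[["rel_v"]],
      abs_dev_h = dev[["abs_h"]], abs_dev_v = dev[["abs_v"]],
      n_saccades = sstats[["n_saccades"]],
      mean_amplitude = sstats[["mean_amplitude"]],
      n_sacc_crossing_before = sstats[["n_sacc_crossing_before"]],
      n_sacc_crossing_after = sstats[["n_sacc_crossing_after"]],
      interpolated_fraction = cl$interpolated_fraction)
  })
  do.call(rbind, rows)
}

#' Gaze metrics for a whole dataset
#'
#' @param dataset a `crossgaze_dataset` with gaze traces.
#' @param ... passed to [trial_gaze_metrics()].
#' @return A tibble of per-trial-interval metrics.
#' @export
compute_gaze_metrics <- function(dataset, ...) {
  out <- lapply(dataset$traces, trial_gaze_metrics,
                scene = dataset$scene, ...)
  do.call(rbind, out)
}

gaze_feature_names <- function() {
  c("gain", "rel_dev_h", "rel_dev_v", "abs_dev_h", "abs_dev_v",
    "n_saccades", "mean_amplitude",
    "n_sacc_crossing_before", "n_sacc_crossing_after")
}
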