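#' Parameters of a synthetic observer
#'
#' A synthetic observer couples a gaze model (smooth pursuit at a sampled
#' gain plus catch-up and spontaneous saccades, blinks, and fixation noise)
#' with a noisy internal-estimate decision model for the 2IFC judgements.
#'
#' Cue weights are given per task because the two sessions judge different
#' internal dimensions ("faster" vs "earlier"); a negative TTA weight makes
#' larger internal estimates mean "arrives earlier". The defaults are
#' illustrative values producing roadside-plausible behaviour, not
#' estimates from any dataset.
#'
#' @param participant_id label carried into generated data.
#' @param pursuit_gain_mean,pursuit_gain_sd per-trial pursuit gain is drawn
#'   from Normal(mean, sd).
#' @param fixation_noise_sd per-sample Gaussian measurement noise, deg.
#' @param catchup_threshold position error (deg) that triggers a catch-up
#'   saccade.
#' @param saccade_amplitude_noise_sd landing-point noise, deg.
#' @param saccade_rate_bias rate (Hz) of spontaneous re-centering saccades
#'   on top of error-triggered ones.
#' @param spontaneous_amp_sd dispersion (deg) of spontaneous saccade
#'   landing points around the target.
#' @param error_correction_gain slow position servo (1/s) pulling gaze back
#'   toward the target between saccades; set 0 for a pure velocity tracker.
#' @param gaze_offset c(h, v): the observer's habitual gaze placement
#'   relative to the AOI center, in deg; h is "ahead" along the motion
#'   direction, v is up. Idiosyncratic and stable within an observer.
#' @param blink_rate Poisson blink rate, Hz.
#' @param cue_weights list with elements `speed` and `tta`, each a named
#'   vector of weights over `c(speed, tta, start, end)` applied to z-scored
#'   cues.
#' @param internal_noise_sd SD of the Gaussian noise added to each
#'   interval's internal estimate (z-scored cue units).
#' @param lapse_prob probability of a uniform guess.
#' @param second_interval_bias constant added to the second interval's
#'   internal estimate (positive reproduces a second-interval preference).
#' @param seed observer-level seed.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(participant_id = "P01",
                            pursuit_gain_mean = 0.9,
                            pursuit_gain_sd = 0.05,
                            fixation_noise_sd = 0.008,
                            catchup_threshold = 1.0,
                            saccade_amplitude_noise_sd = 0.1,
                            saccade_rate_bias = 1.0,
                            spontaneous_amp_sd = 0.6,
                            error_correction_gain = 0.1,
                            gaze_offset = c(h = 0.5, v = 0.7),
                            blink_rate = 0.15,
                            cue_weights = list(
                              speed = c(speed = 1, tta = -0.15,
                                        start = 0.25, end = 0.25),
                              tta = c(speed = 0.1, tta = -1,
                                      start = -0.25, end = -0.35)),
                            internal_noise_sd = 0.95,
                            lapse_prob = 0.02,
                            second_interval_bias = 0.1,
                            seed = 1) {
  stopifnot(lapse_prob >= 0, lapse_prob <= 1,
            pursuit_gain_sd >= 0, fixation_noise_sd >= 0,
            internal_noise_sd >= 0, blink_rate >= 0)
  if (all(unlist(cue_weights) == 0))
    stop("at least one cue weight must be nonzero")
  structure(as.list(environment()), class = "observer_params")
}

#' A cohort of synthetic observers with idiosyncratic gaze parameters
#'
#' Draws per-participant gaze parameters around roadside-plausible group
#' values (pursuit gain ~ 0.87, two to three counted saccades per interval
#' with amplitudes near 1 deg), so that observers are mutually
#' distinguishable while the two tasks share generative parameters.
#'
#' @param n number of observers.
#' @param seed cohort seed.
#' @param distinct_observers if FALSE all observers share identical gaze
#'   parameters (used for null checks).
#' @return List of [observer_params()].
#' @export
default_observer_cohort <- function(n = 15, seed = 1,
                                    distinct_observers = TRUE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    if (distinct_observers) {
      observer_params(
        participant_id = sprintf("P%02d", i),
        pursuit_gain_mean = min(1.1, max(0.55, rnorm(1, 0.87, 0.1))),
        fixation_noise_sd = runif(1, 0.004, 0.012),
        saccade_rate_bias = runif(1, 0.4, 1.6),
        spontaneous_amp_sd = runif(1, 0.4, 0.9),
        gaze_offset = c(h = rnorm(1, 0.5, 0.3), v = rnorm(1, 0.7, 0.5)),
        internal_noise_sd = exp(rnorm(1, log(0.95), 0.2)),
        second_interval_bias = rnorm(1, 0.1, 0.05),
        seed = seed * 1000L + i)
    } else {
      observer_params(participant_id = sprintf("P%02d", i),
                      seed = seed * 1000L + i)
    }
  })
}

min_jerk <- function(s) s^3 * (10 - 15 * s + 6 * s^2)

#' Simulate a gaze trace for one interval
#'
#' Gaze follows the projected vehicle-AOI center with a per-trial velocity
#' gain; position error accumulates and, when it exceeds
#' `catchup_threshold`, a ballistic catch-up saccade (minimum-jerk profile,
#' duration 20 ms + 2 ms/deg) is injected and logged in the ground truth.
#' Spontaneous re-centering saccades occur at `saccade_rate_bias` Hz.
#' Blinks are Poisson events of 100-300 ms zeroing pupil validity.
#' Gaussian fixation noise is added per sample.
#'
#' @param trial one-row trial spec (or NULL with `traj`).
#' @param traj a [trajectory()] covering the full interval.
#' @param params an [observer_params()].
#' @param scene a [scene_config()].
#' @param seed integer seed.
#' @param interval `"standard"` or `"comparison"` (metadata only).
#' @param trial_id identifier carried in the trace.
#' @return A list of class `gaze_trace`: `samples` (tibble t_ms, gaze_x,
#'   gaze_y, pupil_valid), `target` (screen path), `truth` (event labels),
#'   `fs`, plus trial metadata.
#' @export
simulate_gaze <- function(trial = NULL, traj, params, scene = scene_config(),
                          seed = 1, interval = "comparison",
                          trial_id = "trial") {
  set.seed(seed)
  fs <- traj$sample_rate
  dt <- 1 / fs
  target <- aoi_center_path(traj, scene)
  n <- nrow(target)
  g_trial <- rnorm(1, params$pursuit_gain_mean, params$pursuit_gain_sd)
  kp <- params$error_correction_gain
  # habitual gaze placement: ahead of the AOI center along the motion
  # direction and above it, idiosyncratic per observer
  n_vis <- max(2L, sum(traj$visible))
  motion_sign <- sign(target[n_vis, 1] - target[1, 1])
  if (motion_sign == 0) motion_sign <- 1
  off <- params$gaze_offset %||% c(h = 0, v = 0)
  aim <- cbind(target[, 1] + motion_sign * off[[1]], target[, 2] + off[[2]])

  gaze <- matrix(0, n, 2)
  gaze[1, ] <- aim[1, ]
  truth_sac <- list(); truth_blink <- list()

  # scheduled saccade state
  sac_end_i <- 0L; sac_start_i <- 0L
  sac_from <- c(0, 0); sac_to <- c(0, 0)

  # spontaneous saccade and blink event times (sample indices)
  spont <- integer(0)
  if (params$saccade_rate_bias > 0) {
    tt <- cumsum(rexp(ceiling(params$saccade_rate_bias * n * dt) + 20,
                      params$saccade_rate_bias))
    spont <- unique(pmax(2L, as.integer(round(tt[tt < n * dt] * fs))))
  }
  blink_on <- integer(0); blink_off <- integer(0)
  if (params$blink_rate > 0) {
    tb <- cumsum(rexp(ceiling(params$blink_rate * n * dt) + 20,
                      params$blink_rate))
    tb <- tb[tb < n * dt]
    for (b in tb) {
      i0 <- as.integer(round(b * fs))
      i1 <- min(n, i0 + as.integer(round(runif(1, 0.1, 0.3) * fs)))
      if (i0 >= 1 && i0 < n) {
        blink_on <- c(blink_on, i0); blink_off <- c(blink_off, i1)
      }
    }
  }

  launch <- function(i, to) {
    amp <- sqrt(sum((to - gaze[i - 1, ])^2))
    dur_s <- 0.020 + 0.002 * amp
    sac_start_i <<- i
    sac_end_i <<- i + max(1L, as.integer(round(dur_s * fs)))
    sac_from <<- gaze[i - 1, ]
    sac_to <<- to
    truth_sac[[length(truth_sac) + 1]] <<- c(
      onset_ms = (i - 1) * dt * 1000,
      offset_ms = (min(sac_end_i, n) - 1) * dt * 1000,
      amplitude = amp,
      direction = unname(atan2(to[2] - gaze[i - 1, 2],
                               to[1] - gaze[i - 1, 1])) * DEG)
  }

  refractory <- as.integer(round(0.15 * fs))  # saccadic refractory period
  for (i in 2:n) {
    if (i <= sac_end_i) {
      s <- min_jerk((i - sac_start_i) / (sac_end_i - sac_start_i))
      gaze[i, ] <- sac_from + s * (sac_to - sac_from)
      next
    }
    vt <- (target[i, ] - target[i - 1, ]) * fs
    err_prev <- aim[i - 1, ] - gaze[i - 1, ]
    gaze[i, ] <- gaze[i - 1, ] + (g_trial * vt + kp * err_prev) * dt
    err <- aim[i, ] - gaze[i, ]
    may_launch <- i > sac_end_i + refractory
    if (may_launch && sqrt(sum(err^2)) > params$catchup_threshold) {
      to <- aim[i, ] + rnorm(2, 0, params$saccade_amplitude_noise_sd)
      launch(i, to)
    } else if (may_launch && i %in% spont) {
      to <- aim[i, ] + rnorm(2, 0, params$spontaneous_amp_sd)
      launch(i, to)
    }
  }

  pupil_valid <- rep(TRUE, n)
  for (b in seq_along(blink_on)) {
    idx <- blink_on[b]:blink_off[b]
    pupil_valid[idx] <- FALSE
    truth_blink[[length(truth_blink) + 1]] <- c(
      onset_ms = (blink_on[b] - 1) * dt * 1000,
      offset_ms = (blink_off[b] - 1) * dt * 1000)
  }

  noisy <- gaze + matrix(rnorm(2 * n, 0, params$fixation_noise_sd), n, 2)
  samples <- tibble::tibble(
    t_ms = round((seq_len(n) - 1) * dt * 1000, 6),
    gaze_x = noisy[, 1], gaze_y = noisy[, 2],
    pupil_valid = pupil_valid)
  truth <- list(
    saccades = if (length(truth_sac))
      as.data.frame(do.call(rbind, truth_sac)) else
        data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                   amplitude = numeric(0), direction = numeric(0)),
    blinks = if (length(truth_blink))
      as.data.frame(do.call(rbind, truth_blink)) else
        data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  structure(list(trial_id = trial_id, interval = interval,
                 participant_id = params$participant_id,
                 task = if (!is.null(trial)) trial$task else NA_character_,
                 fs = fs, samples = samples, target = target,
                 truth = truth, gain_true = g_trial),
            class = "gaze_trace")
}

grid_cues <- function(grid, scene = scene_config()) {
  cells <- expand.grid(speed = grid$speed_levels, tta = grid$tta_levels,
                       KEEP.OUT.ATTRS = FALSE)
  v <- kmh_to_ms(cells$speed)
  cells$start <- v * (scene$display_duration + cells$tta)
  cells$end <- v * cells$tta
  cells
}

cue_scaler <- function(grid, scene = scene_config()) {
  cells <- grid_cues(grid, scene)
  mu <- vapply(cells, mean, 0)
  sdv <- vapply(cells, sd, 0)
  function(speed, tta) {
    v <- kmh_to_ms(speed)
    x <- cbind(speed = speed, tta = tta,
               start = v * (scene$display_duration + tta),
               end = v * tta)
    sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  }
}

#' Noisy internal estimate of one interval's stimulus
#'
#' Weighted sum of the z-scored cues (speed, TTA, start and end distance,
#' standardized over the 81-cell design grid) plus Gaussian internal noise.
#'
#' @param cues_z length-4 named numeric of z-scored cues, e.g. a row from
#'   the scaler built by the generator.
#' @param params an [observer_params()].
#' @param task `"speed"` or `"tta"` (selects the weight map).
#' @param seed optional seed.
#' @return Scalar internal estimate.
#' @export
internal_estimate <- function(cues_z, params, task = "speed", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- params$cue_weights[[task]]
  sum(w * cues_z[names(w)]) + rnorm(1, 0, params$internal_noise_sd)
}

#' Simulate the 2IFC choices for a session's trial list
#'
#' Each interval receives a noisy internal estimate of the task-relevant
#' dimension ("faster" for the speed task; "earlier" for the TTA task, via
#' a negative TTA weight). The interval with the larger estimate is chosen;
#' `second_interval_bias` is added to the second interval's estimate and
#' lapses replace the choice by a fair coin.
#'
#' @param design trial tibble from [make_design()].
#' @param params an [observer_params()].
#' @param grid the [design_grid()] (for cue standardization).
#' @param scene a [scene_config()].
#' @param seed integer seed.
#' @return The design tibble with columns `chose_comparison`,
#'   `chose_interval2`, `response_interval`, `correct` added.
#' @export
simulate_responses <- function(design, params, grid = design_grid(),
                               scene = scene_config(), seed = 1) {
  set.seed(seed)
  task <- design$task[1]
  scaler <- cue_scaler(grid, scene)
  z_cmp <- scaler(design$comparison_speed, design$comparison_tta)
  z_std <- scaler(rep(grid$standard_speed, nrow(design)),
                  rep(grid$standard_tta, nrow(design)))
  w <- params$cue_weights[[task]]
  n <- nrow(design)
  est_cmp <- as.vector(z_cmp[, names(w)] %*% w) +
    rnorm(n, 0, params$internal_noise_sd)
  est_std <- as.vector(z_std[, names(w)] %*% w) +
    rnorm(n, 0, params$internal_noise_sd)
  est1 <- ifelse(design$standard_first, est_std, est_cmp)
  est2 <- ifelse(design$standard_first, est_cmp, est_std) +
    params$second_interval_bias
  chose2 <- est2 > est1
  lapse <- runif(n) < params$lapse_prob
  chose2[lapse] <- runif(sum(lapse)) < 0.5
  chose_cmp <- ifelse(design$standard_first, chose2, !chose2)
  # ground truth: which interval really was faster / earlier
  if (task == "speed") {
    cmp_wins <- design$comparison_speed > grid$standard_speed
    tie <- design$comparison_speed == grid$standard_speed
  } else {
    cmp_wins <- design$comparison_tta < grid$standard_tta
    tie <- design$comparison_tta == grid$standard_tta
  }
  correct <- ifelse(tie, NA, chose_cmp == cmp_wins)
  out <- design
  out$chose_comparison <- as.logical(chose_cmp)
  out$chose_interval2 <- as.logical(chose2)
  out$response_interval <- ifelse(chose2, 2L, 1L)
  out$correct <- correct
  out
}

#' Generate a complete synthetic dataset
#'
#' For every observer, both sessions (speed and TTA task) are generated:
#' the randomized trial list, 2IFC responses from the noisy
#' internal-estimate model and, optionally, gaze traces with ground-truth
#' event labels for both intervals of every trial.
#'
#' @param participants list of [observer_params()] (see
#'   [default_observer_cohort()]).
#' @param grid a [design_grid()].
#' @param scene a [scene_config()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @param gaze generate gaze traces? (responses only if FALSE).
#' @param gaze_sample_rate gaze sampling rate in Hz.
#' @param gaze_intervals which intervals to simulate gaze for
#'   (`c("comparison", "standard")` or a subset).
#' @param tasks sessions to generate.
#' @return List of class `crossgaze_dataset` with `trials` (tibble),
#'   `traces` (named list of `gaze_trace`), `grid`, `scene`.
#' @export
generate_dataset <- function(participants = default_observer_cohort(3),
                             grid = design_grid(),
                             scene = scene_config(),
                             seed = 1, gaze = TRUE,
                             gaze_sample_rate = 250,
                             gaze_intervals = "comparison",
                             tasks = c("speed", "tta")) {
  trials <- list(); traces <- list()
  for (p in seq_along(participants)) {
    par <- participants[[p]]
    for (task in tasks) {
      s_base <- (seed * 97L + p * 13L +
                   ifelse(task == "speed", 0L, 500000L)) %% .Machine$integer.max
      des <- make_design(grid, par$participant_id, task, seed = s_base + 1L)
      des <- simulate_responses(des, par, grid, scene, seed = s_base + 2L)
      des$trial_id <- sprintf("%s_%s_%03d", par$participant_id, task,
                              des$trial_index)
      trials[[length(trials) + 1]] <- des
      if (gaze) {
        for (k in seq_len(nrow(des))) {
          for (iv in gaze_intervals) {
            if (iv == "comparison") {
              traj <- trajectory(des[k, ], scene, gaze_sample_rate)
            } else {
              traj <- trajectory(NULL, scene, gaze_sample_rate,
                                 speed_kmh = grid$standard_speed,
                                 tta_s = grid$standard_tta,
                                 approach_side = des$approach_side[k])
            }
            tr <- simulate_gaze(des[k, ], traj, par, scene,
                                seed = s_base + 10L + 7L * k +
                                  ifelse(iv == "comparison", 0L, 3L),
                                interval = iv, trial_id = des$trial_id[k])
            traces[[paste(des$trial_id[k], iv, sep = "_")]] <- tr
          }
        }
      }
    }
  }
  structure(list(trials = do.call(rbind, trials), traces = traces,
                 grid = grid, scene = scene,
                 participants = participants),
            class = "crossgaze_dataset")
}

#' @export
print.crossgaze_dataset <- function(x, ...) {
  cat("<crossgaze_dataset>\n")
  cat(sprintf("  %d trials, %d participants, %d gaze traces\n",
              nrow(x$trials), length(unique(x$trials$participant_id)),
              length(x$traces)))
  invisible(x)
}
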