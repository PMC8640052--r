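# Shared fixture builders. Everything is generated in code; the heavier
# objects are built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

test_scene <- function() scene_config()

# a hand-built gaze trace: constant-velocity drift with optional injected
# saccadic steps (minimum-jerk) and blinks, plus ground truth
make_synth_trace <- function(duration_s = 5, fs = 500,
                             drift_dps = c(0.3, 0), start = c(0, 0),
                             steps = NULL, blink_runs = NULL,
                             noise_sd = 0) {
  n <- duration_s * fs
  t <- (seq_len(n) - 1) / fs
  x <- start[1] + drift_dps[1] * t
  y <- start[2] + drift_dps[2] * t
  truth <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude = numeric(0), direction = numeric(0))
  if (!is.null(steps)) {
    for (k in seq_len(nrow(steps))) {
      t0 <- steps$t0[k]; dur <- steps$dur[k]
      ax <- steps$ax[k]; ay <- steps$ay[k]
      idx <- which(t >= t0 & t < t0 + dur)
      s <- (t[idx] - t0) / dur
      prof <- s^3 * (10 - 15 * s + 6 * s^2)
      x[idx] <- x[idx] + ax * prof
      y[idx] <- y[idx] + ay * prof
      after <- t >= t0 + dur
      x[after] <- x[after] + ax
      y[after] <- y[after] + ay
      truth <- rbind(truth, data.frame(
        onset_ms = t0 * 1000, offset_ms = (t0 + dur) * 1000,
        amplitude = sqrt(ax^2 + ay^2),
        direction = atan2(ay, ax) * 180 / pi))
    }
  }
  pupil <- rep(TRUE, n)
  if (!is.null(blink_runs)) {
    for (k in seq_len(nrow(blink_runs))) {
      idx <- which(t >= blink_runs$t0[k] & t < blink_runs$t1[k])
      pupil[idx] <- FALSE
    }
  }
  if (noise_sd > 0) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
  }
  structure(list(trial_id = "synth", interval = "comparison",
                 participant_id = "PX", task = "speed", fs = fs,
                 samples = tibble::tibble(t_ms = t * 1000, gaze_x = x,
                                          gaze_y = y, pupil_valid = pupil),
                 target = cbind(x, y) * 0,
                 truth = list(saccades = truth,
                              blinks = data.frame(onset_ms = numeric(0),
                                                  offset_ms = numeric(0)))),
            class = "gaze_trace")
}

# small end-to-end dataset: gaze for the comparison interval only,
# a subset of trials per session, 100 Hz
small_gaze_dataset <- function(n_participants = 4, trials_per_task = 24,
                               seed = 42, distinct_observers = TRUE) {
  cohort <- default_observer_cohort(n_participants, seed = seed,
                                    distinct_observers = distinct_observers)
  grid <- design_grid(n_blocks = 1)
  ds <- generate_dataset(cohort, grid, scene_config(), seed = seed,
                         gaze = FALSE)
  # keep the same stimulus cells in every session so that task labels
  # carry no stimulus-composition signal
  keep <- unlist(lapply(split(seq_len(nrow(ds$trials)),
                              paste(ds$trials$participant_id,
                                    ds$trials$task)),
                        function(ix) {
                          o <- order(ds$trials$comparison_speed[ix],
                                     ds$trials$comparison_tta[ix],
                                     ds$trials$block[ix])
                          ix[o][seq_len(trials_per_task)]
                        }))
  ds$trials <- ds$trials[sort(keep), ]
  sc <- ds$scene
  traces <- list()
  for (k in seq_len(nrow(ds$trials))) {
    row <- ds$trials[k, ]
    par <- cohort[[match(row$participant_id,
                         vapply(cohort, `[[`, "", "participant_id"))]]
    traj <- trajectory(row, sc, 250)
    traces[[paste0(row$trial_id, "_comparison")]] <-
      simulate_gaze(row, traj, par, sc,
                    seed = seed + 31L * k, trial_id = row$trial_id)
  }
  ds$traces <- traces
  ds
}

small_metrics <- function() {
  fixture("small_metrics", function() {
    ds <- fixture("small_dataset", function() small_gaze_dataset())
    compute_gaze_metrics(ds)
  })
}
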