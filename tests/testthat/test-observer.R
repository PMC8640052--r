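perfect_params <- function(...) {
  defaults <- list(pursuit_gain_mean = 1, pursuit_gain_sd = 0,
                   fixation_noise_sd = 0, saccade_rate_bias = 0,
                   blink_rate = 0, catchup_threshold = Inf,
                   error_correction_gain = 0,
                   gaze_offset = c(h = 0, v = 0))
  do.call(observer_params, modifyList(defaults, list(...)))
}

test_that("a noise-free unit-gain tracker reproduces the target path", {
  sc <- test_scene()
  traj <- trajectory(NULL, sc, 250, speed_kmh = 50, tta_s = 3.04)
  tr <- simulate_gaze(NULL, traj, perfect_params(), sc, seed = 1)
  expect_lt(max(abs(tr$samples$gaze_x - tr$target[, 1])), 1e-9)
  expect_lt(max(abs(tr$samples$gaze_y - tr$target[, 2])), 1e-9)
  expect_equal(nrow(tr$truth$saccades), 0)
  expect_true(all(tr$samples$pupil_valid))
  # duration covers display + post-offset
  expect_equal(nrow(tr$samples), 250 * 5)
})

test_that("gaze simulation is deterministic under a fixed seed", {
  sc <- test_scene()
  traj <- trajectory(NULL, sc, 100, speed_kmh = 70, tta_s = 2.24)
  par <- observer_params()
  a <- simulate_gaze(NULL, traj, par, sc, seed = 99)
  b <- simulate_gaze(NULL, traj, par, sc, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c <- simulate_gaze(NULL, traj, par, sc, seed = 100)
  expect_false(identical(a$samples$gaze_x, c$samples$gaze_x))
})

test_that("an under-gained tracker emits catch-up saccades along the motion", {
  sc <- test_scene()
  # close, fast approach: large target excursion accumulates error quickly
  traj <- trajectory(NULL, sc, 250, speed_kmh = 20, tta_s = 1.44)
  par <- observer_params(pursuit_gain_mean = 0.5, pursuit_gain_sd = 0,
                         fixation_noise_sd = 0, saccade_rate_bias = 0,
                         blink_rate = 0, catchup_threshold = 0.4,
                         saccade_amplitude_noise_sd = 0,
                         error_correction_gain = 0)
  tr <- simulate_gaze(NULL, traj, par, sc, seed = 2)
  sac <- tr$truth$saccades
  onsets <- sac$onset_ms[sac$onset_ms < 2900]
  expect_gt(length(onsets), 0)
  # target moves toward increasing azimuth (right-side approach); catch-up
  # saccades must point the same way
  for (k in which(sac$onset_ms < 2900)) {
    expect_lt(abs(sac$direction[k]), 90)
  }
})

test_that("blinks zero pupil validity for 100-300 ms runs", {
  sc <- test_scene()
  traj <- trajectory(NULL, sc, 250, speed_kmh = 50, tta_s = 3.04)
  par <- perfect_params(blink_rate = 0.8)
  tr <- simulate_gaze(NULL, traj, par, sc, seed = 5)
  expect_gt(nrow(tr$truth$blinks), 0)
  durs <- tr$truth$blinks$offset_ms - tr$truth$blinks$onset_ms
  expect_true(all(durs >= 90 & durs <= 310))
  expect_false(all(tr$samples$pupil_valid))
})

test_that("the differencing rule yields P(correct) = Phi(delta / (sigma sqrt(2)))", {
  # Monte-Carlo oracle frozen against the closed form: sigma = 10,
  # delta = 10 -> Phi(10 / (10 sqrt 2)) = 0.7602
  set.seed(42)
  n <- 2e5
  est_a <- 10 + rnorm(n, 0, 10)
  est_b <- 0 + rnorm(n, 0, 10)
  expect_equal(mean(est_a > est_b), pnorm(10 / (10 * sqrt(2))),
               tolerance = 0.005)
  expect_equal(pnorm(10 / (10 * sqrt(2))), 0.760, tolerance = 1e-3)
})

test_that("internal estimates rank stimuli by their weighted cues", {
  par <- observer_params(internal_noise_sd = 0,
                         cue_weights = list(
                           speed = c(speed = 1, tta = 0, start = 0, end = 0),
                           tta = c(speed = 0, tta = -1, start = 0, end = 0)))
  z60 <- c(speed = 0.5, tta = 0, start = 0, end = 0)
  z50 <- c(speed = 0, tta = 0, start = 0, end = 0)
  expect_gt(internal_estimate(z60, par, "speed", seed = 1),
            internal_estimate(z50, par, "speed", seed = 1))
  # tta weight -1: smaller TTA -> larger "earlier" estimate
  z_early <- c(speed = 0, tta = -1.5, start = 0, end = 0)
  expect_gt(internal_estimate(z_early, par, "tta", seed = 1),
            internal_estimate(z50, par, "tta", seed = 1))
})

test_that("response simulation honours bias, lapse and determinism", {
  grid <- design_grid(n_blocks = 1)
  des <- make_design(grid, task = "speed", seed = 3)
  # pure bias, identical-stimulus trials only
  par_bias <- observer_params(internal_noise_sd = 0.3, lapse_prob = 0,
                              second_interval_bias = 0.8)
  r <- simulate_responses(des, par_bias, grid, seed = 10)
  same <- r[r$comparison_speed == 50 & r$comparison_tta == 3.04, ]
  many <- do.call(rbind, lapply(1:60, function(s)
    simulate_responses(des, par_bias, grid, seed = s)))
  same_many <- many[many$comparison_speed == 50 &
                      many$comparison_tta == 3.04, ]
  expect_gt(mean(same_many$chose_interval2), 0.6)
  # full lapsing -> chance correctness
  par_lapse <- observer_params(lapse_prob = 1)
  rl <- do.call(rbind, lapply(1:30, function(s)
    simulate_responses(des, par_lapse, grid, seed = s)))
  expect_equal(mean(rl$correct, na.rm = TRUE), 0.5, tolerance = 0.05)
  # deterministic TTA rule
  par_tta <- observer_params(internal_noise_sd = 0, lapse_prob = 0,
                             second_interval_bias = 0,
                             cue_weights = list(
                               speed = c(speed = 1, tta = 0, start = 0,
                                         end = 0),
                               tta = c(speed = 0, tta = -1, start = 0,
                                       end = 0)))
  des_t <- make_design(grid, task = "tta", seed = 4)
  rt <- simulate_responses(des_t, par_tta, grid, seed = 11)
  hard <- rt[rt$comparison_tta != 3.04, ]
  expect_true(all(hard$correct))
  expect_identical(simulate_responses(des, par_bias, grid, seed = 10),
                   simulate_responses(des, par_bias, grid, seed = 10))
})

test_that("dataset generation produces the full session bookkeeping", {
  cohort <- default_observer_cohort(2, seed = 1)
  grid <- design_grid(n_blocks = 1)
  ds <- generate_dataset(cohort, grid, seed = 1, gaze = FALSE)
  # participants x tasks x blocks x 81
  expect_equal(nrow(ds$trials), 2 * 2 * 81)
  expect_setequal(unique(ds$trials$task), c("speed", "tta"))
  expect_equal(anyDuplicated(ds$trials$trial_id), 0)
  # full design arithmetic: 3 blocks -> 243 per session, 15 x 2 x 243 rows
  expect_equal(15 * 2 * 3 * 81, 7290)
  # gaze traces link back to trials
  ds2 <- generate_dataset(cohort[1], design_grid(n_blocks = 1),
                          seed = 2, gaze = TRUE, gaze_sample_rate = 100,
                          tasks = "speed")
  expect_equal(length(ds2$traces), 81)
  tr <- ds2$traces[[1]]
  expect_true(tr$trial_id %in% ds2$trials$trial_id)
  expect_s3_class(tr, "gaze_trace")
})

test_that("psychometric slope of simulated responses matches sigma sqrt(2)", {
  # responses driven purely by the z-scored speed cue with internal noise
  # sigma must fit with slope ~ sigma * sqrt(2) on the z scale
  grid <- design_grid(n_blocks = 1)
  par <- observer_params(internal_noise_sd = 0.73, lapse_prob = 0,
                         second_interval_bias = 0,
                         cue_weights = list(
                           speed = c(speed = 1, tta = 0, start = 0, end = 0),
                           tta = c(speed = 0, tta = -1, start = 0, end = 0)))
  des <- make_design(grid, task = "speed", seed = 6)
  r <- do.call(rbind, lapply(1:40, function(s)
    simulate_responses(des, par, grid, seed = 600 + s)))
  pd <- psychometric_data(r, "speed")
  fit <- fit_psychometric(pd$levels, pd$k, pd$n, n_boot = 0)
  sd_speed_grid <- sd(rep(seq(10, 90, 10), 9))
  sigma_expected <- 0.73 * sqrt(2) * sd_speed_grid
  expect_equal(fit$sigma, sigma_expected, tolerance = 0.12)
  expect_equal(fit$pse, 50, tolerance = 2.5)
})
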