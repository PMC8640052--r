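test_that("3D angular velocity matches constant-rotation closed forms", {
  # 0.005 deg per 1 ms sample -> 5 deg/s
  ang <- seq(0, 0.5, by = 0.005) * pi / 180
  dirs <- cbind(sin(ang), cos(ang), 0)
  w <- angular_velocity_3d(dirs, dt = 0.001)
  expect_equal(w, rep(5, length(w)), tolerance = 1e-9)
  # static direction -> 0
  dirs0 <- matrix(rep(c(0, 1, 0), 10), ncol = 3, byrow = TRUE)
  expect_equal(angular_velocity_3d(dirs0, 0.001), rep(0, 10))
  expect_error(angular_velocity_3d(rbind(c(0, 0, 0), c(0, 1, 0)), 0.001),
               "zero")
})

test_that("3D angular velocity agrees with the planar 2D speed near center", {
  # small eccentricity: great-circle rate equals the planar hypotenuse rate
  fs <- 500
  t <- seq(0, 1, by = 1 / fs)
  sx <- 0.5 + 2 * t; sy <- -1 + 1 * t   # 2.236 deg/s planar, < 5 deg ecc
  sc <- test_scene()
  dirs <- screen_eye_direction(cbind(sx, sy), sc)
  w <- angular_velocity_3d(dirs, 1 / fs)
  planar <- sqrt(2^2 + 1^2)
  expect_equal(mean(w), planar, tolerance = 1e-3 * planar)
})

test_that("pursuit gain is 1 for perfect tracking and 0 for static gaze", {
  sc <- test_scene()
  traj <- trajectory(NULL, sc, 250, speed_kmh = 50, tta_s = 3.04)
  par0 <- observer_params(pursuit_gain_mean = 1, pursuit_gain_sd = 0,
                          fixation_noise_sd = 0, saccade_rate_bias = 0,
                          blink_rate = 0, catchup_threshold = Inf,
                          error_correction_gain = 0,
                          gaze_offset = c(h = 0, v = 0))
  tr <- simulate_gaze(NULL, traj, par0, sc, seed = 1)
  expect_equal(pursuit_gain(tr, scene = sc), 1, tolerance = 1e-6)
  trs <- tr
  trs$samples$gaze_x <- trs$samples$gaze_x * 0 + tr$target[1, 1]
  trs$samples$gaze_y <- trs$samples$gaze_y * 0 + tr$target[1, 2]
  expect_equal(pursuit_gain(trs, tr$target, scene = sc), 0,
               tolerance = 1e-9)
})

test_that("pursuit gain recovers the generating gain across levels", {
  sc <- test_scene()
  traj <- trajectory(NULL, sc, 250, speed_kmh = 50, tta_s = 3.04)
  for (g in c(0.5, 0.8, 1.1)) {
    par <- observer_params(pursuit_gain_mean = g, pursuit_gain_sd = 0,
                           fixation_noise_sd = 0, saccade_rate_bias = 0,
                           blink_rate = 0, catchup_threshold = Inf,
                           error_correction_gain = 0,
                           gaze_offset = c(h = 0, v = 0))
    tr <- simulate_gaze(NULL, traj, par, sc, seed = 3)
    expect_equal(pursuit_gain(tr, scene = sc), g, tolerance = 0.02)
  }
})

test_that("pursuit gain is undefined for an essentially static target", {
  sc <- test_scene()
  tr <- make_synth_trace(duration_s = 5, fs = 250, drift_dps = c(0.3, 0))
  static_target <- matrix(0, nrow(tr$samples), 2)
  expect_true(is.na(pursuit_gain(tr, static_target, scene = sc)))
})

test_that("position deviations split signed and absolute components", {
  tr <- make_synth_trace(duration_s = 5, fs = 250, drift_dps = c(0, 0))
  n <- nrow(tr$samples)
  target <- cbind(seq(0, 2, length.out = n), rep(0, n))  # moves rightward
  # gaze identical to target
  tr$samples$gaze_x <- target[, 1]; tr$samples$gaze_y <- target[, 2]
  d0 <- position_deviation(tr, target, window = c(2, 3))
  expect_equal(unname(d0), c(0, 0, 0, 0))
  # constant +0.5 above
  tr$samples$gaze_y <- target[, 2] + 0.5
  d1 <- position_deviation(tr, target, window = c(2, 3))
  expect_equal(d1[["rel_v"]], 0.5); expect_equal(d1[["abs_v"]], 0.5)
  # symmetric horizontal jitter: rel ~ 0, abs ~ 1
  set.seed(1)
  tr$samples$gaze_x <- target[, 1] + sample(c(-1, 1), n, TRUE)
  d2 <- position_deviation(tr, target, window = c(2, 3))
  expect_lt(abs(d2[["rel_h"]]), 0.15)
  expect_equal(d2[["abs_h"]], 1, tolerance = 1e-9)
  # "ahead" flips with motion direction: gaze +0.3 right of a leftward
  # target is behind it
  targetL <- cbind(seq(0, -2, length.out = n), rep(0, n))
  tr$samples$gaze_x <- targetL[, 1] + 0.3
  tr$samples$gaze_y <- targetL[, 2]
  dL <- position_deviation(tr, targetL, window = c(2, 3))
  expect_equal(dL[["rel_h"]], -0.3)
})

test_that("saccade statistics drop the first saccade and split at offset", {
  ev1 <- structure(list(
    saccades = data.frame(onset_ms = 500, offset_ms = 530,
                          amplitude = 2, direction = 0),
    blinks = data.frame(onset_ms = numeric(0), offset_ms = numeric(0))),
    class = "event_labels")
  s1 <- saccade_stats(ev1)
  expect_equal(s1[["n_saccades"]], 0)

  ev3 <- structure(list(
    saccades = data.frame(onset_ms = c(500, 1500, 2500),
                          offset_ms = c(530, 1530, 2530),
                          amplitude = c(1, 2, 3), direction = 0),
    blinks = data.frame(onset_ms = numeric(0), offset_ms = numeric(0))),
    class = "event_labels")
  s3 <- saccade_stats(ev3)
  expect_equal(s3[["n_saccades"]], 2)
  expect_equal(s3[["mean_amplitude"]], 2.5)

  # a saccade landing inside the crossing AOI after 3 s counts as "after"
  sc <- test_scene()
  cross <- crossing_aoi(sc, "right")
  tr <- make_synth_trace(duration_s = 5, fs = 250)
  idx <- which(tr$samples$t_ms >= 3520)[1]
  tr$samples$gaze_x[idx:nrow(tr$samples)] <- cross$center[1, 1]
  tr$samples$gaze_y[idx:nrow(tr$samples)] <- cross$center[1, 2]
  ev <- structure(list(
    saccades = data.frame(onset_ms = c(500, 3500), offset_ms = c(530, 3530),
                          amplitude = c(1, 8), direction = 0),
    blinks = data.frame(onset_ms = numeric(0), offset_ms = numeric(0))),
    class = "event_labels")
  s <- saccade_stats(ev, tr, cross, vehicle_offset_time = 3)
  expect_equal(s[["n_sacc_crossing_after"]], 1)
  expect_equal(s[["n_sacc_crossing_before"]], 0)
})

test_that("symmetric MAD filter reproduces the brute-force score", {
  x <- c(1:9, 100)
  med <- median(x)
  madv <- median(abs(x - med))
  score100 <- abs(100 - med) / (1.4826 * madv)
  expect_equal(score100, 25.5, tolerance = 0.01)
  keep <- mad_outlier_filter(x)
  expect_identical(which(!keep), 10L)
  # constant vector: guard, nothing flagged
  expect_warning(k0 <- mad_outlier_filter(rep(3, 10)), "zero")
  expect_true(all(k0))
  # standard-normal sample: < 0.2% flagged
  set.seed(2)
  z <- rnorm(1e4)
  expect_lt(mean(!mad_outlier_filter(z)), 0.002)
})

test_that("double-MAD filter matches a brute-force oracle exactly", {
  brute <- function(x, cut = 4.5, cc = 1.4826) {
    med <- median(x)
    m_lo <- median(abs(x[x <= med] - med))
    m_hi <- median(abs(x[x >= med] - med))
    keep <- rep(TRUE, length(x))
    for (i in seq_along(x)) {
      if (x[i] < med && m_lo > 0)
        keep[i] <- abs(x[i] - med) / (cc * m_lo) <= cut
      if (x[i] > med && m_hi > 0)
        keep[i] <- abs(x[i] - med) / (cc * m_hi) <= cut
    }
    keep
  }
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(3:20, 1)
    x <- round(rexp(n, 1 / 3) + rnorm(n), 2)
    expect_identical(
      suppressWarnings(mad_outlier_filter(x, asymmetric = TRUE)),
      suppressWarnings(brute(x)))
  }
})

test_that("MAD filtering is scale-invariant", {
  set.seed(3)
  x <- c(rexp(30, 1 / 2), 40)
  for (c_mult in c(0.01, 1, 250)) {
    expect_identical(mad_outlier_filter(x * c_mult, asymmetric = TRUE),
                     mad_outlier_filter(x, asymmetric = TRUE))
    expect_identical(mad_outlier_filter(x * c_mult),
                     mad_outlier_filter(x))
  }
})

test_that("trial metrics land in roadside-plausible ranges", {
  m <- small_metrics()
  f <- m[m$window == "feature", ]
  gain_kept <- f$gain[mad_outlier_filter(f$gain)]
  expect_gt(mean(gain_kept, na.rm = TRUE), 0.7)
  expect_lt(mean(gain_kept, na.rm = TRUE), 1.3)
  expect_gt(mean(f$n_saccades), 1)
  expect_lt(mean(f$n_saccades), 5)
  expect_gt(mean(f$mean_amplitude, na.rm = TRUE), 0.5)
  expect_lt(mean(f$mean_amplitude, na.rm = TRUE), 2)
  # crossing-area saccades are rare, as in the fixate-the-vehicle regime
  expect_lt(mean(f$n_sacc_crossing_before), 0.2)
  # outlier removal on clean synthetic data stays at the few-percent
  # level when averaged over the nine features
  flagged <- vapply(gaze_feature_names(), function(col) {
    x <- f[[col]][is.finite(f[[col]])]
    if (length(unique(x)) < 4) return(0)
    asym <- col %in% c("n_saccades", "mean_amplitude")
    mean(!suppressWarnings(mad_outlier_filter(x, asymmetric = asym)))
  }, 0)
  expect_lt(mean(flagged), 0.08)
})
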