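# small labelled feature table: n_obs participants x trials, with optional
# per-participant and per-task feature shifts
toy_features <- function(n_obs = 5, n_trials = 16, p = 3,
                         obs_shift = 0, task_shift = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_obs)) {
    mu_i <- rnorm(p, 0, obs_shift)
    for (task in c("speed", "tta")) {
      mu_t <- if (task == "speed") rep(task_shift, p) else rep(0, p)
      X <- matrix(rnorm(n_trials * p), n_trials, p) +
        matrix(mu_i + mu_t, n_trials, p, byrow = TRUE)
      colnames(X) <- paste0("f", seq_len(p))
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = sprintf("P%02d", i), task = task, X)
    }
  }
  do.call(rbind, rows)
}

test_that("the paired-Hotelling MANOVA matches a determinant oracle", {
  set.seed(10)
  n <- 14; p <- 9
  A <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  B <- A + matrix(rnorm(n * p, 0.2, 1), n, p)
  res <- manova_compare(A, B)
  # independent route: Wilks's Lambda via determinants,
  # Lambda = det(E) / det(E + H) with E = (n-1) S, H = n dbar dbar'
  D <- A - B
  E <- (n - 1) * cov(D)
  H <- n * tcrossprod(colMeans(D))
  lambda_det <- det(E) / det(E + H)
  expect_equal(res$wilks_lambda, lambda_det, tolerance = 1e-10)
  expect_equal(res$f_stat,
               (1 - lambda_det) / lambda_det * (n - p) / p,
               tolerance = 1e-10)
  expect_equal(res$df, c(9, 5))
  # univariate F equals the squared paired t
  tt <- t.test(D[, 3])$statistic
  expect_equal(unname(res$univariate[3, "F"]), unname(tt^2),
               tolerance = 1e-9)
})

test_that("identical task means give Lambda = 1 and F = 0", {
  set.seed(13)
  A <- matrix(rnorm(12 * 4), 12, 4)
  # differences with exactly zero column means: T2 = 0, Lambda = 1
  D <- scale(matrix(rnorm(12 * 4), 12, 4), center = TRUE, scale = FALSE)
  res <- manova_compare(A, A - D)
  expect_equal(res$wilks_lambda, 1, tolerance = 1e-12)
  expect_lt(res$f_stat, 1e-12)
})

test_that("the MANOVA null rejection rate is calibrated near alpha", {
  set.seed(20)
  rej <- mean(replicate(150, {
    A <- matrix(rnorm(12 * 3), 12, 3)
    B <- matrix(rnorm(12 * 3), 12, 3)
    manova_compare(A, B)$p_value < 0.05
  }))
  expect_gt(rej, 0.01); expect_lt(rej, 0.11)
})

test_that("collinear paired differences trigger the singularity error", {
  set.seed(12)
  A <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  B <- A
  B[, 1] <- A[, 1] - rnorm(10)
  B[, 2] <- A[, 2] - 2 * (A[, 1] - B[, 1])  # difference b = 2 x difference a
  expect_error(manova_compare(A, B), "collinear|singular")
})

test_that("the radial-kernel classifier separates blobs and not noise", {
  set.seed(30)
  X <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  clf <- train_classifier(X, y)
  expect_gt(mean(clf$predict(X) == y), 0.95)
  expect_lte(clf$support_vector_fraction, 1)
  # shuffled labels: near-chance out-of-sample
  ys <- sample(y)
  clf2 <- train_classifier(X[1:80, ], ys[1:80])
  expect_lt(mean(clf2$predict(X[81:100, ]) == ys[81:100]), 0.85)
  expect_error(train_classifier(X, rep("a", 100)), "single-class")
})

test_that("duplicated feature columns do not change predictions", {
  set.seed(31)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 3), 30, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c("a", "b"), each = 30)
  clf1 <- train_classifier(X, y, gamma = 1 / 2)
  X2 <- cbind(X, u2 = X[, 1])
  clf2 <- train_classifier(X2, y, gamma = 1 / 2)
  # same decision on the training points (kernel widths matched per spec:
  # gamma fixed, duplicated information does not flip labels)
  expect_gt(mean(clf1$predict(X) == clf2$predict(X2)), 0.95)
})

test_that("LOSO partitions by participant and reports NIR correctly", {
  d <- toy_features(n_obs = 5, obs_shift = 0, task_shift = 2, seed = 2)
  rep <- loso_cv(d, label = "task", feature_cols = c("f1", "f2", "f3"))
  expect_gt(rep$accuracy, 0.9)
  expect_equal(rep$nir, 0.5)
  expect_lt(rep$binomial_p, 1e-6)
  expect_length(rep$per_set_accuracy, 5)
  expect_error(loso_cv(d[d$participant_id %in% c("P01", "P02"), ],
                       label = "task", feature_cols = c("f1", "f2", "f3")),
               ">= 3")
})

test_that("task decoding stays at chance without task differences", {
  d <- toy_features(n_obs = 6, obs_shift = 1.5, task_shift = 0, seed = 3)
  rep <- loso_cv(d, label = "task", feature_cols = c("f1", "f2", "f3"))
  expect_lt(rep$accuracy, rep$nir + 0.12)
})

test_that("k-fold CV decodes observers with idiosyncratic features", {
  d <- toy_features(n_obs = 6, obs_shift = 2, task_shift = 0, seed = 4)
  rep <- kfold_cv(d, label = "participant_id", k = 10, seed = 5,
                  feature_cols = c("f1", "f2", "f3"))
  expect_gt(rep$accuracy, 3 * (1 / 6))
  expect_lt(rep$binomial_p, 1e-6)
  # identical observers: near chance
  d0 <- toy_features(n_obs = 6, obs_shift = 0, task_shift = 0, seed = 6)
  rep0 <- kfold_cv(d0, label = "participant_id", k = 10, seed = 7,
                   feature_cols = c("f1", "f2", "f3"))
  expect_lt(rep0$accuracy, rep0$nir + 0.12)
  # folds partition the data exactly: counts add up
  expect_equal(rep$n_total, nrow(d))
})

test_that("the permutation test is deterministic and respects boundaries", {
  d <- toy_features(n_obs = 4, n_trials = 10, obs_shift = 0,
                    task_shift = 2.5, seed = 8)
  pt1 <- permutation_test(d, "task", cv_fun = loso_cv, n_perm = 19,
                          seed = 9, feature_cols = c("f1", "f2", "f3"))
  pt2 <- permutation_test(d, "task", cv_fun = loso_cv, n_perm = 19,
                          seed = 9, feature_cols = c("f1", "f2", "f3"))
  expect_identical(pt1$p, pt2$p)
  # strongly separable tasks: no permutation beats the observed accuracy
  expect_equal(pt1$p, 0)
  expect_match(pt1$p_string, "^< ")
  # and an always-wrong observed statistic gives p = 1
  dnull <- d
  pt3 <- permutation_test(dnull, "task", cv_fun = function(data, label, ...) {
    # degenerate "classifier": accuracy 0 on the observed labels, chance
    # on permuted ones
    acc <- if (identical(data$task, d$task)) 0 else 0.5
    list(accuracy = acc)
  }, n_perm = 11, seed = 10)
  expect_equal(pt3$p, 1)
})

test_that("binomial comparison to NIR is one-sided in the right direction", {
  d <- toy_features(n_obs = 5, obs_shift = 0, task_shift = 0, seed = 11)
  rep <- loso_cv(d, label = "task", feature_cols = c("f1", "f2", "f3"))
  # at-chance classification should not be called significant
  expect_gt(rep$binomial_p, 0.05)
})
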