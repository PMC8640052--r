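#' Repeated-measures MANOVA for two tasks (paired Hotelling form)
#'
#' One-sample multivariate test on the paired task differences of the
#' per-participant feature means: `T2 = n * dbar' S^-1 dbar`,
#' `Lambda = 1 / (1 + T2 / (n - 1))`,
#' `F = ((1 - Lambda) / Lambda) * ((n - p) / p)` on (p, n - p) df.
#' Univariate paired F(1, n-1) tests accompany the multivariate result.
#'
#' @param means_a,means_b n x p matrices of per-participant feature means
#'   in the two task conditions (rows aligned by participant).
#' @return Object of class `task_comparison`: `wilks_lambda`, `f_stat`,
#'   `df`, `p_value`, `univariate` (per-feature F and p).
#' @export
manova_compare <- function(means_a, means_b) {
  A <- as.matrix(means_a); B <- as.matrix(means_b)
  stopifnot(all(dim(A) == dim(B)))
  D <- A - B
  n <- nrow(D); p <- ncol(D)
  if (n - p < 1) stop("manova_compare: need n - p >= 1 for the F transform")
  dbar <- colMeans(D)
  S <- stats::cov(D)
  qrS <- qr(S)
  if (qrS$rank < p) {
    bad <- colnames(D)[setdiff(seq_len(p), qrS$pivot[seq_len(qrS$rank)])]
    stop("manova_compare: singular covariance; collinear features: ",
         paste(bad, collapse = ", "))
  }
  T2 <- n * as.numeric(t(dbar) %*% solve(S, dbar))
  lambda <- 1 / (1 + T2 / (n - 1))
  f_stat <- ((1 - lambda) / lambda) * ((n - p) / p)
  p_value <- pf(f_stat, p, n - p, lower.tail = FALSE)
  uni <- t(apply(D, 2, function(d) {
    tt <- mean(d) / (sd(d) / sqrt(n))
    c(F = tt^2, p = pf(tt^2, 1, n - 1, lower.tail = FALSE))
  }))
  structure(list(wilks_lambda = lambda, f_stat = f_stat,
                 df = c(p, n - p), p_value = p_value,
                 hotelling_t2 = T2, univariate = uni),
            class = "task_comparison")
}

#' Wilks's Lambda to F for the paired two-condition design
#'
#' The exact transform used by [manova_compare()], exposed so a reported
#' Lambda can be converted to its F statistic directly.
#'
#' @param lambda Wilks's Lambda.
#' @param n participants; @param p features.
#' @return List `f`, `df`.
#' @export
wilks_to_f <- function(lambda, n, p) {
  list(f = ((1 - lambda) / lambda) * ((n - p) / p), df = c(p, n - p))
}

#' @export
print.task_comparison <- function(x, ...) {
  cat(sprintf(
    "<task_comparison> Lambda = %.3f, F(%d,%d) = %.2f, p = %.3f\n",
    x$wilks_lambda, x$df[1], x$df[2], x$f_stat, x$p_value))
  invisible(x)
}

std_train_test <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu, "-"), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu, "-"), 2, sdv, "/"))
}

#' Radial-kernel maximum-margin classifier
#'
#' Wraps a radial-basis SVM (cost 1, kernel width 1/p on z-scored
#' features); features are standardized with training-set statistics only.
#'
#' @param features training feature matrix.
#' @param labels factor of class labels.
#' @param cost,gamma hyperparameters (`gamma = NULL` uses 1/p).
#' @return List with `predict(newdata)` closure, `support_vector_fraction`,
#'   and the scaler.
#' @export
train_classifier <- function(features, labels, cost = 1, gamma = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("train_classifier: single-class training set")
  X <- as.matrix(features)
  mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  fit <- e1071::svm(Xs, labels, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  list(
    predict = function(newdata) {
      Xn <- sweep(sweep(as.matrix(newdata), 2, mu, "-"), 2, sdv, "/")
      predict(fit, Xn)
    },
    support_vector_fraction = nrow(fit$SV) / nrow(Xs),
    model = fit)
}

classifier_report <- function(acc_per_set, nir_per_set, n_correct, n_total,
                              confusion, sv_frac) {
  accuracy <- mean(acc_per_set)
  nir <- mean(nir_per_set)
  bt <- tryCatch(
    binom.test(n_correct, n_total, p = min(1 - 1e-12, max(1e-12, nir)),
               alternative = "greater"),
    error = function(e) NULL)
  structure(list(
    accuracy = accuracy,
    ci = if (!is.null(bt)) as.numeric(bt$conf.int) else c(NA, NA),
    nir = nir,
    binomial_p = if (!is.null(bt)) bt$p.value else NA_real_,
    n_correct = n_correct, n_total = n_total,
    per_set_accuracy = acc_per_set,
    confusion_matrix = confusion,
    support_vector_fraction = sv_frac),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> accuracy = %.3f, NIR = %.3f, binomial p = %.3g\n",
    x$accuracy, x$nir, x$binomial_p))
  invisible(x)
}

prep_features <- function(data, feature_cols) {
  X <- as.matrix(data[, feature_cols, drop = FALSE])
  # undefined metrics (zero-saccade amplitude, unmeasurable gain) are
  # imputed by the column mean so they stay uninformative
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- mean(X[!bad, j])
  }
  X
}

#' Leave-one-subject-out cross-validation
#'
#' Each participant in turn is the test set; accuracy is the mean of the
#' per-left-out-participant accuracies and the no-information rate the
#' mean of each test set's majority-class share.
#'
#' @param data data frame with `participant_id`, a label column and the
#'   feature columns.
#' @param label label column name (default `"task"`).
#' @param feature_cols feature column names.
#' @param ... passed to [train_classifier()].
#' @return A `classifier_report`.
#' @export
loso_cv <- function(data, label = "task",
                    feature_cols = gaze_feature_names(), ...) {
  parts <- unique(data$participant_id)
  if (length(parts) < 3) stop("loso_cv: need >= 3 participants")
  y <- as.factor(data[[label]])
  X <- prep_features(data, feature_cols)
  acc <- nir <- numeric(length(parts))
  ncor <- 0; ntot <- 0
  conf <- table(factor(levels(y), levels(y)),
                factor(levels(y), levels(y))) * 0
  svf <- numeric(length(parts))
  for (i in seq_along(parts)) {
    test <- data$participant_id == parts[i]
    clf <- train_classifier(X[!test, , drop = FALSE], y[!test], ...)
    pred <- factor(clf$predict(X[test, , drop = FALSE]), levels(y))
    truth <- factor(y[test], levels(y))
    acc[i] <- mean(pred == truth)
    nir[i] <- max(table(truth)) / length(truth)
    ncor <- ncor + sum(pred == truth); ntot <- ntot + length(truth)
    conf <- conf + table(truth, pred)
    svf[i] <- clf$support_vector_fraction
  }
  classifier_report(acc, nir, ncor, ntot, conf, mean(svf))
}

#' k-fold cross-validation
#'
#' Seeded random folds (no stratification): each fold sets aside ~1/k of
#' the rows as the test set.
#'
#' @param data data frame with a label column and feature columns.
#' @param label label column name (default `"participant_id"`).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param feature_cols feature column names.
#' @param ... passed to [train_classifier()].
#' @return A `classifier_report`.
#' @export
kfold_cv <- function(data, label = "participant_id", k = 10, seed = 1,
                     feature_cols = gaze_feature_names(), ...) {
  y <- as.factor(data[[label]])
  if (nrow(data) < k * nlevels(y))
    stop("kfold_cv: need >= k * classes observations")
  X <- prep_features(data, feature_cols)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), nrow(data)))
  acc <- nir <- svf <- numeric(k)
  ncor <- 0; ntot <- 0
  conf <- table(factor(levels(y), levels(y)),
                factor(levels(y), levels(y))) * 0
  for (i in seq_len(k)) {
    test <- fold == i
    clf <- train_classifier(X[!test, , drop = FALSE],
                            droplevels(y[!test]), ...)
    pred <- factor(as.character(clf$predict(X[test, , drop = FALSE])),
                   levels(y))
    truth <- factor(y[test], levels(y))
    acc[i] <- mean(pred == truth, na.rm = TRUE)
    nir[i] <- max(table(truth)) / length(truth)
    ncor <- ncor + sum(pred == truth, na.rm = TRUE); ntot <- ntot + length(truth)
    conf <- conf + table(truth, pred)
    svf[i] <- clf$support_vector_fraction
  }
  classifier_report(acc, nir, ncor, ntot, conf, mean(svf))
}

#' Permutation test for classifier accuracy
#'
#' Recomputes the cross-validated accuracy under label permutations (task
#' labels permuted within participant, observer labels globally) and
#' reports the one-sided p-value: the fraction of permuted accuracies at
#' or above the observed one. An exact zero is reported as `< 1/n_perm`.
#'
#' @param data data frame as for the CV functions.
#' @param label label column.
#' @param cv_fun cross-validation function (e.g. [loso_cv()] or a wrapper).
#' @param n_perm number of permutations.
#' @param seed seed.
#' @param within_participant permute within participant?
#' @param ... passed to `cv_fun`.
#' @return List `p`, `p_string`, `observed`, `permuted`.
#' @export
permutation_test <- function(data, label, cv_fun = loso_cv, n_perm = 1000,
                             seed = 1, within_participant = label == "task",
                             ...) {
  observed <- cv_fun(data, label = label, ...)$accuracy
  set.seed(seed)
  perm_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    d <- data
    if (within_participant) {
      for (pid in unique(d$participant_id)) {
        sel <- d$participant_id == pid
        d[[label]][sel] <- sample(d[[label]][sel])
      }
    } else {
      d[[label]] <- sample(d[[label]])
    }
    perm_acc[b] <- cv_fun(d, label = label, ...)$accuracy
  }
  p <- sum(perm_acc >= observed) / n_perm
  list(p = p,
       p_string = if (p == 0) sprintf("< %.3g", 1 / n_perm) else
         sprintf("%.3g", p),
       observed = observed, permuted = perm_acc)
}

#' Per-participant-task feature means for the MANOVA and group tables
#'
#' Averages the feature-window trial metrics within participant and task.
#'
#' @param metrics tibble from [compute_gaze_metrics()].
#' @param window which averaging window's rows to use.
#' @param feature_cols features to average.
#' @return Data frame of means with `participant_id` and `task` columns.
#' @export
participant_task_means <- function(metrics, window = "feature",
                                   feature_cols = gaze_feature_names()) {
  m <- metrics[metrics$window == window, ]
  out <- aggregate(m[, feature_cols],
                   by = list(participant_id = m$participant_id,
                             task = m$task),
                   FUN = function(x) mean(x, na.rm = TRUE))
  out
}
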