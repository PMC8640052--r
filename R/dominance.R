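#' Logistic regression of choices on stimulus cues
#'
#' Maximum-likelihood logistic fit of a binary choice on standardized
#' predictors, with McFadden's pseudo-R^2
#' `R2_M = 1 - logLik(model) / logLik(null)`.
#'
#' @param choices logical/0-1 vector.
#' @param predictors data frame or matrix of cue values (standardized
#'   internally).
#' @return List `coefficients`, `r2m`, `loglik`, `loglik_null`,
#'   `separation` flag (TRUE when complete separation forced a ridge
#'   refit).
#' @export
fit_cue_logistic <- function(choices, predictors) {
  y <- as.integer(choices)
  X <- scale(as.matrix(predictors))
  X[is.nan(X)] <- 0
  df <- data.frame(y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  ll0 <- logLik(glm(y ~ 1, data = df, family = binomial()))
  if (sep) {
    # weak L2 penalty via data augmentation keeps coefficients finite
    p <- ncol(X)
    Xa <- rbind(X, diag(1e-2, p), -diag(1e-2, p))
    ya <- c(y, rep(0.5, 2 * p))
    dfa <- data.frame(y = ya, Xa)
    colnames(dfa) <- colnames(df)
    fit <- suppressWarnings(glm(y ~ ., data = dfa, family = binomial()))
    eta <- cbind(1, X) %*% coef(fit)
    pr <- pmin(1 - 1e-12, pmax(1e-12, 1 / (1 + exp(-eta))))
    ll <- sum(y * log(pr) + (1 - y) * log(1 - pr))
  } else ll <- as.numeric(logLik(fit))
  list(coefficients = coef(fit),
       r2m = 1 - ll / as.numeric(ll0),
       loglik = ll, loglik_null = as.numeric(ll0),
       separation = sep)
}

subset_loglik <- function(y, X, cols) {
  if (!length(cols)) {
    fit <- glm(y ~ 1, family = binomial())
  } else {
    fit <- suppressWarnings(
      glm(y ~ ., data = data.frame(y = y, X[, cols, drop = FALSE]),
          family = binomial()))
  }
  as.numeric(logLik(fit))
}

#' General dominance analysis for logistic regression
#'
#' Fits all non-empty predictor subsets; the general dominance of
#' predictor j is the average (within subset size, then across sizes,
#' the empty set included) of the incremental McFadden R^2 from adding j
#' to subsets that exclude it. General dominance values sum exactly to
#' the full-model R^2.
#'
#' @param choices binary vector.
#' @param predictors data frame/matrix of 2-8 predictors.
#' @return Object of class `dominance_result`: `general_dominance`,
#'   `r2m_full`, `subset_r2m` (named by comma-joined predictor sets),
#'   `coefficients` of the full model.
#' @export
general_dominance <- function(choices, predictors) {
  X <- scale(as.matrix(predictors))
  X[is.nan(X)] <- 0
  p <- ncol(X)
  if (p < 1 || p > 8) stop("general_dominance: 1-8 predictors supported")
  nm <- colnames(X)
  y <- as.integer(choices)
  ll0 <- subset_loglik(y, X, integer(0))

  subsets <- list(integer(0))
  for (s in seq_len(p))
    subsets <- c(subsets, combn(p, s, simplify = FALSE))
  key <- vapply(subsets, function(s)
    paste0("s", paste(sort(s), collapse = ",")), "")
  r2 <- vapply(subsets, function(s) {
    1 - subset_loglik(y, X, s) / ll0
  }, 0)
  names(r2) <- key

  gd <- setNames(numeric(p), nm)
  for (j in seq_len(p)) {
    per_size <- numeric(p)
    for (s0 in 0:(p - 1)) {
      without <- subsets[vapply(subsets, function(s)
        length(s) == s0 && !(j %in% s), TRUE)]
      inc <- vapply(without, function(s) {
        r2[[paste0("s", paste(sort(c(s, j)), collapse = ","))]] -
          r2[[paste0("s", paste(sort(s), collapse = ","))]]
      }, 0)
      per_size[s0 + 1] <- mean(inc)
    }
    gd[j] <- mean(per_size)
  }
  full <- fit_cue_logistic(choices, predictors)
  structure(list(general_dominance = gd,
                 r2m_full = unname(r2[[paste0("s", paste(seq_len(p), collapse = ","))]]),
                 subset_r2m = r2[-1],
                 coefficients = full$coefficients,
                 separation = full$separation),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat("<dominance_result> full-model R2_M =", round(x$r2m_full, 4), "\n")
  print(round(x$general_dominance, 4))
  invisible(x)
}

#' Choices of a noisy theoretical observer
#'
#' The theoretical observer responds "faster" (speed rule) or "earlier"
#' (TTA rule) whenever the comparison's noised task cue beats the noised
#' standard cue; Gaussian noise of SD `noise_sd` (stimulus units) is added
#' to the task cue of both intervals (symmetric differencing; set
#' `noise_both = FALSE` to noise only the comparison).
#'
#' @param trials trial tibble with `comparison_speed`, `comparison_tta`.
#' @param rule `"speed"` (faster-if-speed-greater) or `"tta"`
#'   (earlier-if-tta-smaller).
#' @param noise_sd noise SD in the task cue's stimulus units (e.g. the
#'   participant's fitted psychometric sigma).
#' @param standard_speed,standard_tta the standard stimulus.
#' @param noise_both add noise to both intervals?
#' @param seed seed.
#' @return Logical vector: TRUE when the comparison is chosen.
#' @export
theoretical_observer_responses <- function(trials, rule = c("speed", "tta"),
                                           noise_sd,
                                           standard_speed = 50,
                                           standard_tta = 3.04,
                                           noise_both = TRUE, seed = 1) {
  rule <- match.arg(rule)
  set.seed(seed)
  n <- nrow(trials)
  sd_cmp <- noise_sd
  sd_std <- if (noise_both) noise_sd else 0
  if (rule == "speed") {
    cmp <- trials$comparison_speed + rnorm(n, 0, sd_cmp)
    std <- standard_speed + rnorm(n, 0, sd_std)
    cmp > std
  } else {
    cmp <- trials$comparison_tta + rnorm(n, 0, sd_cmp)
    std <- standard_tta + rnorm(n, 0, sd_std)
    cmp < std
  }
}

#' Cue table for dominance analyses
#'
#' The four cues of the comparison interval: speed (km/h), TTA (s), start
#' and end distance (m), the latter two determined by the first two and
#' the fixed display interval.
#'
#' @param trials trial tibble.
#' @param scene a [scene_config()].
#' @return Data frame with columns `speed`, `tta`, `start`, `end`.
#' @export
cue_table <- function(trials, scene = scene_config()) {
  v <- kmh_to_ms(trials$comparison_speed)
  data.frame(speed = trials$comparison_speed,
             tta = trials$comparison_tta,
             start = v * (scene$display_duration + trials$comparison_tta),
             end = v * trials$comparison_tta)
}
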