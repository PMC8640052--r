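#' Mixed-model specification for the performance analysis
#'
#' Trial-level correctness is modelled by a logistic mixed model with the
#' gaze metrics of the full visible interval as fixed effects and
#' observer, comparison speed and comparison TTA as (categorical) random
#' factors. Random-effect covariances are diagonal (slopes uncorrelated
#' with intercepts).
#'
#' @param fixed fixed-effect predictor names.
#' @param random_factors grouping-factor column names.
#' @param slopes include random slopes (besides intercepts)?
#' @return `mixed_model_spec` object.
#' @export
mixed_model_spec <- function(fixed = c("gain", "n_saccades",
                                       "mean_amplitude", "rel_dev_h",
                                       "rel_dev_v", "abs_dev_h",
                                       "abs_dev_v"),
                             random_factors = c("participant_id",
                                                "comparison_speed_f",
                                                "comparison_tta_f"),
                             slopes = TRUE) {
  structure(list(fixed = fixed, random_factors = random_factors,
                 slopes = slopes), class = "mixed_model_spec")
}

mixed_formula <- function(spec, slopes = spec$slopes) {
  fx <- paste(spec$fixed, collapse = " + ")
  re <- vapply(spec$random_factors, function(g) {
    if (slopes) sprintf("(1 + %s || %s)", fx, g) else sprintf("(1 | %s)", g)
  }, "")
  as.formula(paste("correct ~", fx, "+", paste(re, collapse = " + ")))
}

#' Variance inflation factors of a fixed-effect design
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor j on
#' the remaining predictors.
#'
#' @param design data frame or matrix of predictors.
#' @return Named vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qx$pivot[-1] - 1)]
    stop("vif: rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, 0) |> setNames(colnames(X))
}

prepare_model_frame <- function(data, spec) {
  d <- as.data.frame(data)
  d <- d[stats::complete.cases(d[, c("correct", spec$fixed)]), ]
  if ("comparison_speed" %in% names(d))
    d$comparison_speed_f <- factor(d$comparison_speed)
  if ("comparison_tta" %in% names(d))
    d$comparison_tta_f <- factor(d$comparison_tta)
  scaling <- list()
  for (f in spec$fixed) {
    mu <- mean(d[[f]]); sdv <- sd(d[[f]])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    d[[f]] <- (d[[f]] - mu) / sdv
    scaling[[f]] <- c(mean = mu, sd = sdv)
  }
  d$correct <- as.integer(d$correct)
  attr(d, "scaling") <- scaling
  d
}

glmer_converged <- function(fit) {
  if (is.null(fit)) return(FALSE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  # a boundary (singular) fit is a converged fit with a zero variance
  # component, not an optimizer failure
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  warn <- fit@optinfo$warnings
  length(msgs) == 0 && length(warn) == 0
}

#' Fit the logistic mixed model (one rung of the ladder)
#'
#' Laplace-approximate ML fit via lme4 with diagonal random-effect
#' covariance; fixed-effect predictors are standardized first and
#' estimates reported on the standardized scale (the scaling is recorded).
#'
#' @param data data frame with `correct`, the fixed-effect metrics and the
#'   random-factor columns (`participant_id`, `comparison_speed`,
#'   `comparison_tta`).
#' @param spec a [mixed_model_spec()].
#' @param require_convergence if TRUE (default) a non-converged fit
#'   raises a condition of class `ladder_advance`.
#' @return Object of class `mixed_model_report`: coefficient table,
#'   random variances, loglik, AIC, VIFs, the fit, and the scaling.
#' @export
fit_mixed_logistic <- function(data, spec = mixed_model_spec(),
                               require_convergence = TRUE) {
  d <- prepare_model_frame(data, spec)
  for (g in spec$random_factors)
    if (length(unique(d[[g]])) < 2)
      stop("fit_mixed_logistic: random factor ", g, " has < 2 levels")
  fml <- mixed_formula(spec)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = d, family = binomial(),
                  control = lme4::glmerControl(calc.derivs = TRUE)))),
    error = function(e) NULL)
  conv <- glmer_converged(fit)
  if (!conv && require_convergence) {
    cond <- structure(class = c("ladder_advance", "error", "condition"),
                      list(message = "mixed model did not converge",
                           call = sys.call()))
    stop(cond)
  }
  if (is.null(fit)) stop("fit_mixed_logistic: model could not be fitted")
  cf <- summary(fit)$coefficients
  report <- structure(list(
    estimates = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    z = cf[, "z value"],
    p = cf[, "Pr(>|z|)"],
    random_variances = lapply(lme4::VarCorr(fit), function(v)
      diag(as.matrix(v))),
    loglik = as.numeric(logLik(fit)),
    aic = AIC(fit),
    vif = vif(d[, spec$fixed, drop = FALSE]),
    converged = conv,
    scaling = attr(d, "scaling"),
    formula = deparse1(fml),
    fit = fit), class = "mixed_model_report")
  report
}

#' @export
print.mixed_model_report <- function(x, ...) {
  cat("<mixed_model_report>", x$formula, "\n")
  tab <- cbind(Estimate = x$estimates, SE = x$se, z = x$z, p = x$p)
  print(round(tab, 3))
  cat(sprintf("  logLik %.1f, AIC %.1f, converged: %s\n",
              x$loglik, x$aic, x$converged))
  invisible(x)
}

#' Random-effects simplification ladder
#'
#' Tries, in order: (1) the full model with uncorrelated (diagonal)
#' intercepts and slopes for every random factor; (2) uncorrelated slopes
#' for the observer only, intercepts for the stimulus factors;
#' (3) intercepts only. Stops at the first converging rung and records the
#' log-likelihood/AIC of the converged model and of the next-simpler one
#' for comparison. If nothing converges, a plain logistic fit is returned
#' with a prominent flag.
#'
#' @param data as in [fit_mixed_logistic()].
#' @param spec a [mixed_model_spec()].
#' @return A `mixed_model_report` with `ladder_record` describing the path
#'   and `comparison` (logLik/AIC of the next-simpler rung, when
#'   available).
#' @export
simplify_ladder <- function(data, spec = mixed_model_spec()) {
  rungs <- list(
    full_uncorrelated = spec,
    observer_slopes_only = {
      s <- spec; s$slopes <- TRUE; s$slopes_only_first <- TRUE; s
    },
    intercepts_only = { s <- spec; s$slopes <- FALSE; s })
  attempted <- character(0)
  fit_rung <- function(name) {
    s <- rungs[[name]]
    if (isTRUE(s$slopes_only_first)) {
      # slopes on the first factor, intercepts elsewhere
      fx <- paste(s$fixed, collapse = " + ")
      re1 <- sprintf("(1 + %s || %s)", fx, s$random_factors[1])
      rei <- sprintf("(1 | %s)", s$random_factors[-1])
      fml <- as.formula(paste("correct ~", fx, "+",
                              paste(c(re1, rei), collapse = " + ")))
      d <- prepare_model_frame(data, s)
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::glmer(fml, data = d, family = binomial()))),
        error = function(e) NULL)
      if (!glmer_converged(fit)) return(NULL)
      rep <- fit_mixed_report_from(fit, d, s, fml)
      return(rep)
    }
    tryCatch(fit_mixed_logistic(data, s),
             ladder_advance = function(c) NULL,
             error = function(e) NULL)
  }
  result <- NULL
  for (name in names(rungs)) {
    attempted <- c(attempted, name)
    result <- fit_rung(name)
    if (!is.null(result)) break
  }
  if (is.null(result)) {
    # plain logistic fallback
    d <- prepare_model_frame(data, spec)
    fml <- as.formula(paste("correct ~",
                            paste(spec$fixed, collapse = " + ")))
    fit <- glm(fml, data = d, family = binomial())
    cf <- summary(fit)$coefficients
    result <- structure(list(
      estimates = cf[, 1], se = cf[, 2], z = cf[, 3], p = cf[, 4],
      random_variances = list(), loglik = as.numeric(logLik(fit)),
      aic = AIC(fit), vif = vif(d[, spec$fixed, drop = FALSE]),
      converged = TRUE, fallback_plain_logistic = TRUE,
      scaling = attr(d, "scaling"), formula = deparse1(fml), fit = fit),
      class = "mixed_model_report")
    warning("simplify_ladder: no mixed model converged; ",
            "plain logistic fallback used")
  }
  result$ladder_record <- attempted
  # next-simpler comparison
  conv_idx <- length(attempted)
  if (conv_idx < length(rungs) && is.null(result$fallback_plain_logistic)) {
    nxt <- fit_rung(names(rungs)[conv_idx + 1])
    if (!is.null(nxt))
      result$comparison <- c(loglik_next = nxt$loglik, aic_next = nxt$aic,
                             loglik = result$loglik, aic = result$aic)
  }
  result
}

fit_mixed_report_from <- function(fit, d, spec, fml) {
  cf <- summary(fit)$coefficients
  structure(list(
    estimates = cf[, "Estimate"], se = cf[, "Std. Error"],
    z = cf[, "z value"], p = cf[, "Pr(>|z|)"],
    random_variances = lapply(lme4::VarCorr(fit), function(v)
      diag(as.matrix(v))),
    loglik = as.numeric(logLik(fit)), aic = AIC(fit),
    vif = vif(d[, spec$fixed, drop = FALSE]),
    converged = TRUE, scaling = attr(d, "scaling"),
    formula = deparse1(fml), fit = fit), class = "mixed_model_report")
}
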