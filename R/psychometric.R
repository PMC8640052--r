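#' Cumulative-normal psychometric function
#'
#' `psi(x) = gamma + (1 - gamma - lambda) * Phi((x - pse) / sigma)`.
#'
#' @param x stimulus values.
#' @param pse point of subjective equality.
#' @param sigma slope parameter (stimulus units).
#' @param gamma guess rate (lower asymptote offset).
#' @param lambda lapse rate (upper asymptote offset).
#' @return Probabilities.
#' @export
psy_fun <- function(x, pse, sigma, gamma = 0, lambda = 0) {
  gamma + (1 - gamma - lambda) * pnorm((x - pse) / sigma)
}

psy_nll <- function(par, levels, k, n) {
  p <- psy_fun(levels, par[1], par[2], par[3], par[4])
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -sum(dbinom(k, n, p, log = TRUE))
}

#' Maximum-likelihood psychometric fit
#'
#' Fits the cumulative-normal psychometric function to binomial response
#' counts by maximum likelihood, with the PSE constrained to the stimulus
#' range, the guess rate to \[0, 0.05\] and the lapse rate to \[0, 0.1\].
#' A multistart over a coarse (PSE, sigma) grid guards against the local
#' optima that asymptote parameters create. The JND is half the distance
#' between the 25% and 75% points of the full function (asymptotes
#' included); its standard error comes from a parametric bootstrap.
#'
#' @param levels stimulus levels (>= 4 distinct).
#' @param k_chosen number of "faster"/"earlier" (target) responses.
#' @param n_trials trials per level.
#' @param guess_max,lapse_max asymptote bounds.
#' @param n_boot bootstrap replicates for `se_jnd` (0 to skip).
#' @param seed bootstrap seed.
#' @param start optional parameter vector (pse, sigma, gamma, lambda) used
#'   as the sole optimizer start (warm restarts, e.g. inside bootstraps).
#' @return Object of class `psy_fit`: `pse`, `sigma`, `gamma`, `lambda`,
#'   `jnd`, `se_jnd`, `loglik`, `deviance`, `uninformative` flag, data.
#' @export
fit_psychometric <- function(levels, k_chosen, n_trials,
                             guess_max = 0.05, lapse_max = 0.1,
                             n_boot = 200, seed = 1, start = NULL) {
  stopifnot(length(levels) == length(k_chosen),
            length(levels) == length(n_trials))
  if (length(unique(levels)) < 4)
    stop("fit_psychometric: need >= 4 distinct levels")
  if (any(n_trials < 1)) stop("fit_psychometric: n_trials must be >= 1")
  rng <- range(levels)
  span <- diff(rng)
  lower <- c(rng[1], span / 100, 0, 0)
  upper <- c(rng[2], span * 3, guess_max, lapse_max)

  starts <- expand.grid(
    pse = seq(rng[1], rng[2], length.out = 5),
    sigma = exp(seq(log(span / 30), log(span), length.out = 5)))
  start_list <- if (is.null(start)) {
    lapply(seq_len(nrow(starts)), function(s)
      c(starts$pse[s], starts$sigma[s], 0.01, 0.01))
  } else {
    list(pmin(upper, pmax(lower, start)))
  }
  best <- NULL
  for (s in seq_along(start_list)) {
    par0 <- start_list[[s]]
    fit <- tryCatch(
      optim(par0, psy_nll, levels = levels, k = k_chosen, n = n_trials,
            method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("fit_psychometric: optimization failed")
  par <- best$par
  names(par) <- c("pse", "sigma", "gamma", "lambda")
  ll <- -best$value
  phat <- k_chosen / n_trials
  ll_sat <- sum(dbinom(k_chosen, n_trials,
                       pmin(1 - 1e-12, pmax(1e-12, phat)), log = TRUE))
  dev <- 2 * (ll_sat - ll)
  # degenerate-data flag: the sigmoid explains no more than a constant
  # response probability (likelihood-ratio against the pooled-rate model)
  p_pool <- sum(k_chosen) / sum(n_trials)
  ll_const <- sum(dbinom(k_chosen, n_trials,
                         pmin(1 - 1e-12, pmax(1e-12, p_pool)), log = TRUE))
  uninformative <- 2 * (ll - ll_const) < qchisq(0.95, df = 3)

  fitobj <- structure(list(
    pse = par[["pse"]], sigma = par[["sigma"]],
    gamma = par[["gamma"]], lambda = par[["lambda"]],
    loglik = ll, deviance = dev, uninformative = uninformative,
    levels = levels, k = k_chosen, n = n_trials), class = "psy_fit")
  fitobj$jnd <- tryCatch(jnd(fitobj), error = function(e) NA_real_)
  fitobj$weber <- NA_real_

  if (n_boot > 0) {
    set.seed(seed)
    p <- psy_fun(levels, par[1], par[2], par[3], par[4])
    jnds <- replicate(n_boot, {
      kb <- rbinom(length(levels), n_trials, p)
      fb <- tryCatch(
        fit_psychometric(levels, kb, n_trials, guess_max, lapse_max,
                         n_boot = 0, start = unname(par)),
        error = function(e) NULL)
      if (is.null(fb)) NA_real_ else fb$jnd
    })
    fitobj$se_jnd <- sd(jnds, na.rm = TRUE)
    fitobj$boot_jnds <- jnds
  } else fitobj$se_jnd <- NA_real_
  fitobj
}

#' @export
print.psy_fit <- function(x, ...) {
  cat(sprintf(
    "<psy_fit> pse = %.3f, sigma = %.3f, gamma = %.3f, lambda = %.3f\n",
    x$pse, x$sigma, x$gamma, x$lambda))
  cat(sprintf("  jnd = %.3f (se %.3f), deviance = %.2f%s\n",
              x$jnd, x$se_jnd %||% NA, x$deviance,
              if (isTRUE(x$uninformative)) " [uninformative]" else ""))
  invisible(x)
}

#' Just-noticeable difference of a fitted psychometric function
#'
#' Half the distance between the stimulus values generating 75% and 25%
#' target responses, taking the asymptotes into account. If either
#' quantile is unreachable given the asymptotes, the JND is undefined.
#'
#' @param fit a `psy_fit` (or list with pse, sigma, gamma, lambda).
#' @return JND in stimulus units.
#' @export
jnd <- function(fit) {
  q <- function(p) {
    pr <- (p - fit$gamma) / (1 - fit$gamma - fit$lambda)
    if (pr <= 0 || pr >= 1)
      stop("jnd undefined: quantile outside the asymptote range")
    fit$pse + fit$sigma * qnorm(pr)
  }
  (q(0.75) - q(0.25)) / 2
}

#' Weber fraction
#'
#' @param jnd just-noticeable difference, stimulus units.
#' @param standard the standard stimulus magnitude (> 0).
#' @return `jnd / standard`.
#' @export
weber <- function(jnd, standard) {
  if (any(standard <= 0)) stop("weber: standard must be positive")
  jnd / standard
}

#' Deviance goodness of fit with bootstrap p-value
#'
#' Deviance is twice the log-likelihood gap between the saturated model
#' and the fit; its null distribution is obtained by parametric bootstrap
#' from the fitted function.
#'
#' @param fit a `psy_fit`.
#' @param n_boot bootstrap replicates.
#' @param seed seed.
#' @return List `deviance`, `p` (fraction of bootstrap deviances >= observed).
#' @export
deviance_gof <- function(fit, n_boot = 1000, seed = 1) {
  set.seed(seed)
  p0 <- psy_fun(fit$levels, fit$pse, fit$sigma, fit$gamma, fit$lambda)
  devs <- replicate(n_boot, {
    kb <- rbinom(length(fit$levels), fit$n, p0)
    fb <- tryCatch(
      fit_psychometric(fit$levels, kb, fit$n, n_boot = 0,
                       start = c(fit$pse, fit$sigma, fit$gamma,
                                 fit$lambda)),
      error = function(e) NULL)
    if (is.null(fb)) NA_real_ else fb$deviance
  })
  list(deviance = fit$deviance, p = mean(devs >= fit$deviance, na.rm = TRUE))
}

#' Aggregate a session's responses onto the comparison-stimulus axis
#'
#' For the speed task the proportion of "chose comparison (faster)"
#' responses per comparison speed; for the TTA task the proportion judged
#' "later" (the complement of "earlier") per comparison TTA, so the fitted
#' function is increasing in both tasks; the JND is unaffected and the PSE
#' lives on the same axis.
#'
#' @param trials trial tibble with responses (see [simulate_responses()]).
#' @param task `"speed"` or `"tta"`.
#' @return List `levels`, `k`, `n`.
#' @export
psychometric_data <- function(trials, task = c("speed", "tta")) {
  task <- match.arg(task)
  tr <- trials[trials$task == task, ]
  if (task == "speed") {
    lev <- sort(unique(tr$comparison_speed))
    k <- vapply(lev, function(l)
      sum(tr$chose_comparison[tr$comparison_speed == l]), 0L)
    n <- vapply(lev, function(l) sum(tr$comparison_speed == l), 0L)
  } else {
    lev <- sort(unique(tr$comparison_tta))
    k <- vapply(lev, function(l)
      sum(!tr$chose_comparison[tr$comparison_tta == l]), 0L)
    n <- vapply(lev, function(l) sum(tr$comparison_tta == l), 0L)
  }
  list(levels = lev, k = as.integer(k), n = as.integer(n))
}

#' Interval-bias psychometric fit
#'
#' Recode responses as "chose the second interval" and regress on the
#' stimulus value shown in the second interval; a PSE shifted away from
#' the standard indicates a temporal-order (interval) bias. For the TTA
#' task the "second judged later" proportion is fitted so that the curve
#' increases with the second interval's TTA.
#'
#' @param trials trial tibble with responses.
#' @param task `"speed"` or `"tta"`.
#' @param standard the standard stimulus value.
#' @param ... passed to [fit_psychometric()].
#' @return A `psy_fit` plus a `bias` element (standard - PSE; positive =
#'   preference to call the second interval faster/earlier).
#' @export
interval_bias_fit <- function(trials, task = c("speed", "tta"),
                              standard = NULL, ...) {
  task <- match.arg(task)
  tr <- trials[trials$task == task, ]
  if (is.null(standard)) standard <- if (task == "speed") 50 else 3.04
  val2 <- if (task == "speed") {
    ifelse(tr$standard_first, tr$comparison_speed, standard)
  } else {
    ifelse(tr$standard_first, tr$comparison_tta, standard)
  }
  target <- if (task == "speed") tr$chose_interval2 else !tr$chose_interval2
  lev <- sort(unique(val2))
  k <- vapply(lev, function(l) sum(target[val2 == l]), 0L)
  n <- vapply(lev, function(l) sum(val2 == l), 0L)
  fit <- fit_psychometric(lev, as.integer(k), as.integer(n), ...)
  # positive bias = propensity to pick the second interval ("faster" needs
  # less speed in interval 2; "earlier" tolerated at a later true TTA)
  fit$bias <- if (task == "speed") standard - fit$pse else fit$pse - standard
  fit
}
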