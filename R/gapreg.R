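#' Arm-stratified Bayesian regression of one gap time on the previous one
#'
#' Fits, within one arm, the simple linear regression of the
#' progression-to-death gap on the relapse-to-progression gap (raw days by
#' default; a log-scale option is available), with mean-zero Gaussian priors
#' on intercept and slope and a vague Gamma prior on the residual precision,
#' by conjugate Gibbs sampling. With a vague prior the posterior mean equals
#' the ordinary least-squares solution. Only complete-case records (all
#' three events observed) enter the fit.
#'
#' This is a lag-1 regression across ordered gaps *within* subjects — the
#' dependency structure between consecutive gap times — not a time-series
#' autoregression.
#'
#' @param cohort A [gap_cohort()].
#' @param arm Arm code (0 or 1) to fit.
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param log_scale Regress log gaps instead of raw gaps (default `FALSE`;
#'   the dependency model is stated on raw gap times).
#' @param predictor_gap,response_gap Which gaps link (defaults: gap 2,
#'   relapse to progression, predicts gap 3, progression to death).
#' @return Object of class `gap_regression_fit`: posterior means
#'   `intercept`, `slope`, `sigma`, the [posterior_draws()], a
#'   [summarize_draws()] summary (DIC/pD on the normal deviance), the exact
#'   `conditional` posterior of the coefficients at the posterior-mean
#'   residual SD, `n`, and the training pairs.
#' @export
fit_gap_regression <- function(cohort, arm, prior = prior_spec(),
                               mcmc = mcmc_settings(), log_scale = FALSE,
                               predictor_gap = 2L, response_gap = 3L) {
  stopifnot(inherits(cohort, "gap_cohort"), arm %in% c(0, 1))
  gaps <- cohort_gap_times(complete_case_subset(cohort))
  gaps <- gaps[gaps$arm == arm, , drop = FALSE]
  g_pred <- gaps[[paste0("gap", predictor_gap)]]
  g_resp <- gaps[[paste0("gap", response_gap)]]
  if (length(g_pred) < 3L)
    stop("need at least 3 complete-case records in arm ", arm)
  if (stats::sd(g_pred) == 0)
    stop("predictor gap has zero variance in arm ", arm)
  if (log_scale) {
    g_pred <- log(g_pred)
    g_resp <- log(g_resp)
  }
  X <- cbind(intercept = 1, slope = g_pred)
  draws <- bayes_lm_gibbs(g_resp, X, prior, mcmc,
                          par_names = c("intercept", "slope"))
  dev_fn <- function(th)
    -2 * sum(stats::dnorm(g_resp, th[1L] + th[2L] * g_pred, th[3L],
                          log = TRUE))
  summ <- summarize_draws(draws, deviance_fn = dev_fn)
  # exact conditional posterior of (intercept, slope) at the posterior-mean
  # residual SD; with a vague prior this is the least-squares solution
  cond <- bayes_lm_conditional(g_resp, X,
                               summ$mean[summ$parameter == "sigma"],
                               1 / prior_variance(prior))
  structure(
    list(intercept = summ$mean[summ$parameter == "intercept"],
         slope = summ$mean[summ$parameter == "slope"],
         sigma = summ$mean[summ$parameter == "sigma"],
         draws = draws, summary = summ, conditional = cond,
         arm = arm, n = length(g_resp), log_scale = log_scale,
         data = data.frame(predictor = g_pred, response = g_resp)),
    class = "gap_regression_fit"
  )
}

#' @export
print.gap_regression_fit <- function(x, ...) {
  cat(sprintf("Gap-dependency regression, arm %d (n = %d%s)\n",
              x$arm, x$n, if (x$log_scale) ", log scale" else ""))
  print(x$summary)
  invisible(x)
}

#' Posterior of the between-arm slope difference
#'
#' Element-wise difference of the two arms' slope draws (independent chains
#' aligned by draw index — legitimate because the arms are fit on disjoint
#' data, so draws are exchangeable). The posterior of
#' `slope(arm 1) - slope(arm 0)` measures how much the dependent gap time's
#' response to the previous gap changes with the arm.
#'
#' @param fit0,fit1 `gap_regression_fit` objects for arms 0 and 1.
#' @return Object of class `arm_effect_difference`: difference draws, mean,
#'   SD, 95% HPD, `p_greater_0` (posterior probability the difference
#'   exceeds 0), and a kernel-density table (`grid`, `density`) for
#'   plotting.
#' @export
arm_effect_difference <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "gap_regression_fit"),
            inherits(fit1, "gap_regression_fit"))
  s0 <- fit0$draws$draws[, "slope"]
  s1 <- fit1$draws$draws[, "slope"]
  if (length(s0) != length(s1))
    stop("mismatched draw counts between arms (", length(s0), " vs ",
         length(s1), "); refit with identical MCMC settings")
  d <- s1 - s0
  dens <- stats::density(d)
  structure(
    list(draws = d, mean = mean(d), sd = stats::sd(d),
         hpd = hpd_interval(d),
         p_greater_0 = mean(d > 0),
         density = data.frame(grid = dens$x, density = dens$y)),
    class = "arm_effect_difference"
  )
}

#' @export
print.arm_effect_difference <- function(x, ...) {
  cat(sprintf(
    "Slope difference (arm 1 - arm 0): mean %.3f (SD %.3f), 95%% HPD (%.3f, %.3f)\n",
    x$mean, x$sd, x$hpd[1L], x$hpd[2L]))
  cat(sprintf("P(difference > 0) = %.3f\n", x$p_greater_0))
  invisible(x)
}

#' Combined arm inference from the AFT and dependency models
#'
#' Joins the two routes by which the arm acts on the gap-time process:
#' (i) the AFT arm effect on the first modelled gap, (ii) the between-arm
#' difference of dependency slopes, and (iii) their draw-wise sum as the
#' combined arm signal. Draws are aligned by index; if the two inputs carry
#' different draw counts the common prefix is used.
#'
#' @param aft_fit An [fit_aft_bayes()] result for the first modelled gap.
#' @param diff An [arm_effect_difference()].
#' @return Object of class `combined_arm_report`: a data frame `table` with
#'   rows `aft_arm_effect`, `slope_difference`, `combined` (mean, SD, 95%
#'   HPD each) and the combined draws.
#' @export
combined_arm_inference <- function(aft_fit, diff) {
  stopifnot(inherits(aft_fit, "aft_fit"),
            inherits(diff, "arm_effect_difference"))
  a <- aft_fit$draws$draws[, "arm"]
  d <- diff$draws
  n <- min(length(a), length(d))
  if (length(a) != length(d))
    warning("draw counts differ; using the first ", n, " draws of each")
  a <- a[seq_len(n)]
  d <- d[seq_len(n)]
  comb <- a + d
  row_of <- function(x) {
    h <- hpd_interval(x)
    c(mean = mean(x), sd = stats::sd(x), hpd_lower = h[[1L]],
      hpd_upper = h[[2L]])
  }
  tab <- rbind(aft_arm_effect = row_of(a),
               slope_difference = row_of(d),
               combined = row_of(comb))
  structure(list(table = as.data.frame(tab), combined_draws = comb),
            class = "combined_arm_report")
}

#' @export
print.combined_arm_report <- function(x, ...) {
  cat("Combined arm inference (AFT effect + dependency-slope difference)\n")
  print(round(x$table, 3))
  invisible(x)
}

#' Predict the next gap time from the previous one
#'
#' Posterior-predictive distribution of the dependent gap given the
#' previous gap: for each posterior draw `(b0, b1, sigma)` the prediction is
#' `b0 + b1 * g1` plus normal residual noise, so the interval reflects both
#' parameter uncertainty and residual spread.
#'
#' @param g1 Previous gap time(s), > 0 (vectorised).
#' @param fit A [fit_gap_regression()] result.
#' @param level Interval coverage (default 0.95).
#' @param seed Seed for the predictive noise draws.
#' @return Data frame with `g1`, posterior-predictive `mean`, and
#'   `lower`/`upper` interval bounds, one row per element of `g1`.
#' @export
predict_next_gap <- function(g1, fit, level = 0.95, seed = 20741L) {
  stopifnot(inherits(fit, "gap_regression_fit"), all(g1 > 0),
            level > 0, level < 1)
  b0 <- fit$draws$draws[, "intercept"]
  b1 <- fit$draws$draws[, "slope"]
  sg <- fit$draws$draws[, "sigma"]
  ndraw <- length(b0)
  a <- (1 - level) / 2
  with_seed(seed, {
    out <- do.call(rbind, lapply(g1, function(g) {
      m <- b0 + b1 * g
      pred <- m + sg * stats::rnorm(ndraw)
      q <- stats::quantile(pred, c(a, 1 - a), names = FALSE)
      data.frame(g1 = g, mean = mean(m), lower = q[1L], upper = q[2L])
    }))
    out
  })
}
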