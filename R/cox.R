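# Prepared Cox data: subjects sorted by decreasing time so risk-set sums are
# cumulative sums; ties share a denominator via the last index of their group.
cox_prepare <- function(time, event, Z) {
  Z <- as.matrix(Z)
  stopifnot(length(time) == length(event), nrow(Z) == length(time))
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  if (sum(event) == 0) stop("no events in the data")
  ord <- order(time, decreasing = TRUE)
  t_ord <- time[ord]
  # last index of each tied block (times sorted decreasing, ties contiguous)
  tie_last <- ave(seq_along(t_ord), match(t_ord, unique(t_ord)),
                  FUN = max)
  ev_ord <- event[ord]
  list(time = t_ord, event = ev_ord, Z = Z[ord, , drop = FALSE],
       tie_last = tie_last, E = which(ev_ord == 1),
       p = ncol(Z), n = length(time))
}

# log partial likelihood only (hot path for the Metropolis sampler)
cox_ll <- function(beta, pd) {
  eta <- drop(pd$Z %*% beta)
  S0 <- cumsum(exp(eta))[pd$tie_last]
  sum(eta[pd$E]) - sum(log(S0[pd$E]))
}

# Breslow partial log-likelihood with gradient and Hessian.
cox_ngr <- function(beta, pd) {
  Z <- pd$Z
  p <- pd$p
  eta <- drop(Z %*% beta)
  w <- exp(eta)
  S0 <- cumsum(w)[pd$tie_last]
  S1 <- apply(Z * w, 2, cumsum)[pd$tie_last, , drop = FALSE]
  E <- which(pd$event == 1)
  ll <- sum(eta[E]) - sum(log(S0[E]))
  Zbar <- S1[E, , drop = FALSE] / S0[E]
  grad <- colSums(Z[E, , drop = FALSE] - Zbar)
  hess <- matrix(0, p, p)
  for (j in seq_len(p)) {
    for (k in j:p) {
      S2jk <- cumsum(Z[, j] * Z[, k] * w)[pd$tie_last]
      hjk <- -sum(S2jk[E] / S0[E] - Zbar[, j] * Zbar[, k])
      hess[j, k] <- hjk
      hess[k, j] <- hjk
    }
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

# Efron-tied partial log-likelihood (value only; used when ties = "efron").
cox_loglik_efron <- function(beta, time, event, Z) {
  Z <- as.matrix(Z)
  eta <- drop(Z %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    s_all <- sum(w[R])
    s_tied <- sum(w[D])
    ll <- ll + sum(eta[D]) -
      sum(log(s_all - (seq_len(d) - 1) / d * s_tied))
  }
  ll
}

#' Cox partial log-likelihood
#'
#' Breslow-tied log partial likelihood of a proportional-hazards model.
#' At `beta = 0` it equals minus the sum, over events, of the log risk-set
#' size (ties counted with a shared denominator). Efron's tie correction is
#' available by flag.
#'
#' @param beta Coefficient vector (one per covariate column).
#' @param time Follow-up times (>= 0).
#' @param event 0/1 event indicators; at least one event required.
#' @param covariates Numeric matrix (or data frame) of covariate columns.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Scalar log partial likelihood.
#' @export
cox_partial_loglik <- function(beta, time, event, covariates,
                               ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  Z <- as.matrix(covariates)
  if (ties == "efron") {
    if (sum(event) == 0) stop("no events in the data")
    if (any(time < 0)) stop("negative follow-up time")
    return(cox_loglik_efron(beta, time, event, Z))
  }
  pd <- cox_prepare(time, event, Z)
  cox_ngr(beta, pd)$loglik
}

#' Maximum partial likelihood Cox fit (Newton-Raphson)
#'
#' Maximises the Breslow partial likelihood by Newton-Raphson with
#' step-halving, returning Wald 95% confidence intervals from the inverse
#' observed information. Monotone likelihood (separation) is detected when a
#' coefficient diverges and reported as an error.
#'
#' @param time,event,covariates As in [cox_partial_loglik()].
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Iteration cap.
#' @return Object of class `cox_fit` with `coefficients`, `covariance`,
#'   `se`, `ci` (Wald 95%), `loglik`, `loglik_null`, `aic`, `mode = "mle"`,
#'   `iterations`, `grad_norm`.
#' @export
fit_cox_mle <- function(time, event, covariates, tol = 1e-9,
                        max_iter = 50L) {
  Z <- as.matrix(covariates)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  pd <- cox_prepare(time, event, Z)
  if (sum(event) < ncol(Z))
    stop("fewer events than covariates; model not identifiable")
  beta <- rep(0, pd$p)
  cur <- cox_ngr(beta, pd)
  ll0 <- cur$loglik
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$gradient)) < tol) break
    step <- tryCatch(solve(cur$hessian, cur$gradient),
                     error = function(e) stop(
                       "singular information matrix; check for collinear ",
                       "covariates"))
    cand <- beta - step
    nxt <- cox_ngr(cand, pd)
    halvings <- 0L
    while ((!is.finite(nxt$loglik) || nxt$loglik < cur$loglik) &&
           halvings < 30L) {
      cand <- (beta + cand) / 2
      nxt <- cox_ngr(cand, pd)
      halvings <- halvings + 1L
    }
    beta <- cand
    cur <- nxt
    if (any(abs(beta) > 20))
      stop("monotone partial likelihood detected (coefficient diverging); ",
           "the data separate and no finite MLE exists")
  }
  if (max(abs(cur$gradient)) >= max(tol, 1e-6))
    stop("Newton-Raphson failed to converge in ", max_iter, " iterations")
  covm <- solve(-cur$hessian)
  dimnames(covm) <- list(colnames(Z), colnames(Z))
  se <- stats::setNames(sqrt(diag(covm)), colnames(Z))
  names(beta) <- colnames(Z)
  ci <- cbind(lower = beta - 1.959963984540054 * se,
              upper = beta + 1.959963984540054 * se)
  rownames(ci) <- colnames(Z)
  structure(
    list(coefficients = beta, covariance = covm, se = se, ci = ci,
         loglik = cur$loglik, loglik_null = ll0,
         aic = aic(cur$loglik, pd$p), mode = "mle", iterations = it,
         grad_norm = max(abs(cur$gradient)),
         data = list(time = time, event = event, Z = Z)),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards fit (%s)\n", x$mode))
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    lower95 = x$ci[, "lower"], upper95 = x$ci[, "upper"])
  print(round(tab, digits))
  cat(sprintf("log partial likelihood %.3f", x$loglik))
  if (x$mode == "mle") cat(sprintf("  AIC %.2f", x$aic))
  if (x$mode == "bayes" && !is.null(x$summary))
    cat(sprintf("  DIC %.2f  pD %.2f",
                attr(x$summary, "dic"), attr(x$summary, "pd")))
  cat("\n")
  invisible(x)
}

#' Bayesian Cox fit by random-walk Metropolis on the partial likelihood
#'
#' Samples the posterior proportional to the Breslow partial likelihood
#' times independent mean-zero Gaussian coefficient priors, using
#' component-wise random-walk Metropolis. Proposal scales adapt towards a
#' 20-50% acceptance rate during burn-in only, so the retained chain is a
#' valid Markov chain. The baseline hazard is left unmodelled (the
#' partial-likelihood posterior), matching a covariate-effects-only report.
#'
#' @param time,event,covariates As in [cox_partial_loglik()].
#' @param prior A [prior_spec()]; default vague (precision 0.001).
#' @param mcmc An [mcmc_settings()].
#' @return A `cox_fit` with `mode = "bayes"`: posterior means as
#'   `coefficients`, posterior covariance, per-parameter [summarize_draws()]
#'   summary (with DIC/pD on the partial-likelihood deviance), and the
#'   [posterior_draws()] in `draws`.
#' @export
fit_cox_bayes <- function(time, event, covariates, prior = prior_spec(),
                          mcmc = mcmc_settings()) {
  Z <- as.matrix(covariates)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  pd <- cox_prepare(time, event, Z)
  p <- pd$p
  sd0 <- sqrt(prior_variance(prior))
  logpost <- function(beta)
    cox_ll(beta, pd) + sum(stats::dnorm(beta, 0, sd0, log = TRUE))
  n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  all_draws <- matrix(NA_real_, n_keep * mcmc$n_chains, p,
                      dimnames = list(NULL, colnames(Z)))
  chain_id <- integer(n_keep * mcmc$n_chains)
  acc_all <- numeric(p)
  with_seed(mcmc$seed, {
    for (ch in seq_len(mcmc$n_chains)) {
      beta <- stats::rnorm(p, 0, 0.1)       # overdispersed chain starts
      lp <- logpost(beta)
      scales <- rep(0.2, p)
      acc_win <- integer(p)
      acc_post <- integer(p)
      kept <- 0L
      for (it in seq_len(mcmc$n_iter)) {
        for (j in seq_len(p)) {
          cand <- beta
          cand[j] <- beta[j] + stats::rnorm(1, 0, scales[j])
          lp_cand <- logpost(cand)
          if (is.finite(lp_cand) &&
              log(stats::runif(1)) < lp_cand - lp) {
            beta <- cand
            lp <- lp_cand
            acc_win[j] <- acc_win[j] + 1L
            if (it > mcmc$burn_in) acc_post[j] <- acc_post[j] + 1L
          }
        }
        # adapt proposal scales during burn-in only (target ~35% acceptance)
        if (it <= mcmc$burn_in && it %% 50L == 0L) {
          rate <- acc_win / 50
          scales <- scales * exp(rate - 0.35)
          scales <- pmin(pmax(scales, 1e-4), 10)
          acc_win <- integer(p)
        }
        if (it > mcmc$burn_in &&
            (it - mcmc$burn_in) %% mcmc$thin == 0L) {
          kept <- kept + 1L
          row <- (ch - 1L) * n_keep + kept
          all_draws[row, ] <- beta
          chain_id[row] <- ch
        }
      }
      acc_all <- acc_all + acc_post / (mcmc$n_iter - mcmc$burn_in)
    }
  })
  acc_all <- acc_all / mcmc$n_chains
  names(acc_all) <- colnames(Z)
  if (all(acc_all == 0)) stop("Metropolis chain rejected every proposal")
  draws <- posterior_draws(all_draws, chain_id, seed = mcmc$seed,
                           acceptance = acc_all)
  dev_fn <- function(beta) -2 * cox_ll(beta, pd)
  summ <- summarize_draws(draws, deviance_fn = dev_fn)
  post_mean <- stats::setNames(summ$mean, summ$parameter)
  covm <- stats::cov(all_draws)
  structure(
    list(coefficients = post_mean, covariance = covm,
         se = stats::setNames(summ$sd, summ$parameter),
         ci = matrix(c(summ$hpd_lower, summ$hpd_upper), ncol = 2,
                     dimnames = list(summ$parameter, c("lower", "upper"))),
         loglik = cox_ngr(post_mean, pd)$loglik,
         mode = "bayes", draws = draws, summary = summ,
         acceptance = acc_all,
         data = list(time = time, event = event, Z = Z)),
    class = "cox_fit"
  )
}

#' Kolmogorov-type supremum test of proportional hazards
#'
#' Lin-Wei-Ying-style check: the observed supremum of the standardised
#' cumulative score process (each component scaled by the square root of
#' its diagonal information) is compared against `n_resample` realisations
#' simulated with standard-normal multipliers on the per-event score
#' contributions, with the usual information correction. The p-value per
#' covariate is the fraction of simulated suprema at or above the observed
#' one.
#'
#' @param fit An MLE `cox_fit` from [fit_cox_mle()].
#' @param n_resample Number of multiplier realisations (>= 100).
#' @param seed Integer seed; fixed seed gives identical p-values.
#' @return Object of class `sup_ph_test`: per-covariate observed suprema and
#'   p-values.
#' @export
supremum_ph_test <- function(fit, n_resample = 1000L, seed = 20741L) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$mode != "mle")
    stop("supremum_ph_test requires a maximum-likelihood fit")
  if (n_resample < 100L) stop("n_resample must be at least 100")
  time <- fit$data$time
  event <- fit$data$event
  Z <- fit$data$Z
  p <- ncol(Z)
  beta <- fit$coefficients
  # event-ordered score residuals and running information
  ord <- order(time)
  tt <- time[ord]; ee <- event[ord]; ZZ <- Z[ord, , drop = FALSE]
  w <- exp(drop(ZZ %*% beta))
  E <- which(ee == 1)
  m <- length(E)
  r <- matrix(0, m, p)              # Z_i - Zbar(t_i) at each event
  Imat <- matrix(0, m, p * p)       # running information I(t_k), vectorised
  Icum <- matrix(0, p, p)
  for (k in seq_len(m)) {
    i <- E[k]
    # risk set: everyone with time >= t_i (earlier-indexed ties included)
    first_tie <- i
    while (first_tie > 1L && tt[first_tie - 1L] == tt[i])
      first_tie <- first_tie - 1L
    R <- first_tie:length(tt)
    wR <- w[R]
    S0 <- sum(wR)
    zbar <- colSums(ZZ[R, , drop = FALSE] * wR) / S0
    r[k, ] <- ZZ[i, ] - zbar
    Zc <- sweep(ZZ[R, , drop = FALSE], 2, zbar)
    Icum <- Icum + crossprod(Zc, Zc * wR) / S0
    Imat[k, ] <- as.numeric(Icum)
  }
  I_tau <- matrix(Imat[m, ], p, p)
  sd_tau <- sqrt(diag(I_tau))
  U_obs <- apply(r, 2, cumsum)
  if (m == 1L) U_obs <- matrix(U_obs, 1L, p)
  sup_obs <- apply(abs(U_obs), 2, max) / sd_tau
  A <- solve(I_tau)
  exceed <- numeric(p)
  with_seed(seed, {
    for (b in seq_len(n_resample)) {
      G <- stats::rnorm(m)
      s <- r * G
      cumS <- apply(s, 2, cumsum)
      if (m == 1L) cumS <- matrix(cumS, 1L, p)
      ctot <- A %*% colSums(s)
      corr <- matrix(0, m, p)
      for (j in seq_len(p))
        corr[, j] <- Imat[, ((j - 1L) * p + 1L):(j * p), drop = FALSE] %*%
          ctot
      sup_b <- apply(abs(cumS - corr), 2, max) / sd_tau
      exceed <- exceed + (sup_b >= sup_obs)
    }
  })
  structure(
    list(sup_observed = stats::setNames(sup_obs, colnames(Z)),
         p_value = stats::setNames(exceed / n_resample, colnames(Z)),
         n_resample = n_resample, seed = seed),
    class = "sup_ph_test"
  )
}

#' @export
print.sup_ph_test <- function(x, ...) {
  cat("Kolmogorov-type supremum test of proportional hazards\n")
  print(data.frame(supremum = round(x$sup_observed, 3),
                   p_value = x$p_value))
  invisible(x)
}

#' Design matrix for endpoint Cox models
#'
#' Builds the Arm + Age + Gender covariate matrix from a cohort. Age enters
#' either standardised (mean 0, SD 1; the default, since a coefficient per
#' year and per SD differ only by scale) or binarised at the cohort median.
#'
#' @param cohort A [gap_cohort()].
#' @param covariates Covariate names among `arm`, `age`, `gender`.
#' @param age_coding `"standardized"` (default) or `"binary"` (above-median
#'   indicator).
#' @return Numeric matrix with one named column per covariate.
#' @export
cox_design <- function(cohort, covariates = c("arm", "age", "gender"),
                       age_coding = c("standardized", "binary")) {
  age_coding <- match.arg(age_coding)
  stopifnot(all(covariates %in% c("arm", "age", "gender")))
  cols <- lapply(covariates, function(cv) {
    x <- cohort[[cv]]
    if (cv == "age") {
      if (age_coding == "standardized") {
        s <- stats::sd(x)
        if (s == 0) s <- 1
        x <- (x - mean(x)) / s
      } else {
        x <- as.numeric(x > stats::median(x))
      }
    }
    x
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Fit a Cox model for a trial endpoint
#'
#' Convenience wrapper: extracts the endpoint's time/indicator columns,
#' builds the Arm/Age/Gender design via [cox_design()], and fits by maximum
#' partial likelihood, Metropolis posterior sampling, or both.
#'
#' @param cohort A [gap_cohort()].
#' @param endpoint `"LRC"`, `"PFS"` or `"OS"`.
#' @param covariates,age_coding Passed to [cox_design()].
#' @param mode `"mle"`, `"bayes"`, or `"both"`.
#' @param prior,mcmc Passed to [fit_cox_bayes()].
#' @return A `cox_fit` (or, for `mode = "both"`, a list with elements
#'   `mle` and `bayes`).
#' @export
fit_cox_endpoint <- function(cohort, endpoint,
                             covariates = c("arm", "age", "gender"),
                             mode = c("both", "mle", "bayes"),
                             prior = prior_spec(), mcmc = mcmc_settings(),
                             age_coding = "standardized") {
  mode <- match.arg(mode)
  dat <- endpoint_data(cohort, endpoint)
  Z <- cox_design(cohort, covariates, age_coding)
  if (mode == "mle")
    return(fit_cox_mle(dat$time, dat$event, Z))
  if (mode == "bayes")
    return(fit_cox_bayes(dat$time, dat$event, Z, prior, mcmc))
  list(mle = fit_cox_mle(dat$time, dat$event, Z),
       bayes = fit_cox_bayes(dat$time, dat$event, Z, prior, mcmc))
}
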