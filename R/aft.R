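#' Log-normal AFT log-likelihood
#'
#' Log-likelihood of gap times under the accelerated failure time model
#' `log(G) = mu + beta * x + sigma * e`, `e ~ N(0, 1)`: the sum of
#' log-normal log-densities, i.e. the normal log-density of the log gaps
#' minus the `sum(log(gap))` Jacobian.
#'
#' @param mu Intercept on the log-time scale.
#' @param beta Arm coefficient on the log-time scale.
#' @param scale Residual SD `sigma` on the log-time scale (> 0).
#' @param gaps Strictly positive gap times (days).
#' @param x Arm codes (0/1), same length as `gaps`.
#' @return Scalar log-likelihood.
#' @export
aft_loglik <- function(mu, beta, scale, gaps, x) {
  stopifnot(length(gaps) == length(x), scale > 0)
  if (any(gaps <= 0)) stop("gap times must be strictly positive")
  sum(stats::dlnorm(gaps, meanlog = mu + beta * x, sdlog = scale,
                    log = TRUE))
}

#' AFT survival function
#'
#' Survival probability under the log-normal AFT model: the baseline
#' survival evaluated at `exp(-(mu + beta * x)) * t`, which for normal
#' errors equals `1 - Phi((log t - mu - beta x) / sigma)`.
#'
#' @param t Time (>= 0); vectorised.
#' @param x Arm code.
#' @param mu,beta,scale AFT parameters as in [aft_loglik()].
#' @return Survival probability in `[0, 1]` (1 at `t = 0`).
#' @export
aft_survival <- function(t, x, mu, beta, scale) {
  stopifnot(all(t >= 0), scale > 0)
  1 - stats::pnorm((log(t) - mu - beta * x) / scale)
}

#' Bayesian log-normal AFT fit for one gap time by Gibbs sampling
#'
#' Fits `log(G) = mu + beta * arm + e`, `e ~ N(0, sigma^2)` with independent
#' mean-zero Gaussian priors on `(mu, beta)` and a vague Gamma prior on the
#' precision `1/sigma^2`, via the exact conjugate full conditionals (Gibbs
#' sampling). The residual scale `sigma` is estimated and reported as the
#' model's third parameter.
#'
#' @param gaps Strictly positive gap times.
#' @param x Arm codes (0/1); both arms must be present with at least two
#'   subjects each.
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param sigma_known Optional fixed residual SD; when given, only
#'   `(mu, beta)` are sampled and their exact conditional posterior is also
#'   returned in `conditional` (vague prior: ordinary least squares).
#' @return Object of class `aft_fit`: posterior means `mu`, `beta`, `scale`,
#'   the [posterior_draws()], and a [summarize_draws()] summary with DIC/pD
#'   on the full log-normal deviance.
#' @export
fit_aft_bayes <- function(gaps, x, prior = prior_spec(),
                          mcmc = mcmc_settings(), sigma_known = NULL) {
  stopifnot(length(gaps) == length(x))
  if (any(gaps <= 0)) stop("gap times must be strictly positive")
  if (length(unique(x)) < 2L)
    stop("single-arm data: the arm effect is not identifiable")
  if (any(table(x) < 2L)) stop("need at least 2 subjects per arm")
  y <- log(gaps)
  X <- cbind(intercept = 1, arm = x)
  draws <- bayes_lm_gibbs(y, X, prior, mcmc, sigma_known = sigma_known,
                          par_names = c("intercept", "arm"))
  if (!is.null(sigma_known)) {
    dev_fn <- function(th) -2 * aft_loglik(th[1L], th[2L], sigma_known,
                                           gaps, x)
  } else {
    dev_fn <- function(th) -2 * aft_loglik(th[1L], th[2L], th[3L], gaps, x)
  }
  summ <- summarize_draws(draws, deviance_fn = dev_fn)
  cond <- if (!is.null(sigma_known))
    bayes_lm_conditional(y, X, sigma_known, 1 / prior_variance(prior))
  structure(
    list(mu = summ$mean[summ$parameter == "intercept"],
         beta = summ$mean[summ$parameter == "arm"],
         scale = if (is.null(sigma_known))
           summ$mean[summ$parameter == "sigma"] else sigma_known,
         draws = draws, summary = summ, conditional = cond,
         n = length(gaps), sigma_known = sigma_known),
    class = "aft_fit"
  )
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("Bayesian log-normal AFT fit (n = %d)\n", x$n))
  print(x$summary)
  invisible(x)
}
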