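#' Prior specification for Bayesian fits
#'
#' All Bayesian models in gapsurv place independent Gaussian priors with
#' mean 0 on regression coefficients (and intercepts), and a vague Gamma
#' prior on residual precision where a scale parameter is estimated.
#'
#' The headline Gaussian hyperparameter is given as `0.001` in the OpenBUGS
#' tradition, where `dnorm(0, 0.001)` is parameterised by *precision*, i.e.
#' variance 1000 — an essentially flat prior. Because the value is sometimes
#' misread as a variance (an extremely informative prior that would pin all
#' coefficients at zero), both interpretations are selectable.
#'
#' @param value Gaussian hyperparameter for coefficient priors (default
#'   `0.001`).
#' @param interpretation Either `"precision"` (default; variance is
#'   `1/value`) or `"variance"` (variance is `value` itself).
#' @param gamma_shape,gamma_rate Shape and rate of the Gamma prior on the
#'   residual precision `1/sigma^2` in models that estimate a scale.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()                       # vague: coefficient variance 1000
#' prior_spec(0.001, "variance")      # informative: variance 0.001
#' @export
prior_spec <- function(value = 0.001,
                       interpretation = c("precision", "variance"),
                       gamma_shape = 0.001, gamma_rate = 0.001) {
  interpretation <- match.arg(interpretation)
  stopifnot(is.numeric(value), length(value) == 1L, value > 0,
            gamma_shape > 0, gamma_rate > 0)
  structure(
    list(value = value, interpretation = interpretation,
         gamma_shape = gamma_shape, gamma_rate = gamma_rate),
    class = "prior_spec"
  )
}

#' Coefficient prior variance implied by a prior_spec
#' @param prior A [prior_spec()].
#' @return Scalar variance of the Gaussian coefficient prior.
#' @export
prior_variance <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  if (prior$interpretation == "precision") 1 / prior$value else prior$value
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "Gaussian coefficient prior: mean 0, %s %g (variance %g)\n",
    x$interpretation, x$value, prior_variance(x)))
  cat(sprintf("Precision prior: Gamma(shape %g, rate %g)\n",
              x$gamma_shape, x$gamma_rate))
  invisible(x)
}

#' MCMC settings
#'
#' @param n_chains Number of independent chains (>= 2 recommended so that
#'   split-R-hat can be computed).
#' @param n_iter Iterations per chain, including burn-in.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; every sampler in gapsurv derives its random
#'   stream from this value so runs are reproducible.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 4L, n_iter = 10000L, burn_in = 5000L,
                          thin = 1L, seed = 20741L) {
  stopifnot(n_chains >= 1L, n_iter > burn_in, burn_in >= 0L, thin >= 1L)
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "mcmc_settings"
  )
}

#' @export
print.mcmc_settings <- function(x, ...) {
  cat(sprintf("%d chain(s) x %d iterations (%d burn-in, thin %d), seed %d\n",
              x$n_chains, x$n_iter, x$burn_in, x$thin, x$seed))
  invisible(x)
}
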