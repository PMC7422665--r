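# Conjugate Bayesian normal linear model, shared by the AFT-on-log-gaps and
# gap-dependency regressions.
#
# Model: y = X theta + e, e ~ N(0, sigma^2); theta ~ N(0, (1/tau0) I);
# 1/sigma^2 ~ Gamma(a0, b0). Gibbs alternates the exact full conditionals:
#   theta | lambda ~ N(V lambda X'y, V),  V = (lambda X'X + tau0 I)^-1
#   lambda | theta ~ Gamma(a0 + n/2, b0 + RSS/2)

# Exact conditional posterior of theta given the error SD (vague prior
# tau0 -> 0 recovers ordinary least squares).
bayes_lm_conditional <- function(y, X, sigma, tau0) {
  lambda <- 1 / sigma^2
  V <- solve(lambda * crossprod(X) + tau0 * diag(ncol(X)))
  list(mean = drop(V %*% (lambda * crossprod(X, y))), cov = V)
}

bayes_lm_gibbs <- function(y, X, prior = prior_spec(),
                           mcmc = mcmc_settings(), sigma_known = NULL,
                           par_names = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n > p)
  tau0 <- 1 / prior_variance(prior)
  a0 <- prior$gamma_shape
  b0 <- prior$gamma_rate
  if (is.null(par_names)) par_names <- paste0("b", seq_len(p) - 1L)
  n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  draws <- matrix(NA_real_, n_keep * mcmc$n_chains, p + 1L,
                  dimnames = list(NULL, c(par_names, "sigma")))
  chain_id <- integer(nrow(draws))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  with_seed(mcmc$seed, {
    for (ch in seq_len(mcmc$n_chains)) {
      sigma <- if (is.null(sigma_known)) stats::sd(y) * stats::runif(1, 0.5, 2)
               else sigma_known
      theta <- rep(0, p)
      kept <- 0L
      for (it in seq_len(mcmc$n_iter)) {
        lambda <- 1 / sigma^2
        V <- solve(lambda * XtX + tau0 * diag(p))
        mu_t <- drop(V %*% (lambda * Xty))
        L <- chol(V)
        theta <- mu_t + drop(crossprod(L, stats::rnorm(p)))
        if (is.null(sigma_known)) {
          rss <- sum((y - drop(X %*% theta))^2)
          lambda <- stats::rgamma(1, a0 + n / 2, b0 + rss / 2)
          sigma <- 1 / sqrt(lambda)
        }
        if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
          kept <- kept + 1L
          row <- (ch - 1L) * n_keep + kept
          draws[row, ] <- c(theta, sigma)
          chain_id[row] <- ch
        }
      }
    }
  })
  posterior_draws(draws, chain_id, seed = mcmc$seed)
}
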