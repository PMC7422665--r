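test_that("AFT log-likelihood equals the log-normal density sum", {
  # standard normal at zero, Jacobian log(1) = 0
  expect_equal(aft_loglik(0, 0, 1, gaps = 1, x = 0),
               -0.5 * log(2 * pi))
  # manual normal-on-log-scale formula at random points
  set.seed(6)
  gaps <- rexp(5) + 0.2
  x <- c(0, 1, 0, 1, 1)
  mu <- 0.4; beta <- -0.3; s <- 0.7
  manual <- sum(-0.5 * log(2 * pi) - log(s) -
                  (log(gaps) - mu - beta * x)^2 / (2 * s^2) - log(gaps))
  expect_equal(aft_loglik(mu, beta, s, gaps, x), manual)
  expect_error(aft_loglik(0, 0, 1, c(1, -2), c(0, 1)), "positive")
})

test_that("rescaling time shifts the intercept by log(c) exactly", {
  set.seed(7)
  gaps <- rexp(20) + 0.5
  x <- rbinom(20, 1, 0.5)
  c_ <- 3.7
  expect_equal(aft_loglik(1.2 + log(c_), 0.3, 0.8, c_ * gaps, x),
               aft_loglik(1.2, 0.3, 0.8, gaps, x) - 20 * log(c_))
})

test_that("AFT survival follows the accelerated baseline identity", {
  # mu = beta = 0: survival equals the baseline at every t
  t <- c(0.1, 0.5, 1, 2, 10)
  expect_equal(aft_survival(t, 1, 0, 0, 0.6),
               1 - pnorm(log(t) / 0.6))
  # median at exp(mu + beta x)
  expect_equal(aft_survival(exp(1.4 + 0.3), 1, 1.4, 0.3, 0.5), 0.5)
  # bounds and monotonicity
  expect_equal(aft_survival(0, 0, 1, 0, 1), 1)
  expect_lt(aft_survival(1e8, 0, 1, 0, 1), 1e-10)
  grid <- aft_survival(seq(0.1, 50, length.out = 80), 0, 2, 0.1, 0.7)
  expect_true(all(diff(grid) < 0))
})

test_that("known-scale vague-prior posterior mean is the OLS fit", {
  set.seed(12)
  n <- 74
  x <- rep(c(0, 1), c(43, 31))
  gaps <- exp(5.3 + 0.1 * x + 0.8 * rnorm(n))
  fit <- fit_aft_bayes(gaps, x, prior = prior_spec(1e-10, "precision"),
                       mcmc = quick_mcmc(seed = 2L), sigma_known = 0.8)
  ols <- coef(lm(log(gaps) ~ x))
  expect_equal(unname(fit$conditional$mean), unname(ols),
               tolerance = 1e-6)
})

test_that("Gibbs sampler recovers generative AFT parameters", {
  for (n_pair in list(c(43L, 31L), c(1000L, 1000L))) {
    gen <- generate_cohort(synthetic_params(
      n_arm0 = n_pair[1], n_arm1 = n_pair[2], seed = 18L))
    gaps <- cohort_gap_times(gen$cohort)
    fit <- fit_aft_bayes(gaps$gap2, gaps$arm, mcmc = quick_mcmc(seed = 3L))
    s <- fit$summary
    truth <- c(intercept = 5.3, arm = 0.1, sigma = 0.8)
    for (p in names(truth)) {
      i <- which(s$parameter == p)
      expect_lt(abs(s$mean[i] - truth[[p]]), 3 * s$sd[i])
    }
  }
})

test_that("Gibbs moments agree with an independent Metropolis sampler", {
  set.seed(30)
  n <- 60
  x <- rep(c(0, 1), each = 30)
  gaps <- exp(2 + 0.4 * x + 0.5 * rnorm(n))
  fit <- fit_aft_bayes(gaps, x, mcmc = quick_mcmc(seed = 4L, n_iter = 8000L,
                                                  burn_in = 2000L))
  # brute-force random-walk Metropolis on (mu, beta, log sigma), same
  # posterior: log-normal likelihood x N(0, 1000) coefficient priors x
  # Gamma(0.001, 0.001) on the precision
  lp <- function(th) {
    s <- exp(th[3])
    aft_loglik(th[1], th[2], s, gaps, x) +
      sum(dnorm(th[1:2], 0, sqrt(1000), log = TRUE)) +
      dgamma(1 / s^2, 0.001, 0.001, log = TRUE) + log(2 / s^2)
  }
  th <- c(2, 0, 0); cur <- lp(th)
  keep <- matrix(NA_real_, 20000, 3)
  for (i in 1:25000) {
    cand <- th + rnorm(3, 0, c(0.12, 0.18, 0.12))
    lc <- lp(cand)
    if (log(runif(1)) < lc - cur) { th <- cand; cur <- lc }
    if (i > 5000) keep[i - 5000, ] <- th
  }
  mh_mean <- c(mean(keep[, 1]), mean(keep[, 2]), mean(exp(keep[, 3])))
  s <- fit$summary
  for (j in 1:3) {
    mcse <- s$sd[j] / sqrt(effective_sample_size(
      fit$draws$draws[, j], fit$draws$chain_id))
    mh_mcse <- sd(keep[, j]) / sqrt(effective_sample_size(keep[, j]))
    expect_lt(abs(s$mean[j] - mh_mean[j]),
              4 * sqrt(mcse^2 + mh_mcse^2) + 0.01)
  }
})

test_that("degenerate designs and dominating priors behave as expected", {
  gaps <- rexp(20) + 1
  expect_error(fit_aft_bayes(gaps, rep(0, 20)), "single-arm")
  expect_error(fit_aft_bayes(c(-1, gaps), c(0, rep(c(0, 1), 10))),
               "positive")
  set.seed(9)
  x <- rep(c(0, 1), each = 25)
  g <- exp(3 + 0.5 * x + 0.3 * rnorm(50))
  fit0 <- fit_aft_bayes(g, x, prior = prior_spec(1e7, "precision"),
                        mcmc = quick_mcmc(seed = 10L))
  expect_lt(abs(fit0$mu), 0.01)
  expect_lt(abs(fit0$beta), 0.01)
})
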