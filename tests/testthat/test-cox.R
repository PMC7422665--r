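test_that("partial likelihood at beta = 0 counts risk sets", {
  ll <- cox_partial_loglik(0, c(1, 2, 3), c(1, 1, 1),
                           cbind(z = c(0.4, -1, 2)))
  expect_equal(ll, -(log(3) + log(2) + log(1)))
  # Breslow ties: both events at t=1 see the full risk set of 3
  ll_tie <- cox_partial_loglik(0, c(1, 1, 2), c(1, 1, 1), cbind(z = 1:3))
  expect_equal(ll_tie, -(2 * log(3) + log(1)))
})

test_that("partial likelihood matches the exhaustive risk-set oracle", {
  time <- c(2, 5, 3, 8)
  event <- c(1, 0, 1, 1)
  Z <- cbind(z = c(0.5, -0.2, 1.3, 0))
  expect_equal(cox_partial_loglik(0.5, time, event, Z),
               oracle_partial_loglik(0.5, time, event, Z))
  # tied data, several coefficients
  set.seed(9)
  time2 <- sample(1:5, 12, replace = TRUE)
  event2 <- rbinom(12, 1, 0.8)
  event2[1] <- 1
  Z2 <- cbind(a = rnorm(12), b = rbinom(12, 1, 0.5))
  for (b in list(c(0, 0), c(0.5, -1), c(-0.3, 0.7)))
    expect_equal(cox_partial_loglik(b, time2, event2, Z2),
                 oracle_partial_loglik(b, time2, event2, Z2))
})

test_that("partial likelihood is invariant to covariate location shifts", {
  d <- gen_ph_data(30, 0.5, seed = 2)
  expect_equal(cox_partial_loglik(0.7, d$time, d$event, d$Z),
               cox_partial_loglik(0.7, d$time, d$event, d$Z + 100))
})

test_that("partial likelihood is concave (numeric Hessian <= 0)", {
  d <- gen_ph_data(25, 0.3, seed = 4)
  h <- 1e-4
  for (b in c(-1, 0, 0.8, 2)) {
    f <- function(x) cox_partial_loglik(x, d$time, d$event, d$Z)
    second <- (f(b + h) - 2 * f(b) + f(b - h)) / h^2
    expect_lte(second, 1e-6)
  }
})

test_that("Newton-Raphson MLE equals a fine grid search on a toy dataset", {
  time <- c(3, 1, 4, 6, 2, 5)
  event <- c(1, 1, 0, 1, 1, 1)
  Z <- cbind(z = c(1, 0, 1, 0, 1, 0))
  fit <- fit_cox_mle(time, event, Z)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b)
    oracle_partial_loglik(b, time, event, Z), 0)
  expect_lt(abs(fit$coefficients[["z"]] - grid[which.max(ll)]), 1e-3)
  expect_lt(fit$grad_norm, 1e-6)
})

test_that("MLE agrees with survival::coxph (Breslow and Efron)", {
  gen <- generate_cohort(synthetic_params(censor_rate = 0.2, seed = 17L))
  d <- endpoint_data(gen$cohort, "OS")
  Z <- cox_design(gen$cohort)
  fit <- fit_cox_mle(d$time, d$event, Z)
  ref <- survival::coxph(survival::Surv(d$time, d$event) ~ Z,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)

  # Efron tie handling, value cross-check on tied data
  set.seed(3)
  tt <- sample(1:6, 30, replace = TRUE)
  ev <- rbinom(30, 1, 0.7); ev[1] <- 1
  zz <- cbind(z = rnorm(30))
  ref2 <- survival::coxph(survival::Surv(tt, ev) ~ zz, ties = "efron")
  expect_equal(cox_partial_loglik(coef(ref2), tt, ev, zz, ties = "efron"),
               ref2$loglik[2], tolerance = 1e-8)
})

test_that("MLE recovers a known log-hazard ratio within 3 SE at n = 2000", {
  d <- gen_ph_data(2000, -0.3, seed = 12)
  fit <- fit_cox_mle(d$time, d$event, d$Z)
  expect_lt(abs(fit$coefficients[["arm"]] - (-0.3)), 3 * fit$se[["arm"]])
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(cox_partial_loglik(0, c(1, 2), c(0, 0), cbind(z = 1:2)),
               "no events")
  expect_error(fit_cox_mle(c(1, 2), c(1, 0), cbind(a = 1:2, b = 2:1)),
               "fewer events")
  # perfect separation: the high-covariate subjects all fail first
  expect_error(
    fit_cox_mle(1:6, rep(1, 6), cbind(z = c(1, 1, 1, 0, 0, 0))),
    "monotone")
})

test_that("Metropolis posterior matches the MLE under a vague prior", {
  d <- gen_ph_data(400, 0.5, seed = 23)
  mle <- fit_cox_mle(d$time, d$event, d$Z)
  bay <- fit_cox_bayes(d$time, d$event, d$Z,
                       mcmc = quick_mcmc(seed = 23L, n_iter = 6000L,
                                         burn_in = 2000L))
  expect_lt(abs(bay$coefficients[["arm"]] - mle$coefficients[["arm"]]), 0.03)
  expect_lt(abs(bay$se[["arm"]] - mle$se[["arm"]]), 0.03)
  # acceptance tuned into the target band
  expect_true(all(bay$acceptance > 0.15 & bay$acceptance < 0.55))
  # deviance-based pD close to the parameter count for a regular model
  expect_lt(abs(attr(bay$summary, "pd") - 1), 0.5)
})

test_that("an overwhelming prior pulls the posterior to zero", {
  d <- gen_ph_data(200, 1, seed = 31)
  bay <- fit_cox_bayes(d$time, d$event, d$Z,
                       prior = prior_spec(1e6, "precision"),
                       mcmc = quick_mcmc(seed = 5L))
  expect_lt(abs(bay$coefficients[["arm"]]), 0.01)
})

test_that("the supremum test is deterministic and detects a reversal", {
  d <- gen_ph_data(150, 0.4, seed = 44)
  fit <- fit_cox_mle(d$time, d$event, d$Z)
  p1 <- supremum_ph_test(fit, n_resample = 300, seed = 6)
  p2 <- supremum_ph_test(fit, n_resample = 300, seed = 6)
  expect_identical(p1$p_value, p2$p_value)
  expect_error(supremum_ph_test(fit, n_resample = 10), "at least 100")

  # effect reversing sign mid-follow-up: strong violation detected
  set.seed(77)
  n <- 500
  z <- rbinom(n, 1, 0.5)
  t1 <- rexp(n, exp(z))
  tau <- 0.7
  tt <- ifelse(t1 <= tau, t1, tau + rexp(n, exp(-z)))
  fitv <- fit_cox_mle(tt, rep(1, n), cbind(z = z))
  pv <- supremum_ph_test(fitv, n_resample = 300, seed = 8)
  expect_lt(pv$p_value[["z"]], 0.05)
})

test_that("endpoint wrapper builds the Arm/Age/Gender design correctly", {
  gen <- generate_cohort(synthetic_params(seed = 3L))
  Z <- cox_design(gen$cohort)
  expect_equal(colnames(Z), c("arm", "age", "gender"))
  expect_equal(mean(Z[, "age"]), 0, tolerance = 1e-12)
  expect_equal(sd(Z[, "age"]), 1, tolerance = 1e-12)
  Zb <- cox_design(gen$cohort, age_coding = "binary")
  expect_true(all(Zb[, "age"] %in% c(0, 1)))
  both <- fit_cox_endpoint(gen$cohort, "LRC", mode = "mle")
  expect_s3_class(both, "cox_fit")
})
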