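test_that("noise-free linear data is recovered essentially exactly", {
  cohort <- dependency_cohort(20, 20, c(3, 3), c(0.5, 0.5), 0, seed = 1)
  fit <- fit_gap_regression(cohort, 0, prior = prior_spec(1e-10),
                            mcmc = quick_mcmc(seed = 2L))
  expect_lt(abs(fit$conditional$mean[["slope"]] - 0.5), 1e-6)
  expect_lt(abs(fit$slope - 0.5), 1e-3)
  expect_lt(fit$sigma, 0.5)
})

test_that("vague-prior posterior mean equals least squares on a toy set", {
  cohort <- dependency_cohort(5, 5, c(10, 10), c(0.4, 0.4), 15, seed = 3)
  for (arm in 0:1) {
    fit <- fit_gap_regression(cohort, arm, prior = prior_spec(1e-10),
                              mcmc = quick_mcmc(seed = 4L))
    ols <- coef(lm(response ~ predictor, data = fit$data))
    expect_equal(unname(fit$conditional$mean), unname(ols),
                 tolerance = 1e-6)
    # sampled means approach the normal-equations solution too
    expect_lt(abs(fit$slope - ols[[2]]),
              4 * fit$summary$sd[fit$summary$parameter == "slope"] /
                sqrt(50) + 0.02)
  }
})

test_that("a generative slope is recovered within 3 posterior SDs", {
  cohort <- dependency_cohort(2000, 3, c(30, 30), c(0.4, 0.4), 40, seed = 5)
  fit <- fit_gap_regression(cohort, 0, mcmc = quick_mcmc(seed = 6L))
  s <- fit$summary
  i <- which(s$parameter == "slope")
  expect_lt(abs(s$mean[i] - 0.4), 3 * s$sd[i])
})

test_that("insufficient or degenerate arms are rejected", {
  cohort <- dependency_cohort(3, 2, c(3, 3), c(0.5, 0.5), 1, seed = 7)
  expect_error(fit_gap_regression(cohort, 1), "at least 3")
  df <- as.data.frame(dependency_cohort(5, 5, c(3, 3), c(0.5, 0.5), 1,
                                        seed = 8))
  df$t_progression <- df$t_relapse + 50   # zero predictor variance
  df$t_death <- df$t_progression + 30 + (1:10)
  expect_error(fit_gap_regression(gap_cohort(df), 0), "zero variance")
})

test_that("slope-difference posterior is centred, normalised, antisymmetric", {
  cohort <- dependency_cohort(150, 150, c(30, 30), c(0.4, 0.4), 40,
                              seed = 9)
  f0 <- fit_gap_regression(cohort, 0, mcmc = quick_mcmc(seed = 10L))
  f1 <- fit_gap_regression(cohort, 1, mcmc = quick_mcmc(seed = 11L))
  d <- arm_effect_difference(f0, f1)
  # identical generative arms: centred at zero (the posterior SD carries the
  # finite-sample spread of the two slope estimates)
  expect_lt(abs(d$mean), 3 * d$sd)
  expect_equal(d$p_greater_0 + mean(d$draws <= 0), 1)
  # swapping the fits negates the distribution exactly
  d_swap <- arm_effect_difference(f1, f0)
  expect_equal(d_swap$draws, -d$draws)
  expect_equal(d_swap$mean, -d$mean)
  # draw-count mismatch is an error
  f1_short <- fit_gap_regression(cohort, 1,
                                 mcmc = quick_mcmc(seed = 12L,
                                                   n_iter = 2000L,
                                                   burn_in = 1000L))
  expect_error(arm_effect_difference(f0, f1_short), "mismatched draw")
})

test_that("a true slope difference is recovered", {
  cohort <- dependency_cohort(800, 800, c(30, 30), c(0.3, 0.6), 40,
                              seed = 13)
  f0 <- fit_gap_regression(cohort, 0, mcmc = quick_mcmc(seed = 14L))
  f1 <- fit_gap_regression(cohort, 1, mcmc = quick_mcmc(seed = 15L))
  d <- arm_effect_difference(f0, f1)
  expect_lt(abs(d$mean - 0.3), 3 * d$sd)
  expect_gt(d$p_greater_0, 0.99)
})

test_that("combined arm report adds the two effects draw-wise", {
  gen <- generate_cohort(synthetic_params(n_arm0 = 400L, n_arm1 = 400L,
                                          beta1_arm = 0.2,
                                          reg_slopes = c(0.3, 0.6),
                                          seed = 16L))
  gaps <- cohort_gap_times(gen$cohort)
  aft <- fit_aft_bayes(gaps$gap2, gaps$arm, mcmc = quick_mcmc(seed = 17L))
  f0 <- fit_gap_regression(gen$cohort, 0, mcmc = quick_mcmc(seed = 18L))
  f1 <- fit_gap_regression(gen$cohort, 1, mcmc = quick_mcmc(seed = 19L))
  d <- arm_effect_difference(f0, f1)
  rep <- combined_arm_inference(aft, d)
  tab <- rep$table
  expect_equal(rownames(tab),
               c("aft_arm_effect", "slope_difference", "combined"))
  expect_equal(tab["combined", "mean"],
               tab["aft_arm_effect", "mean"] +
                 tab["slope_difference", "mean"])
  # truth: 0.2 (log-scale AFT effect) + 0.3 (slope difference) = 0.5
  expect_lt(abs(tab["combined", "mean"] - 0.5),
            3 * tab["combined", "sd"])
})

test_that("next-gap prediction is calibrated and monotone", {
  cohort <- dependency_cohort(100, 3, c(3, 3), c(0.5, 0.5), 1e-3, seed = 20)
  fit <- fit_gap_regression(cohort, 0, mcmc = quick_mcmc(seed = 21L))
  pred <- predict_next_gap(10, fit)
  expect_equal(pred$mean, 3 + 0.5 * 10, tolerance = 0.01)
  expect_lt(pred$upper - pred$lower, 0.05)
  # monotone in g1 when slope mass is positive
  grid <- predict_next_gap(c(5, 10, 20, 40), fit)
  expect_true(all(diff(grid$mean) > 0))
  expect_error(predict_next_gap(-1, fit), "g1 > 0")
})
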