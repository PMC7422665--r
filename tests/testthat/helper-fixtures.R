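# Hand-built cohorts and brute-force oracles shared across tests.

# 5 subjects: 2 complete cases, 2 censored mid-trajectory, 1 censored before
# any event.
toy_cohort_df <- function() {
  data.frame(
    subject_id = paste0("P", 1:5),
    arm = c(0, 0, 1, 1, 0),
    age = c(54, 61, 48, 70, 58),
    gender = c(1, 0, 1, 1, 0),
    t_relapse = c(10, 20, 15, 30, 12),
    d_relapse = c(1, 1, 1, 1, 0),
    t_progression = c(15, 45, 35, 42, 12),
    d_progression = c(1, 1, 1, 0, 0),
    t_death = c(22, 80, 60, 42, 12),
    d_death = c(1, 1, 0, 0, 0)
  )
}

# Random fully-observed cohort built directly (not via the generator), so
# generator and cohort machinery can be tested against each other.
random_complete_cohort <- function(n, seed = 1) {
  set.seed(seed)
  t1 <- round(runif(n, 1, 100), 3)
  t2 <- t1 + round(runif(n, 1, 200), 3)
  t3 <- t2 + round(runif(n, 1, 300), 3)
  gap_cohort(data.frame(
    subject_id = sprintf("R%04d", seq_len(n)),
    arm = rep_len(c(0, 1), n), age = round(runif(n, 40, 75)),
    gender = rbinom(n, 1, 0.5),
    t_relapse = t1, d_relapse = 1,
    t_progression = t2, d_progression = 1,
    t_death = t3, d_death = 1))
}

# Breslow partial log-likelihood by exhaustive risk-set enumeration.
oracle_partial_loglik <- function(beta, time, event, Z) {
  Z <- as.matrix(Z)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + sum(Z[i, ] * beta) -
      log(sum(exp(Z[risk, , drop = FALSE] %*% beta)))
  }
  ll
}

# Shortest interval containing ceiling(prob * n) sorted draws, by scanning
# every window explicitly.
oracle_hpd <- function(draws, prob) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(prob * n)
  best <- c(s[1], s[n])
  if (m >= n) return(best)
  best_w <- Inf
  for (i in 1:(n - m)) {
    w <- s[i + m - 1] - s[i]
    if (w < best_w) {
      best_w <- w
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}

# Proportional-hazards data with an exponential baseline.
gen_ph_data <- function(n, beta, seed, censor_rate = 0.15) {
  set.seed(seed)
  Z <- cbind(arm = rbinom(n, 1, 0.5))
  t <- rexp(n, rate = exp(Z %*% beta))
  cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
  list(time = pmin(t, cens), event = as.numeric(t <= cens), Z = Z)
}

# Cohort whose arm-specific progression-to-death gap is
# intercept + slope * (relapse-to-progression gap) + N(0, noise).
dependency_cohort <- function(n0, n1, intercepts, slopes, noise, seed) {
  set.seed(seed)
  n <- n0 + n1
  arm <- rep(c(0, 1), c(n0, n1))
  t1 <- runif(n, 5, 50)
  g2 <- runif(n, 20, 400)
  g3 <- intercepts[arm + 1] + slopes[arm + 1] * g2 +
    noise * rnorm(n)
  g3 <- pmax(g3, 0.1)
  gap_cohort(data.frame(
    subject_id = sprintf("D%04d", 1:n), arm = arm,
    age = round(runif(n, 40, 75)), gender = rbinom(n, 1, 0.5),
    t_relapse = t1, d_relapse = 1,
    t_progression = t1 + g2, d_progression = 1,
    t_death = t1 + g2 + g3, d_death = 1))
}

quick_mcmc <- function(seed = 11L, n_iter = 3000L, burn_in = 1000L,
                       n_chains = 2L)
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                seed = seed)
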