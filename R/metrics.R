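#' Container for MCMC posterior draws
#'
#' @param draws Numeric matrix, one row per retained draw, one column per
#'   parameter (named columns).
#' @param chain_id Integer vector, length `nrow(draws)`, identifying the
#'   chain each draw came from.
#' @param seed Seed the sampler ran under.
#' @param acceptance Optional named numeric vector of acceptance rates
#'   (Metropolis samplers only).
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, chain_id, seed = NA_integer_,
                            acceptance = NULL) {
  draws <- as.matrix(draws)
  if (is.null(colnames(draws)))
    colnames(draws) <- paste0("par", seq_len(ncol(draws)))
  stopifnot(nrow(draws) == length(chain_id))
  if (any(!is.finite(draws)))
    stop("posterior draws contain non-finite values")
  structure(
    list(draws = draws, chain_id = as.integer(chain_id),
         seed = seed, acceptance = acceptance),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws x %d parameter(s), %d chain(s)\n",
              nrow(x$draws), ncol(x$draws), length(unique(x$chain_id))))
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' Export posterior draws to CSV (one column per parameter)
#' @param x A [posterior_draws()] object.
#' @param path Output file path.
#' @export
write_draws <- function(x, path) {
  stopifnot(inherits(x, "posterior_draws"))
  utils::write.csv(
    data.frame(chain = x$chain_id, x$draws, check.names = FALSE),
    path, row.names = FALSE)
  invisible(path)
}

#' Akaike information criterion
#'
#' `AIC = -2 log L(theta-hat) + 2 k` for a maximum-likelihood fit with `k`
#' free parameters.
#'
#' @param loglik_at_mle Maximised log-likelihood.
#' @param k Number of estimated parameters (>= 0).
#' @return Scalar AIC.
#' @export
aic <- function(loglik_at_mle, k) {
  stopifnot(is.finite(loglik_at_mle), k >= 0)
  -2 * loglik_at_mle + 2 * k
}

#' Deviance information criterion and effective parameter count
#'
#' `pD` is the posterior mean deviance minus the deviance at the posterior
#' mean of the parameters; `DIC = deviance_at_mean + 2 pD`, equivalently the
#' posterior mean deviance plus `pD`. The identity between the two forms is
#' asserted on every call.
#'
#' @param deviance_draws Per-draw deviance values (`-2 log L` at each draw).
#' @param deviance_at_mean Deviance evaluated at the posterior mean of the
#'   parameters.
#' @return List with elements `dic` and `pd`.
#' @export
dic <- function(deviance_draws, deviance_at_mean) {
  if (length(deviance_draws) < 1L) stop("need at least one deviance draw")
  if (any(!is.finite(deviance_draws)) || !is.finite(deviance_at_mean))
    stop("non-finite deviance")
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_mean
  out <- deviance_at_mean + 2 * pd
  stopifnot(abs(out - (dbar + pd)) < 1e-9 * max(1, abs(out)))
  list(dic = out, pd = pd)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(prob * n)` of the sorted
#' draws. Assumes a unimodal posterior; for multimodal samples the contiguous
#' interval is still returned but is not the true HPD region.
#'
#' @param draws Numeric sample vector (>= 20 draws).
#' @param prob Coverage level in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 20L) stop("need at least 20 draws for an HPD interval")
  stopifnot(prob > 0, prob < 1)
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = s[1L], upper = s[n]))
  starts <- seq_len(n - m)           # windows [i, i + m - 1] of m draws
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1L])
}

#' Split-R-hat convergence diagnostic
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' statistic is computed across the resulting half-chains.
#'
#' @param draws Numeric vector of draws for one parameter.
#' @param chain_id Chain identifier per draw.
#' @return Scalar R-hat (NA if fewer than 2 half-chains or constant draws).
#' @export
split_rhat <- function(draws, chain_id) {
  pieces <- list()
  for (ch in unique(chain_id)) {
    x <- draws[chain_id == ch]
    h <- length(x) %/% 2L
    if (h < 2L) next
    pieces <- c(pieces, list(x[seq_len(h)], x[(h + 1L):(2L * h)]))
  }
  if (length(pieces) < 2L) return(NA_real_)
  n <- min(lengths(pieces))
  pieces <- lapply(pieces, function(x) x[seq_len(n)])
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, stats::var, 0)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w <= 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Effective sample size of an MCMC sample
#'
#' Autocorrelation-based estimate: `n / (1 + 2 * sum(rho_k))` with the sum
#' truncated at the first lag whose autocorrelation drops below 0.05,
#' computed per chain and summed. Used to put Monte-Carlo standard errors
#' on posterior means.
#'
#' @param draws Numeric draw vector for one parameter.
#' @param chain_id Optional chain identifier per draw (single chain
#'   assumed when omitted).
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(draws, chain_id = NULL) {
  if (is.null(chain_id)) chain_id <- rep(1L, length(draws))
  total <- 0
  for (ch in unique(chain_id)) {
    x <- draws[chain_id == ch]
    n <- length(x)
    if (n < 10L || stats::var(x) == 0) { total <- total + n; next }
    rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                      demean = TRUE)$acf[-1L]
    keep <- which(rho < 0.05)
    cut <- if (length(keep)) keep[1L] - 1L else length(rho)
    s <- if (cut > 0) sum(rho[seq_len(cut)]) else 0
    total <- total + n / (1 + 2 * max(s, 0))
  }
  total
}

#' Summarise posterior draws into a fit summary
#'
#' Produces per-parameter posterior mean, SD, equal-tailed 95% credible
#' interval, 95% HPD interval and split-R-hat, plus model-level DIC and pD
#' when a deviance function is supplied.
#'
#' @param draws A [posterior_draws()] object.
#' @param deviance_fn Optional function mapping a parameter vector (one draw)
#'   to its deviance `-2 log L`; used for DIC/pD.
#' @param prob Interval coverage (default 0.95).
#' @return An object of class `fit_summary`: a data frame of per-parameter
#'   summaries with attributes `dic` and `pd`.
#' @export
summarize_draws <- function(draws, deviance_fn = NULL, prob = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  m <- draws$draws
  if (nrow(m) == 0L) stop("empty draws")
  a <- (1 - prob) / 2
  tab <- data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    ci_lower = apply(m, 2, stats::quantile, probs = a, names = FALSE),
    ci_upper = apply(m, 2, stats::quantile, probs = 1 - a, names = FALSE),
    hpd_lower = NA_real_, hpd_upper = NA_real_, rhat = NA_real_,
    row.names = NULL
  )
  for (j in seq_len(ncol(m))) {
    if (nrow(m) >= 20L) {
      h <- hpd_interval(m[, j], prob)
      tab$hpd_lower[j] <- h[[1L]]
      tab$hpd_upper[j] <- h[[2L]]
    }
    tab$rhat[j] <- split_rhat(m[, j], draws$chain_id)
  }
  bad <- tab$rhat[!is.na(tab$rhat)]
  if (length(bad) && any(bad > 1.05))
    warning("split-R-hat > 1.05 for at least one parameter; ",
            "chains may not have converged")
  d <- list(dic = NA_real_, pd = NA_real_)
  if (!is.null(deviance_fn)) {
    dev_draws <- apply(m, 1, deviance_fn)
    d <- dic(dev_draws, deviance_fn(colMeans(m)))
  }
  structure(tab, dic = d$dic, pd = d$pd, prob = prob,
            class = c("fit_summary", "data.frame"))
}

#' @export
print.fit_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  if (is.finite(attr(x, "dic")))
    cat(sprintf("DIC %.2f  pD %.2f\n", attr(x, "dic"), attr(x, "pd")))
  invisible(x)
}
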