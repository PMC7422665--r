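# Map an endpoint code to its time/indicator columns. LRC: registration to
# first loco-regional relapse; PFS: enrolment to progression; OS:
# registration to death or last follow-up.
endpoint_columns <- function(endpoint) {
  switch(toupper(endpoint),
         LRC = c(time = "t_relapse", event = "d_relapse"),
         PFS = c(time = "t_progression", event = "d_progression"),
         OS  = c(time = "t_death", event = "d_death"),
         stop("unknown endpoint '", endpoint, "'; use LRC, PFS or OS"))
}

#' Extract endpoint survival data from a cohort
#'
#' @param cohort A [gap_cohort()].
#' @param endpoint One of `"LRC"`, `"PFS"`, `"OS"`.
#' @return Data frame with `time`, `event`, `arm`, `age`, `gender`.
#' @export
endpoint_data <- function(cohort, endpoint) {
  stopifnot(inherits(cohort, "gap_cohort"))
  cols <- endpoint_columns(endpoint)
  data.frame(time = cohort[[cols[["time"]]]],
             event = cohort[[cols[["event"]]]],
             arm = cohort$arm, age = cohort$age, gender = cohort$gender)
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator with Greenwood standard errors, with the
#' usual tie convention that events precede censorings at the same time.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return Object of class `km_curve`: sorted distinct `time`, `survival`
#'   step values, `at_risk` and `n_events` counts, and Greenwood `std_err`
#'   of the survival estimate. The curve starts at 1 at time 0.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(length(times) == length(events))
  if (any(times <= 0)) stop("follow-up times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "none")
  structure(
    list(time = sf$time, survival = sf$surv, at_risk = sf$n.risk,
         n_events = sf$n.event,
         std_err = sf$surv * sf$std.err,   # Greenwood, survival scale
         n = length(times)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d distinct time(s), %d event(s)\n",
              x$n, length(x$time), sum(x$n_events)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    i <- findInterval(ti, curve$time)
    if (i == 0L) 1 else curve$survival[i]
  }, 0)
}

#' Kaplan-Meier curves per arm for a trial endpoint
#'
#' @param cohort A [gap_cohort()].
#' @param endpoint `"LRC"`, `"PFS"` or `"OS"`.
#' @return List of class `km_by_arm` with one `km_curve` per arm present in
#'   the cohort (named by arm code) and a tidy data frame `table` with
#'   columns `time`, `survival`, `at_risk`, `n_events`, `std_err`, `arm`
#'   ready for CSV export or plotting.
#' @export
km_by_arm <- function(cohort, endpoint) {
  dat <- endpoint_data(cohort, endpoint)
  arms <- sort(unique(dat$arm))
  if (length(arms) < 2L)
    warning("cohort contains a single arm; one curve estimated")
  curves <- lapply(arms, function(a) {
    d <- dat[dat$arm == a, ]
    km_estimate(d$time, d$event)
  })
  names(curves) <- as.character(arms)
  tab <- do.call(rbind, lapply(names(curves), function(a) {
    cv <- curves[[a]]
    data.frame(time = cv$time, survival = cv$survival,
               at_risk = cv$at_risk, n_events = cv$n_events,
               std_err = cv$std_err, arm = as.numeric(a))
  }))
  structure(list(curves = curves, table = tab, endpoint = toupper(endpoint)),
            class = "km_by_arm")
}

#' @export
print.km_by_arm <- function(x, ...) {
  cat(sprintf("Kaplan-Meier by arm, endpoint %s:\n", x$endpoint))
  for (a in names(x$curves)) {
    cv <- x$curves[[a]]
    cat(sprintf("  arm %s: n = %d, events = %d\n", a, cv$n,
                sum(cv$n_events)))
  }
  invisible(x)
}
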