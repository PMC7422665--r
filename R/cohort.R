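#' @keywords internal
"_PACKAGE"

# Canonical column schema for an event table. Times are decimal days from
# registration; indicators are 1 = event observed, 0 = censored at that time.
COHORT_COLUMNS <- c("subject_id", "arm", "age", "gender",
                    "t_relapse", "d_relapse",
                    "t_progression", "d_progression",
                    "t_death", "d_death")
TIME_COLUMNS <- c("t_relapse", "t_progression", "t_death")
EVENT_COLUMNS <- c("d_relapse", "d_progression", "d_death")

#' Construct and validate a two-arm event cohort
#'
#' A cohort is a data frame of per-patient records of the three ordered
#' progression events — loco-regional relapse, progression, death — with one
#' time and one event indicator per event, plus arm, age and gender
#' covariates. Events are ordered: relapse cannot follow progression, and
#' death is terminal, so a censored event implies all later events are
#' censored at the same time.
#'
#' @param df Data frame with columns `subject_id`, `arm` (0 = Arm-A
#'   reference, 1 = Arm-B), `age`, `gender` (binary code), `t_relapse`,
#'   `d_relapse`, `t_progression`, `d_progression`, `t_death`, `d_death`.
#'   Times in days from registration.
#' @param arm_labels Named character vector mapping arm codes to display
#'   names.
#' @return Object of class `gap_cohort` (a validated data frame).
#' @export
gap_cohort <- function(df, arm_labels = c("0" = "Arm-A", "1" = "Arm-B")) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("event table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, c(COHORT_COLUMNS, setdiff(names(df), COHORT_COLUMNS))]
  for (cn in c(TIME_COLUMNS, EVENT_COLUMNS, "arm")) {
    if (!is.numeric(df[[cn]]))
      stop("column '", cn, "' must be numeric")
  }
  if (anyDuplicated(df$subject_id))
    stop("subject_id values must be unique")
  if (!all(df$arm %in% c(0, 1)))
    stop("arm must be coded 0 (reference) or 1")
  if (!all(unlist(df[EVENT_COLUMNS]) %in% c(0, 1)))
    stop("event indicators must be 0 or 1")
  tm <- as.matrix(df[TIME_COLUMNS])
  ev <- as.matrix(df[EVENT_COLUMNS])
  for (i in seq_len(nrow(df))) {
    if (any(!is.finite(tm[i, ])) )
      stop("non-finite event time for subject ", df$subject_id[i])
    obs <- which(ev[i, ] == 1)
    if (length(obs) && any(tm[i, obs] <= 0))
      stop("observed event times must be strictly positive (subject ",
           df$subject_id[i], ")")
    if (is.unsorted(tm[i, ]))
      stop("event times out of order for subject ", df$subject_id[i])
    # ordered events: once censored, every later event is censored too
    if (length(obs) && any(diff(ev[i, ]) > 0))
      stop("event indicators violate ordering (event after censoring) ",
           "for subject ", df$subject_id[i])
  }
  structure(df, arm_labels = arm_labels,
            class = c("gap_cohort", "data.frame"))
}

#' @export
print.gap_cohort <- function(x, ...) {
  lab <- attr(x, "arm_labels")
  cat(sprintf("gap_cohort: %d subject(s)\n", nrow(x)))
  for (code in names(lab))
    cat(sprintf("  %s (arm=%s): n = %d\n", lab[[code]], code,
                sum(x$arm == as.numeric(code))))
  cat(sprintf("  complete cases (all three events observed): %d\n",
              sum(x$d_relapse == 1 & x$d_progression == 1 & x$d_death == 1)))
  invisible(x)
}

#' Read a per-patient event table from CSV
#'
#' Reads a comma-separated, headered, UTF-8 event table and returns a
#' validated [gap_cohort()]. Rows with any missing mapped value are dropped
#' (complete-record ingestion: records with missing observations are not
#' considered) and the number dropped is reported via a message and the
#' `n_dropped` attribute.
#'
#' @param path CSV file path.
#' @param dialect Optional named character vector mapping canonical column
#'   names (see [gap_cohort()]) to the source file's headers, e.g.
#'   `c(t_relapse = "relapse_days")`. Unmapped canonical names are looked up
#'   verbatim.
#' @param arm_labels Passed to [gap_cohort()].
#' @return A `gap_cohort` with attribute `n_dropped`.
#' @export
read_event_table <- function(path, dialect = NULL,
                             arm_labels = c("0" = "Arm-A", "1" = "Arm-B")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  source_names <- stats::setNames(COHORT_COLUMNS, COHORT_COLUMNS)
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), COHORT_COLUMNS)
    if (length(unknown))
      stop("dialect maps unknown column(s): ", paste(unknown, collapse = ", "))
    source_names[names(dialect)] <- dialect
  }
  absent <- source_names[!(source_names %in% names(raw))]
  if (length(absent))
    stop("input lacks mapped column(s): ",
         paste(sprintf("%s (expected header '%s')", names(absent), absent),
               collapse = ", "))
  df <- raw[, unname(source_names)]
  names(df) <- names(source_names)
  for (cn in c("arm", "age", "gender", TIME_COLUMNS, EVENT_COLUMNS)) {
    if (is.character(df[[cn]])) {
      conv <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(!is.na(df[[cn]]) & df[[cn]] != "" & is.na(conv))
      if (length(bad))
        stop("non-numeric value in column '", source_names[[cn]],
             "' at data row ", bad[1L], ": '", df[[cn]][bad[1L]], "'")
      conv[df[[cn]] == ""] <- NA_real_
      df[[cn]] <- conv
    }
  }
  keep <- stats::complete.cases(df[, COHORT_COLUMNS])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing values dropped")
  out <- gap_cohort(df[keep, , drop = FALSE], arm_labels = arm_labels)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write an event table to CSV
#'
#' Inverse of [read_event_table()]: writes the canonical column schema so
#' that a read/write round trip preserves all numeric values.
#'
#' @param cohort A `gap_cohort`.
#' @param path Output CSV path.
#' @export
write_event_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "gap_cohort"))
  utils::write.csv(as.data.frame(cohort)[, COHORT_COLUMNS], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Gap-time decomposition of one subject's ordered event times
#'
#' Decomposes ordered event times into gaps: the first gap is the time to
#' the first event, and each later gap is the increment over the previous
#' event time. Gaps beyond the last observed event are unobserved. A zero
#' gap between two observed events is rejected, because the log-time models
#' downstream require strictly positive gaps.
#'
#' @param times Numeric vector of ordered event times (days), e.g.
#'   relapse, progression, death/last follow-up.
#' @param events 0/1 indicator per time (1 = event observed).
#' @return Object of class `gap_times`: list with `gaps` (observed gaps, in
#'   order), `observed` (logical per position) and `complete` (all events
#'   observed).
#' @examples
#' compute_gap_times(c(10, 15, 22), c(1, 1, 1))  # gaps 10, 5, 7
#' @export
compute_gap_times <- function(times, events) {
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  if (any(diff(events) > 0))
    stop("event indicators violate ordering (event after censoring)")
  obs <- which(events == 1)
  if (length(obs) && is.unsorted(times[obs], strictly = FALSE))
    stop("observed event times are out of order")
  gaps <- diff(c(0, times))
  k <- length(obs)                      # events are ordered: obs == 1..k
  if (k > 0) {
    og <- gaps[seq_len(k)]
    if (any(og == 0))
      stop("zero gap between consecutive observed events; ",
           "log-time gap models require positive gaps")
    if (any(og < 0)) stop("observed event times are out of order")
  }
  structure(
    list(gaps = gaps[seq_len(k)],
         observed = seq_along(times) <= k,
         complete = k == length(times)),
    class = "gap_times"
  )
}

#' @export
print.gap_times <- function(x, ...) {
  cat("gaps:", paste(signif(x$gaps, 6), collapse = ", "),
      if (x$complete) "(complete)" else "(censored)", "\n")
  invisible(x)
}

#' Gap times for every subject in a cohort
#'
#' @param cohort A `gap_cohort`.
#' @return Data frame with `subject_id`, `arm`, `gap1` (registration to
#'   relapse), `gap2` (relapse to progression), `gap3` (progression to
#'   death), `complete`. Unobserved gaps are `NA`.
#' @export
cohort_gap_times <- function(cohort) {
  stopifnot(inherits(cohort, "gap_cohort"))
  n <- nrow(cohort)
  out <- data.frame(subject_id = cohort$subject_id, arm = cohort$arm,
                    gap1 = NA_real_, gap2 = NA_real_, gap3 = NA_real_,
                    complete = FALSE)
  for (i in seq_len(n)) {
    g <- compute_gap_times(
      as.numeric(cohort[i, TIME_COLUMNS]),
      as.numeric(cohort[i, EVENT_COLUMNS]))
    if (length(g$gaps))
      out[i, c("gap1", "gap2", "gap3")[seq_along(g$gaps)]] <- g$gaps
    out$complete[i] <- g$complete
  }
  out
}

#' Complete-case subset of a cohort
#'
#' Returns only subjects for whom all three progression states were
#' observed — the subset entering the gap-time analyses. The input cohort
#' is not modified.
#'
#' @param cohort A `gap_cohort`.
#' @return A `gap_cohort` (possibly with zero rows).
#' @export
complete_case_subset <- function(cohort) {
  stopifnot(inherits(cohort, "gap_cohort"))
  keep <- cohort$d_relapse == 1 & cohort$d_progression == 1 &
    cohort$d_death == 1
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(out) <- NULL
  gap_cohort(out, arm_labels = attr(cohort, "arm_labels"))
}
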