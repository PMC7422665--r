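#' Analysis configuration for the end-to-end strategy
#'
#' @param input Optional CSV path of an event table; when `NULL` the
#'   synthetic preset in `sim_params` is generated instead.
#' @param dialect Column-name mapping passed to [read_event_table()].
#' @param sim_params A [synthetic_params()] preset used when `input` is
#'   `NULL`.
#' @param endpoints Endpoints for the Kaplan-Meier and Cox stages.
#' @param aft_gaps Gap indices modelled by the AFT stage (defaults: gap 2,
#'   relapse to progression, reported as the "PFS" response; gap 3,
#'   progression to death, reported as "OS").
#' @param predictor_gap,response_gap Gap pair linked by the dependency
#'   regression.
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_settings()]; per-stage seeds are derived from
#'   `mcmc$seed` so the whole run is reproducible.
#' @param age_coding Passed to [cox_design()].
#' @param log_scale_regression Fit the dependency regression on log gaps.
#' @param out_dir Optional directory; when given, every table, summary,
#'   draws file and the run manifest are written there.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, dialect = NULL,
                            sim_params = synthetic_params(),
                            endpoints = c("LRC", "PFS", "OS"),
                            aft_gaps = c(2L, 3L),
                            predictor_gap = 2L, response_gap = 3L,
                            prior = prior_spec(), mcmc = mcmc_settings(),
                            age_coding = "standardized",
                            log_scale_regression = FALSE,
                            out_dir = NULL) {
  structure(
    list(input = input, dialect = dialect, sim_params = sim_params,
         endpoints = endpoints, aft_gaps = as.integer(aft_gaps),
         predictor_gap = as.integer(predictor_gap),
         response_gap = as.integer(response_gap),
         prior = prior, mcmc = mcmc, age_coding = age_coding,
         log_scale_regression = log_scale_regression, out_dir = out_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys mirror the arguments of [analysis_config()]; nested
#' blocks `sim_params`, `prior` and `mcmc` take the corresponding
#' constructor arguments.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("input", "endpoints", "aft_gaps", "predictor_gap",
              "response_gap", "age_coding", "log_scale_regression",
              "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$dialect)) args$dialect <- unlist(y$dialect)
  if (!is.null(y$sim_params))
    args$sim_params <- do.call(synthetic_params, y$sim_params)
  if (!is.null(y$prior)) args$prior <- do.call(prior_spec, y$prior)
  if (!is.null(y$mcmc)) args$mcmc <- do.call(mcmc_settings, y$mcmc)
  do.call(analysis_config, args)
}

# Derived per-stage seed, kept inside 32-bit integer range.
stage_seed <- function(base, offset) as.integer((base + offset) %% 2147483647)

stage_mcmc <- function(mcmc, offset) {
  mcmc$seed <- stage_seed(mcmc$seed, offset)
  mcmc
}

#' Run the full gap-time analysis strategy
#'
#' Executes the whole pipeline on a cohort (read from CSV or generated from
#' the synthetic preset): complete-case subset for the gap analyses,
#' Kaplan-Meier curves per endpoint, Cox models (maximum partial likelihood
#' and Metropolis posterior) per endpoint, Bayesian AFT fits per gap,
#' per-arm gap-dependency regressions, the between-arm slope-difference
#' posterior, and the combined arm report. When `config$out_dir` is set,
#' all tables, draws and a manifest (package version, seeds, configuration)
#' are written there.
#'
#' @param config An [analysis_config()].
#' @return A `report_bundle` list: `cohort`, `km` (one per endpoint), `cox`
#'   (per endpoint, each with `mle` and `bayes`), `aft` (per modelled gap),
#'   `gap_regression` (per arm), `difference`, `combined`, `manifest`.
#' @export
run_strategy <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  run_stage <- function(stage, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  cohort <- run_stage("ingest", {
    if (!is.null(config$input))
      read_event_table(config$input, dialect = config$dialect)
    else generate_cohort(config$sim_params)$cohort
  })
  cc <- run_stage("complete_cases", complete_case_subset(cohort))
  km <- run_stage("kaplan_meier",
                  stats::setNames(lapply(config$endpoints, function(ep)
                    km_by_arm(cohort, ep)), config$endpoints))
  cox <- run_stage("cox_ph", {
    fits <- lapply(seq_along(config$endpoints), function(i)
      fit_cox_endpoint(cohort, config$endpoints[i], mode = "both",
                       prior = config$prior,
                       mcmc = stage_mcmc(config$mcmc, 100L + i),
                       age_coding = config$age_coding))
    stats::setNames(fits, config$endpoints)
  })
  gaps_cc <- cohort_gap_times(cc)
  aft_labels <- c("1" = "Relapse", "2" = "PFS", "3" = "OS")
  aft <- run_stage("aft_gap", {
    fits <- lapply(seq_along(config$aft_gaps), function(i) {
      g <- config$aft_gaps[i]
      fit_aft_bayes(gaps_cc[[paste0("gap", g)]], gaps_cc$arm,
                    prior = config$prior,
                    mcmc = stage_mcmc(config$mcmc, 200L + i))
    })
    stats::setNames(fits, aft_labels[as.character(config$aft_gaps)])
  })
  reg <- run_stage("gap_dependency", list(
    arm0 = fit_gap_regression(cohort, 0, prior = config$prior,
                              mcmc = stage_mcmc(config$mcmc, 301L),
                              log_scale = config$log_scale_regression,
                              predictor_gap = config$predictor_gap,
                              response_gap = config$response_gap),
    arm1 = fit_gap_regression(cohort, 1, prior = config$prior,
                              mcmc = stage_mcmc(config$mcmc, 302L),
                              log_scale = config$log_scale_regression,
                              predictor_gap = config$predictor_gap,
                              response_gap = config$response_gap)))
  diff <- run_stage("arm_effect_difference",
                    arm_effect_difference(reg$arm0, reg$arm1))
  first_gap_label <- aft_labels[as.character(config$predictor_gap)]
  combined <- run_stage("combined_inference",
                        combined_arm_inference(aft[[first_gap_label]], diff))
  manifest <- list(
    package = "gapsurv",
    version = as.character(utils::packageVersion("gapsurv")),
    seed = config$mcmc$seed,
    n_subjects = nrow(cohort), n_complete = nrow(cc),
    endpoints = config$endpoints, aft_gaps = config$aft_gaps,
    prior = unclass(config$prior),
    mcmc = unclass(config$mcmc),
    simulated = is.null(config$input),
    sim_params = if (is.null(config$input)) unclass(config$sim_params))
  bundle <- structure(
    list(cohort = cohort, km = km, cox = cox, aft = aft,
         gap_regression = reg, difference = diff, combined = combined,
         manifest = manifest),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("gapsurv report bundle: %d subjects (%d complete cases)\n",
              x$manifest$n_subjects, x$manifest$n_complete))
  cat("  Cox endpoints:", paste(names(x$cox), collapse = ", "), "\n")
  cat("  AFT responses:", paste(names(x$aft), collapse = ", "), "\n")
  cat(sprintf("  slope difference: %.3f (P>0: %.3f)\n",
              x$difference$mean, x$difference$p_greater_0))
  invisible(x)
}

fmt2 <- function(x) sprintf("%.2f", x)

#' Render the fitted bundle as report tables
#'
#' Produces the two headline tables: per-endpoint Cox posterior estimates
#' (Response, Parameter, Posterior Mean (SD), 95% HPD, DIC, pD, and the MLE
#' with its Wald interval) and per-gap AFT posterior estimates (rows
#' Intercept / Arm / Scale). Values are formatted to two decimals.
#'
#' @param bundle A `report_bundle` from [run_strategy()].
#' @return List with data frames `cox_table` and `aft_table`.
#' @export
render_tables <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  cox_rows <- list()
  for (ep in names(bundle$cox)) {
    f <- bundle$cox[[ep]]
    if (is.null(f$bayes) || is.null(f$mle))
      stop("bundle is missing a converged Cox fit for '", ep, "'")
    s <- f$bayes$summary
    for (i in seq_len(nrow(s))) {
      par <- s$parameter[i]
      cox_rows[[length(cox_rows) + 1L]] <- data.frame(
        Response = if (i == 1L) ep else "",
        Parameter = paste0(toupper(substring(par, 1, 1)), substring(par, 2)),
        `Posterior Mean (SD)` = sprintf("%s (%s)", fmt2(s$mean[i]),
                                        fmt2(s$sd[i])),
        `95% HPD` = sprintf("(%s, %s)", fmt2(s$hpd_lower[i]),
                            fmt2(s$hpd_upper[i])),
        DIC = if (i == 1L) fmt2(attr(s, "dic")) else "",
        pD = if (i == 1L) fmt2(attr(s, "pd")) else "",
        MLE = sprintf("%s (%s, %s)", fmt2(f$mle$coefficients[par]),
                      fmt2(f$mle$ci[par, "lower"]),
                      fmt2(f$mle$ci[par, "upper"])),
        check.names = FALSE)
    }
  }
  aft_rows <- list()
  par_label <- c(intercept = "Intercept", arm = "Arm", sigma = "Scale")
  for (resp in names(bundle$aft)) {
    f <- bundle$aft[[resp]]
    if (is.null(f$summary))
      stop("bundle is missing a converged AFT fit for '", resp, "'")
    s <- f$summary
    for (i in seq_len(nrow(s))) {
      aft_rows[[length(aft_rows) + 1L]] <- data.frame(
        Response = if (i == 1L) resp else "",
        Parameter = par_label[[s$parameter[i]]],
        `Posterior Mean (SD)` = sprintf("%s (%s)", fmt2(s$mean[i]),
                                        fmt2(s$sd[i])),
        `95% HPD` = sprintf("(%s, %s)", fmt2(s$hpd_lower[i]),
                            fmt2(s$hpd_upper[i])),
        DIC = if (i == 1L) fmt2(attr(s, "dic")) else "",
        pD = if (i == 1L) fmt2(attr(s, "pd")) else "",
        check.names = FALSE)
    }
  }
  list(cox_table = do.call(rbind, cox_rows),
       aft_table = do.call(rbind, aft_rows))
}

#' Write a report bundle to disk
#'
#' Writes Kaplan-Meier curve tables, the Cox and AFT report tables, all
#' posterior draws, the slope-difference density table, the combined-arm
#' report and the run manifest (JSON) into a directory.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_event_table(bundle$cohort, file.path(dir, "cohort.csv"))
  for (ep in names(bundle$km))
    utils::write.csv(bundle$km[[ep]]$table,
                     file.path(dir, sprintf("km_%s.csv", tolower(ep))),
                     row.names = FALSE)
  tabs <- render_tables(bundle)
  utils::write.csv(tabs$cox_table, file.path(dir, "cox_table.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$aft_table, file.path(dir, "aft_table.csv"),
                   row.names = FALSE)
  for (ep in names(bundle$cox))
    write_draws(bundle$cox[[ep]]$bayes$draws,
                file.path(dir, sprintf("cox_%s_draws.csv", tolower(ep))))
  for (resp in names(bundle$aft))
    write_draws(bundle$aft[[resp]]$draws,
                file.path(dir, sprintf("aft_%s_draws.csv", tolower(resp))))
  for (a in names(bundle$gap_regression))
    write_draws(bundle$gap_regression[[a]]$draws,
                file.path(dir, sprintf("gapreg_%s_draws.csv", a)))
  utils::write.csv(bundle$difference$density,
                   file.path(dir, "arm_difference_density.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(quantity = rownames(bundle$combined$table),
                         bundle$combined$table),
                   file.path(dir, "combined_arm_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
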