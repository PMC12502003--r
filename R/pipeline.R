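#' Run the full simulation and analysis pipeline
#'
#' End to end: simulate a cohort (calibration + continuous phase at 30% of
#' each participant's MST), excise and reconstruct crashes, apply the
#' participant-level outlier rule, compute per-participant iRT via DTW,
#' build trial tables, estimate bootstrap split-half reliability and the
#' stability curve, simulate and summarize a matched flanker cohort
#' (participant means coupled to the same latent lapse rate), and fit the
#' validity regressions with and without age. Every stage runs off one
#' master seed, so the whole bundle is reproducible; with `out_dir` set,
#' all tables are also written as CSV/JSON.
#'
#' @param n_participants Cohort size.
#' @param config A [task_config()].
#' @param seed Master integer seed.
#' @param param_sampler Controller-parameter sampler, as in
#'   [simulate_cohort()].
#' @param band Sakoe-Chiba half-width (samples) for the DTW step; `NULL`
#'   for exact alignment.
#' @param trim_edges_s Edge trim for the iRT mean (seconds).
#' @param bin_s Trial-unit bin width for reliability (seconds).
#' @param n_boot,n_perm Bootstrap draws and permutations per draw.
#' @param out_dir Optional output directory for the report bundle.
#' @return A `cpcst_bundle` list: `manifest`, `exclusions`, `irt_summary`,
#'   `compliance`, `reliability_irt`, `stability_irt`, `flanker_trials`,
#'   `flanker_summary`, `validity` (list of `cpcst_regression`), `records`,
#'   `seed`, and `log` (character vector of stage notes).
#' @export
run_pipeline <- function(n_participants = 20, config = task_config(),
                         seed = 1L, param_sampler = default_param_sampler(),
                         band = 90L, trim_edges_s = 1,
                         bin_s = 1, n_boot = 200L, n_perm = 50L,
                         out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("cpcst pipeline: n = %d, seed = %d", n_participants, seed)

  ## simulate
  cohort <- simulate_cohort(n_participants, param_sampler, config, seed)
  manifest <- cohort_manifest(cohort)
  note("simulated cohort; median MST %.2f /s", median(manifest$mst))

  ## preprocess + outlier rule
  cleaned <- lapply(cohort, function(p) excise_and_interpolate(p$trace, config))
  names(cleaned) <- manifest$participant_id
  exclusions <- apply_outlier_rule(vapply(cleaned, `[[`, integer(1), "n_crashes"))
  retained <- exclusions$participant_id[!exclusions$excluded]
  note("crash excision: %d total crashes; %d participant(s) excluded",
       sum(exclusions$n_crashes), sum(exclusions$excluded))

  ## compliance + iRT on retained participants
  traces <- lapply(cleaned[retained], `[[`, "trace")
  compliance <- compliance_cohort(traces, config)
  irts <- lapply(traces, compute_irt, config = config, band = band,
                 trim_edges_s = trim_edges_s)
  irt_summary <- data.frame(
    participant_id = retained,
    mean_irt_s = vapply(irts, `[[`, numeric(1), "mean_irt_s"),
    n_valid_samples = vapply(irts, `[[`, numeric(1), "n_valid_samples"),
    row.names = NULL)
  note("iRT computed for %d participants; mean of means %.3f s",
       length(irts), mean(irt_summary$mean_irt_s))

  ## trial tables, reliability, stability
  irt_table <- do.call(rbind, lapply(retained, function(id)
    irt_trial_table(irts[[id]], id, config, bin_s = bin_s)))
  reliability_irt <- NULL
  stability_irt <- NULL
  if (length(retained) >= 3) {
    reliability_irt <- bootstrap_reliability(irt_table, n_boot = n_boot,
                                             n_perm = n_perm, seed = seed + 1L)
    stability_irt <- stability_curve(
      irt_table, full_duration_min = ceiling(config$continuous_duration_s / 60))
    note("iRT split-half r = %.4f (95%% CI %.4f-%.4f)",
         reliability_irt$point, reliability_irt$ci_low, reliability_irt$ci_high)
  } else {
    warning("fewer than 3 retained participants; reliability and stability skipped")
    note("reliability/stability skipped: n < 3")
  }

  ## flanker cohort coupled to the same latent lapse rate
  flanker_trials <- simulate_flanker_cohort(
    n_participants, seed = seed + 2L,
    participant_shift_ms = 300 * manifest$lapse_rate_hz +
      rnorm(n_participants, 0, 20),
    ids = manifest$participant_id)
  flanker_summary <- flanker_summaries(flanker_trials)
  note("flanker: %d/%d participants pass the accuracy gate",
       sum(flanker_summary$included), n_participants)

  ## participant records + validity models
  records <- merge(merge(manifest[, c("participant_id", "lapse_rate_hz",
                                      "age_years", "mst")],
                         irt_summary, by = "participant_id"),
                   flanker_summary[flanker_summary$included,
                                   c("participant_id", "conRT", "incRT",
                                     "ic_effect")],
                   by = "participant_id", all.x = TRUE)
  records$ability_score <- simulate_outcome(records, seed = seed + 3L)
  validity <- list()
  if (nrow(records) >= 10) {
    for (oc in c("conRT", "incRT", "ic_effect", "ability_score")) {
      validity[[oc]] <- tryCatch(
        fit_validity_model(records, oc, include_age = FALSE),
        error = function(e) { note("validity %s: %s", oc, conditionMessage(e)); NULL })
      validity[[paste0(oc, "_age")]] <- tryCatch(
        fit_validity_model(records, oc, include_age = TRUE),
        error = function(e) NULL)
    }
    note("validity models fitted: %d", sum(!vapply(validity, is.null, logical(1))))
  } else {
    warning("fewer than 10 complete records; validity regressions skipped")
    note("validity skipped: n < 10")
  }

  bundle <- structure(
    list(manifest = manifest, exclusions = exclusions,
         irt_summary = irt_summary, compliance = compliance,
         reliability_irt = reliability_irt, stability_irt = stability_irt,
         flanker_trials = flanker_trials, flanker_summary = flanker_summary,
         validity = validity, records = records, seed = seed, log = log),
    class = "cpcst_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, cohort, cleaned, config)
  bundle
}

#' @export
print.cpcst_bundle <- function(x, ...) {
  cat("cpCST pipeline bundle\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}

## write the full report bundle as plain-text files
write_bundle <- function(bundle, out_dir, cohort, cleaned, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write.csv(bundle$manifest, p("cohort_manifest.csv"), row.names = FALSE)
  write.csv(bundle$exclusions, p("exclusion_report.csv"), row.names = FALSE)
  write.csv(bundle$irt_summary, p("irt_summary.csv"), row.names = FALSE)
  write.csv(bundle$flanker_summary, p("flanker_summary.csv"), row.names = FALSE)
  write.csv(bundle$flanker_trials, p("flanker_trials.csv"), row.names = FALSE)
  write.csv(bundle$records, p("participant_records.csv"), row.names = FALSE)
  cal <- calibration_tables(lapply(cohort, `[[`, "calibration"))
  write.csv(cal$crashes, p("calibration_crashes.csv"), row.names = FALSE)
  write.csv(cal$summary, p("calibration_summary.csv"), row.names = FALSE)
  traces <- do.call(rbind, lapply(cleaned, function(cl) as.data.frame(cl$trace)))
  write.csv(traces, p("cleaned_traces.csv"), row.names = FALSE)
  if (!is.null(bundle$stability_irt))
    write.csv(as.data.frame(bundle$stability_irt), p("stability_irt.csv"),
              row.names = FALSE)
  if (!is.null(bundle$reliability_irt))
    write_reliability_report(bundle$reliability_irt, p("reliability_irt.json"),
                             measure = "irt", seed = bundle$seed + 1L)
  for (nm in names(bundle$validity)) {
    if (!is.null(bundle$validity[[nm]]))
      write_regression_report(bundle$validity[[nm]],
                              p(sprintf("validity_%s.json", nm)))
  }
  writeLines(c(sprintf("cpcst %s; R %s", as.character(utils::packageVersion("cpcst")),
                       paste(R.version$major, R.version$minor, sep = ".")),
               sprintf("seed: %d", bundle$seed), bundle$log),
             p("pipeline_log.txt"))
  invisible(out_dir)
}
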