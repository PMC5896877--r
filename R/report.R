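#' Render a human-readable analysis report
#'
#' @param results An `icms_results` list from [analyze_sessions()].
#' @return Character vector of report lines, invisibly printed by
#'   `print.icms_results`.
#' @export
format_report <- function(results) {
  s <- results$summary
  cls <- table(results$electrode_classes$class)
  boot <- results$bootstrap
  lines <- c(
    "ICMS percept-mapping analysis",
    "=============================",
    sprintf("Responsive electrodes: %d/%d (%.0f%%)", s$n_responsive,
            s$n_electrodes_tested, s$pct_responsive),
    sprintf("Reported sensations: %d of %d non-catch trials",
            s$n_detected, s$n_noncatch_trials),
    sprintf("Catch trials: %d, false positives: %d", s$n_catch_trials,
            s$n_catch_false_positives),
    sprintf("Electrode classes: %s",
            paste(names(cls), as.integer(cls), sep = "=",
                  collapse = ", ")),
    sprintf("Modality vs amplitude: H = %.2f, p = %.3g",
            results$modality_amplitude$statistic,
            results$modality_amplitude$p_value),
    if (!is.null(results$modality_frequency)) {
      sprintf("Modality vs frequency: H = %.2f, p = %.3g",
              results$modality_frequency$statistic,
              results$modality_frequency$p_value)
    },
    sprintf("Intensity vs amplitude: r = %.3f, p = %.3g, slope = %.4f",
            results$intensity$pearson$statistic,
            results$intensity$pearson$p_value,
            results$intensity$fit[["slope"]]),
    sprintf("Durations short/medium/long: %s (missing %d)",
            paste(results$duration$counts, collapse = "/"),
            results$duration$n_missing),
    sprintf("Receptive fields consistent (region or plane): %d/%d",
            results$receptive_fields$n_consistent,
            nrow(results$receptive_fields$electrodes)),
    sprintf(paste("Bootstrap slopes: proprioceptive %.1f%% positive,",
                  "cutaneous %.1f%% negative"),
            100 * mean(boot$slopes_prop > 0),
            100 * mean(boot$slopes_cut < 0)),
    sprintf("Trial history within shuffle envelope: %d/%d conditionals",
            sum(c(results$trial_history$table$within_envelope_hit,
                  results$trial_history$table$within_envelope_miss),
                na.rm = TRUE),
            sum(!is.na(c(results$trial_history$table$within_envelope_hit,
                         results$trial_history$table$within_envelope_miss))))
  )
  lines[!vapply(lines, is.null, logical(1))]
}

#' @export
print.icms_results <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Write the analysis results bundle
#'
#' Emits plot-ready CSVs and a plain-text summary into a directory:
#' electrode classes, descriptor table, test results, per-amplitude
#' bootstrap medians, slope-KDE grids, and the trial-history table.
#'
#' @param results An `icms_results` list.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(name) file.path(dir, name)
  writeLines(format_report(results), out("summary.txt"))
  readr::write_csv(results$electrode_classes, out("electrode_classes.csv"))
  readr::write_csv(results$descriptors, out("descriptor_table.csv"))

  tests <- list(modality_amplitude = results$modality_amplitude,
                modality_frequency = results$modality_frequency,
                intensity_amplitude = results$intensity$pearson,
                intensity_sd_amplitude = results$intensity$sd_pearson,
                duration_amplitude = results$duration$kw_amplitude,
                duration_frequency = results$duration$kw_frequency)
  tests <- c(tests, results$impedance)
  tests <- tests[!vapply(tests, is.null, logical(1))]
  test_tbl <- dplyr::bind_rows(lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    tibble::tibble(analysis = nm, method = t$method,
                   statistic = t$statistic,
                   p_value = t$p_value, n = paste(t$n, collapse = "/"))
  }))
  readr::write_csv(test_tbl, out("test_results.csv"))

  boot <- results$bootstrap
  readr::write_csv(tibble::tibble(
    amplitude_uA = boot$amplitudes, pool_n = boot$pool_n,
    median_pct_proprioceptive = boot$median_pct_prop,
    median_pct_cutaneous = boot$median_pct_cut
  ), out("bootstrap_medians.csv"))
  if (!is.null(boot$kde_prop)) {
    readr::write_csv(tibble::tibble(
      slope = boot$kde_prop$x, density_proprioceptive = boot$kde_prop$y,
      density_cutaneous = predict(boot$kde_cut, boot$kde_prop$x)
    ), out("slope_kde.csv"))
  }
  readr::write_csv(results$trial_history$table, out("trial_history.csv"))
  invisible(dir)
}
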