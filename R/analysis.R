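#' @importFrom rlang .data
NULL

detected_responses <- function(sessions) {
  sessions[sessions$detected %in% TRUE & !sessions$is_catch, ]
}

# Sample mode; the smallest value among ties.
mode_min <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tab <- table(x)
  vals <- names(tab)[tab == max(tab)]
  if (is.numeric(x)) min(as.numeric(vals)) else min(vals)
}

#' Summarize detection outcomes
#'
#' Headline counts of an amplitude-mapping dataset: how many electrodes
#' elicited at least one percept, how many reports were collected over how
#' many non-catch trials, and the catch-trial false-positive count.
#'
#' @param sessions Session tibble.
#' @return List: `n_electrodes_tested`, `n_responsive`, `pct_responsive`,
#'   `n_detected`, `n_noncatch_trials`, `n_catch_trials`,
#'   `n_catch_false_positives`.
#' @export
summarize_detection <- function(sessions) {
  if (nrow(sessions) == 0) stop("empty session data", call. = FALSE)
  noncatch <- sessions[!sessions$is_catch, ]
  det <- detected_responses(sessions)
  tested <- unique(noncatch$electrode_id)
  responsive <- unique(det$electrode_id)
  list(
    n_electrodes_tested = length(tested),
    n_responsive = length(responsive),
    pct_responsive = if (length(tested)) 100 * length(responsive) /
      length(tested) else NA_real_,
    n_detected = nrow(det),
    n_noncatch_trials = nrow(noncatch),
    n_catch_trials = sum(sessions$is_catch),
    n_catch_false_positives = sum(sessions$is_catch & sessions$detected)
  )
}

#' Classify electrodes by percept modality
#'
#' Partitions responsive electrodes into cutaneous-only,
#' proprioceptive-only and mixed classes from their detected responses.
#' Mixed electrodes are subclassified by strict majority of responses
#' (`mostly_cutaneous` / `mostly_proprioceptive`), with an exact tie
#' labelled `equal`. Electrodes without any detected response are not
#' classified.
#'
#' @param sessions Session tibble (or detected-response subset).
#' @return Tibble: `electrode_id`, `n_cutaneous`, `n_proprioceptive`,
#'   `class`, `mixed_subclass` (NA unless mixed).
#' @export
classify_electrodes <- function(sessions) {
  det <- detected_responses(sessions)
  det <- det[det$modality %in% c("cutaneous", "proprioceptive"), ]
  out <- det |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::summarise(
      n_cutaneous = sum(.data$modality == "cutaneous"),
      n_proprioceptive = sum(.data$modality == "proprioceptive"),
      .groups = "drop"
    )
  out$class <- with(out, ifelse(
    n_proprioceptive == 0, "cutaneous_only",
    ifelse(n_cutaneous == 0, "proprioceptive_only", "mixed")))
  out$mixed_subclass <- with(out, ifelse(
    class != "mixed", NA_character_,
    ifelse(n_cutaneous > n_proprioceptive, "mostly_cutaneous",
           ifelse(n_proprioceptive > n_cutaneous,
                  "mostly_proprioceptive", "equal"))))
  dplyr::arrange(out, .data$electrode_id)
}

#' Descriptor prevalence table
#'
#' For each single-word descriptor: its share of all detected responses and
#' the mode and 25th/75th percentiles of the amplitudes and intensity
#' ratings that accompanied it, sorted by prevalence. Descriptors beyond a
#' cumulative-coverage threshold are pooled into `"other"`, mirroring the
#' convention of listing only the descriptors that cover ~90% of reports.
#' Percentiles interpolate linearly between order statistics; modes take
#' the smallest value among ties.
#'
#' @param sessions Session tibble.
#' @param coverage Cumulative share (0-1] of responses to itemize before
#'   pooling the tail.
#' @return Tibble: `descriptor`, `n`, `pct_of_total`, `amplitude_mode`,
#'   `amplitude_q25`, `amplitude_q75`, `intensity_mode`, `intensity_q25`,
#'   `intensity_q75`.
#' @export
descriptor_table <- function(sessions, coverage = 0.90) {
  det <- detected_responses(sessions)
  det <- det[!is.na(det$descriptor), ]
  if (nrow(det) == 0) stop("no detected responses with descriptors",
                           call. = FALSE)
  total <- nrow(det)
  counts <- sort(table(det$descriptor), decreasing = TRUE)
  keep <- names(counts)[c(0, utils::head(cumsum(counts), -1)) / total <
                          coverage]
  det$descriptor[!(det$descriptor %in% keep)] <- "other"

  summarise_one <- function(rows) {
    tibble::tibble(
      n = nrow(rows),
      pct_of_total = 100 * nrow(rows) / total,
      amplitude_mode = mode_min(rows$amplitude_uA),
      amplitude_q25 = unname(quantile(rows$amplitude_uA, 0.25,
                                      na.rm = TRUE)),
      amplitude_q75 = unname(quantile(rows$amplitude_uA, 0.75,
                                      na.rm = TRUE)),
      intensity_mode = mode_min(rows$intensity),
      intensity_q25 = unname(quantile(rows$intensity, 0.25, na.rm = TRUE)),
      intensity_q75 = unname(quantile(rows$intensity, 0.75, na.rm = TRUE))
    )
  }
  out <- det |>
    dplyr::group_by(descriptor = .data$descriptor) |>
    dplyr::group_modify(~summarise_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$pct_of_total), .data$descriptor)
  out
}

#' Test modality against a stimulation parameter
#'
#' Tie-corrected Kruskal-Wallis test comparing the stimulation parameter's
#' values between proprioceptive and cutaneous responses, i.e. whether the
#' parameter differentiates percept modality.
#'
#' @param sessions Session tibble.
#' @param parameter `"amplitude"` or `"frequency"`.
#' @return An `icms_test`.
#' @export
modality_parameter_tests <- function(sessions,
                                     parameter = c("amplitude",
                                                   "frequency")) {
  parameter <- match.arg(parameter)
  det <- detected_responses(sessions)
  col <- if (parameter == "amplitude") "amplitude_uA" else "frequency_hz"
  groups <- list(
    proprioceptive = det[[col]][det$modality == "proprioceptive"],
    cutaneous = det[[col]][det$modality == "cutaneous"]
  )
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("test undefined: need responses of both modalities",
         call. = FALSE)
  }
  kruskal_wallis(groups)
}

degenerate_test <- function(method, n) {
  new_test_result(method, NA_real_, NA_integer_, NA_real_, n,
                  extra = list(note = "no-variance"))
}

#' Impedance control analyses
#'
#' Checks that electrode impedance carries no information about percept
#' outcomes: (a) a two-sample Kolmogorov-Smirnov test of per-electrode mean
#' impedance for responsive versus non-responsive electrodes; (b) a
#' Kruskal-Wallis test of per-response session impedance between
#' proprioceptive and cutaneous responses; (c) Kruskal-Wallis tests of
#' per-response impedance between unimodal electrode classes
#' (cutaneous-only vs proprioceptive-only) and unimodal vs mixed; (d) a
#' Pearson correlation between per-electrode mean impedance and the
#' electrode's response rate (detections per non-catch trial, pooled over
#' days).
#'
#' @param sessions Session tibble with `impedance_kohm` populated for all
#'   non-catch trials.
#' @return Named list of `icms_test` objects: `ks_responsive`,
#'   `kw_modality`, `kw_unimodal`, `kw_mixed`, `pearson_response_rate`.
#'   Tests on constant impedance are reported with a `no-variance` note.
#' @export
impedance_tests <- function(sessions) {
  noncatch <- sessions[!sessions$is_catch, ]
  missing_imp <- unique(noncatch$electrode_id[is.na(noncatch$impedance_kohm)])
  if (length(missing_imp)) {
    stop("missing impedance for electrode(s): ",
         paste(sort(missing_imp), collapse = ", "), call. = FALSE)
  }
  per_electrode <- noncatch |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::summarise(impedance = mean(.data$impedance_kohm),
                     response_rate = mean(.data$detected),
                     .groups = "drop")
  responsive_ids <- unique(detected_responses(sessions)$electrode_id)
  imp_resp <- per_electrode$impedance[per_electrode$electrode_id %in%
                                        responsive_ids]
  imp_non <- per_electrode$impedance[!(per_electrode$electrode_id %in%
                                         responsive_ids)]
  ks <- if (length(imp_resp) && length(imp_non)) {
    ks_two_sample(imp_resp, imp_non)
  } else degenerate_test("ks_two_sample", c(length(imp_resp),
                                            length(imp_non)))

  det <- detected_responses(sessions)
  kw_modality <- {
    g <- split(det$impedance_kohm, det$modality)
    g <- g[c("proprioceptive", "cutaneous")]
    g <- g[!vapply(g, is.null, logical(1))]
    if (length(g) == 2) kruskal_wallis(g) else
      degenerate_test("kruskal_wallis", vapply(g, length, integer(1)))
  }

  cls <- classify_electrodes(sessions)
  det$eclass <- cls$class[match(det$electrode_id, cls$electrode_id)]
  kw_pair <- function(a, b) {
    g <- list(det$impedance_kohm[det$eclass %in% a],
              det$impedance_kohm[det$eclass %in% b])
    if (all(vapply(g, length, integer(1)) > 0)) kruskal_wallis(g) else
      degenerate_test("kruskal_wallis", vapply(g, length, integer(1)))
  }
  kw_unimodal <- kw_pair("cutaneous_only", "proprioceptive_only")
  kw_mixed <- kw_pair(c("cutaneous_only", "proprioceptive_only"), "mixed")

  pearson_rate <- tryCatch(
    pearson_corr(per_electrode$impedance, per_electrode$response_rate),
    error = function(e) degenerate_test("pearson",
                                        nrow(per_electrode)))

  list(ks_responsive = ks, kw_modality = kw_modality,
       kw_unimodal = kw_unimodal, kw_mixed = kw_mixed,
       pearson_response_rate = pearson_rate)
}

#' Intensity versus amplitude analysis
#'
#' Correlates reported intensity (1-10) with stimulation amplitude and fits
#' the least-squares line. Because intensity ratings drift day to day, a
#' per-session normalization rescales ratings to 0-1 within each session
#' day before the variability analysis: the per-amplitude standard
#' deviation of normalized intensity and its correlation with amplitude.
#' The default normalization is min-max,
#' `(x - min) / (max - min)`; the `"literal"` variant divides the
#' min-subtracted rating by the session maximum instead.
#'
#' @param sessions Session tibble.
#' @param normalization `"minmax"` or `"literal"`.
#' @return List: `pearson` (`icms_test` of raw intensity vs amplitude),
#'   `fit` (slope and intercept), `mean_by_amplitude` tibble,
#'   `sd_by_amplitude` tibble of normalized-intensity SDs, `sd_pearson`
#'   (SD-vs-amplitude correlation, NA-degenerate when < 3 amplitudes),
#'   `degenerate_sessions` (days with constant intensity, excluded from
#'   the SD analysis).
#' @export
intensity_analysis <- function(sessions,
                               normalization = c("minmax", "literal")) {
  normalization <- match.arg(normalization)
  det <- detected_responses(sessions)
  det <- det[!is.na(det$intensity) & !is.na(det$amplitude_uA), ]
  if (nrow(det) < 3) stop("need at least 3 responses with intensity",
                          call. = FALSE)
  pearson <- pearson_corr(det$amplitude_uA, det$intensity)
  fit <- polyfit1(det$amplitude_uA, det$intensity)

  norm_one <- function(x) {
    if (max(x) == min(x)) return(rep(NA_real_, length(x)))
    if (normalization == "minmax") (x - min(x)) / (max(x) - min(x))
    else (x - min(x)) / max(x)
  }
  det <- det |>
    dplyr::group_by(.data$session_day) |>
    dplyr::mutate(intensity_norm = norm_one(.data$intensity)) |>
    dplyr::ungroup()
  degenerate <- sort(unique(det$session_day[is.na(det$intensity_norm)]))

  mean_by_amplitude <- det |>
    dplyr::group_by(amplitude_uA = .data$amplitude_uA) |>
    dplyr::summarise(n = dplyr::n(), mean_intensity = mean(.data$intensity),
                     sd_intensity = sd(.data$intensity), .groups = "drop")
  sd_by_amplitude <- det[!is.na(det$intensity_norm), ] |>
    dplyr::group_by(amplitude_uA = .data$amplitude_uA) |>
    dplyr::summarise(n = dplyr::n(),
                     sd_norm_intensity = sd(.data$intensity_norm),
                     .groups = "drop")
  sd_ok <- !is.na(sd_by_amplitude$sd_norm_intensity)
  sd_pearson <- if (sum(sd_ok) >= 3) {
    tryCatch(pearson_corr(sd_by_amplitude$amplitude_uA[sd_ok],
                          sd_by_amplitude$sd_norm_intensity[sd_ok]),
             error = function(e) degenerate_test("pearson", sum(sd_ok)))
  } else degenerate_test("pearson", sum(sd_ok))

  list(pearson = pearson, fit = fit,
       mean_by_amplitude = mean_by_amplitude,
       sd_by_amplitude = sd_by_amplitude, sd_pearson = sd_pearson,
       degenerate_sessions = degenerate)
}

#' Percept-duration analysis
#'
#' Tallies short/medium/long percept durations (and responses with no
#' recorded duration) and tests whether stimulation amplitude or frequency
#' differs across duration categories (tie-corrected Kruskal-Wallis).
#'
#' @param sessions Session tibble.
#' @return List: `counts` (named short/medium/long), `n_missing`,
#'   `kw_amplitude`, `kw_frequency` (NULL when fewer than two duration
#'   categories are present, or frequency does not vary).
#' @export
duration_analysis <- function(sessions) {
  det <- detected_responses(sessions)
  counts <- vapply(c("short", "medium", "long"), function(lv) {
    sum(det$duration_category %in% lv)
  }, integer(1))
  n_missing <- sum(is.na(det$duration_category))
  with_dur <- det[!is.na(det$duration_category), ]
  kw_for <- function(col) {
    g <- split(with_dur[[col]], with_dur$duration_category)
    g <- g[vapply(g, length, integer(1)) > 0]
    if (length(g) < 2 || length(unique(unlist(g))) < 2) return(NULL)
    kruskal_wallis(g)
  }
  list(counts = counts, n_missing = n_missing,
       kw_amplitude = kw_for("amplitude_uA"),
       kw_frequency = if (length(unique(with_dur$frequency_hz[
         !is.na(with_dur$frequency_hz)])) > 1) kw_for("frequency_hz")
       else NULL)
}

#' Receptive-field consistency
#'
#' Per electrode, whether the reported receptive field stayed in one body
#' region (upper arm / forearm / hand) or one plane (anterior / posterior)
#' across all its detected responses, together with the modal
#' (region, plane) cell. Per array, the distribution of responses over
#' (region, plane) cells and the modal cell's share.
#'
#' @param sessions Session tibble.
#' @return List: `electrodes` tibble (`electrode_id`, `n_responses`,
#'   `consistent_region`, `consistent_plane`, `consistent_any`,
#'   `modal_field`), `n_consistent` (count consistent in region or plane),
#'   `arrays` tibble (`array`, `modal_field`, `modal_share`, and the full
#'   `distribution` list-column).
#' @export
receptive_field_consistency <- function(sessions) {
  det <- detected_responses(sessions)
  det <- det[!is.na(det$region) & !is.na(det$plane), ]
  if (nrow(det) == 0) stop("no detected responses with receptive fields",
                           call. = FALSE)
  det$field <- paste(det$region, det$plane, sep = ":")
  electrodes <- det |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::summarise(
      n_responses = dplyr::n(),
      consistent_region = length(unique(.data$region)) == 1,
      consistent_plane = length(unique(.data$plane)) == 1,
      modal_field = mode_min(.data$field),
      .groups = "drop"
    )
  electrodes$consistent_any <- electrodes$consistent_region |
    electrodes$consistent_plane
  arrays <- det |>
    dplyr::group_by(array = .data$array) |>
    dplyr::summarise(
      n_responses = dplyr::n(),
      modal_field = mode_min(.data$field),
      modal_share = max(table(.data$field)) / dplyr::n(),
      distribution = list(table(.data$field) / dplyr::n()),
      .groups = "drop"
    )
  list(electrodes = electrodes,
       n_consistent = sum(electrodes$consistent_any),
       arrays = arrays)
}

#' Run the full analysis pipeline
#'
#' Convenience wrapper chaining every analysis stage over one session
#' table: detection summary, electrode classification, descriptor table,
#' modality-vs-parameter tests, impedance controls, intensity and duration
#' analyses, receptive-field consistency, the modality bootstrap and the
#' trial-history permutation null.
#'
#' @param sessions Session tibble.
#' @param n_iter Bootstrap iterations.
#' @param n_perm Trial-history permutations.
#' @param seed Seed for the two resampling stages.
#' @return Named list of stage results (class `icms_results`).
#' @export
analyze_sessions <- function(sessions, n_iter = 10000L, n_perm = 10000L,
                             seed = 1L) {
  det <- detected_responses(sessions)
  has_freq_design <- length(unique(sessions$frequency_hz[
    !is.na(sessions$frequency_hz)])) > 1
  res <- list(
    summary = summarize_detection(sessions),
    electrode_classes = classify_electrodes(sessions),
    descriptors = descriptor_table(sessions),
    modality_amplitude = modality_parameter_tests(sessions, "amplitude"),
    modality_frequency = if (has_freq_design)
      modality_parameter_tests(sessions, "frequency") else NULL,
    impedance = impedance_tests(sessions),
    intensity = intensity_analysis(sessions),
    duration = duration_analysis(sessions),
    receptive_fields = receptive_field_consistency(sessions),
    bootstrap = bootstrap_modality_slopes(
      det, n_iter = n_iter, seed = derive_seed(seed, "bootstrap")),
    trial_history = trial_history_null(
      sessions, n_perm = n_perm, seed = derive_seed(seed, "history"))
  )
  structure(res, class = "icms_results")
}
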