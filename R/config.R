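#' Fixed descriptor vocabulary and its modality map
#'
#' Single-word percept descriptors are partitioned into cutaneous
#' (touch-like) and proprioceptive (movement/position-like) classes;
#' `"other"` is modality-ambiguous and admitted under either class. The map
#' is used both by the simulator (to draw modality-consistent descriptors)
#' and by session validation.
#'
#' @return Named character vector mapping descriptor to modality
#'   (`"cutaneous"`, `"proprioceptive"` or `"any"`).
#' @export
descriptor_modality_map <- function() {
  c(
    squeeze = "cutaneous", tap = "cutaneous", vibration = "cutaneous",
    blowing = "cutaneous", pinch = "cutaneous", press = "cutaneous",
    goosebumps = "cutaneous",
    right_movement = "proprioceptive", forward_movement = "proprioceptive",
    upward_movement = "proprioceptive",
    other = "any"
  )
}

#' Default receptive-field weights for one array
#'
#' Weights over the six (region, plane) cells of the body map. The medial
#' array concentrates on the anterior upper arm and the lateral array on the
#' posterior forearm, reproducing the coarse across-array somatotopy of the
#' implant site.
#'
#' @param array `"medial"` or `"lateral"`.
#' @return Named numeric vector over `region:plane` cells, summing to 1.
#' @export
default_region_weights <- function(array = c("medial", "lateral")) {
  array <- match.arg(array)
  w <- if (array == "medial") {
    c("upper_arm:anterior" = 0.46, "upper_arm:posterior" = 0.20,
      "forearm:anterior" = 0.12, "forearm:posterior" = 0.12,
      "hand:anterior" = 0.05, "hand:posterior" = 0.05)
  } else {
    c("forearm:posterior" = 0.51, "forearm:anterior" = 0.15,
      "upper_arm:anterior" = 0.12, "upper_arm:posterior" = 0.12,
      "hand:anterior" = 0.05, "hand:posterior" = 0.05)
  }
  w / sum(w)
}

# Descriptor frequencies within each modality. The relative weights follow
# the observed prevalence of each single-word descriptor among cutaneous
# (respectively proprioceptive) reports, with the residual mass assigned to
# "other".
default_descriptor_weights <- function() {
  cut <- c(squeeze = 24.9, tap = 17.3, vibration = 8.1, blowing = 6.6,
           pinch = 5.5, press = 5.0, goosebumps = 3.1, other = 8.8)
  prop <- c(right_movement = 9.7, forward_movement = 5.8,
            upward_movement = 3.9, other = 1.3)
  list(cutaneous = cut / sum(cut), proprioceptive = prop / sum(prop))
}

#' Simulator configuration
#'
#' Bundles every generative default of the synthetic-data module. Defaults
#' are calibrated so that full amplitude-mapping simulations reproduce the
#' summary structure of a human single-electrode ICMS percept-mapping
#' session series: about 48% of stimulable electrodes responsive, roughly
#' 31% of non-catch trials yielding a report, a pooled proprioceptive
#' fraction near 0.21 that grows with amplitude, reported intensity rising
#' by 0.02 a.u. per microampere, duration categories in proportion
#' 225:122:12 (short:medium:long), and no false positives on catch trials.
#'
#' @param seed Master seed for all derived streams.
#' @param n_arrays,grid_dim,connected_per_array Array geometry: two 7x7
#'   grids with 48 physically connected (stimulable) sites each.
#' @param responsive_fraction Probability that an electrode elicits percepts
#'   at all.
#' @param p_detect_base_mean,p_detect_base_conc Mean and concentration
#'   (alpha + beta) of the Beta distribution from which each responsive
#'   electrode's baseline detection probability is drawn.
#' @param detect_amp_slope Per-microampere increment added to the baseline
#'   detection probability (clipped to `[0, 1]`); kept small because the
#'   dependence of detectability on amplitude is weak.
#' @param modality_beta0,modality_beta1 Logistic intercept and
#'   per-microampere slope of P(proprioceptive | detected). The positive
#'   slope skews proprioceptive reports towards higher amplitudes while
#'   leaving frequency without effect.
#' @param modality_beta0_sd Between-electrode SD of the logistic intercept.
#'   A non-zero spread makes some electrodes effectively unimodal
#'   (cutaneous-only or proprioceptive-only) while others yield mixed
#'   percepts, as observed across a real array.
#' @param intensity_intercept,intensity_slope,intensity_noise_sd Latent
#'   linear model of reported intensity (a.u.) versus amplitude; reports are
#'   rounded and clipped to the 1-10 rating scale.
#' @param duration_weights Probabilities of short/medium/long percept
#'   duration, given that a duration was recorded.
#' @param duration_missing_rate Probability that a detected response has no
#'   recorded duration.
#' @param impedance_meanlog,impedance_sdlog Log-normal parameters of
#'   per-electrode baseline impedance (kOhm); identical for responsive and
#'   non-responsive electrodes, so impedance carries no information about
#'   responsiveness.
#' @param impedance_session_sdlog Log-scale SD of the multiplicative
#'   session-to-session impedance jitter.
#' @param descriptor_weights List with `cutaneous` and `proprioceptive`
#'   named weight vectors over the descriptor vocabulary.
#' @param region_concentration Weight an electrode places on its own home
#'   (region, plane) cell; the remainder follows the array-level weights, so
#'   array marginals are preserved while most electrodes report spatially
#'   consistent receptive fields.
#' @param region_weights List with `medial` and `lateral` array-level
#'   weight vectors (see [default_region_weights()]).
#' @return An object of class `icms_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 42)
#' cfg$responsive_fraction
simulation_config <- function(seed = 1L,
                              n_arrays = 2L,
                              grid_dim = 7L,
                              connected_per_array = 48L,
                              responsive_fraction = 0.48,
                              p_detect_base_mean = 0.526,
                              p_detect_base_conc = 25,
                              detect_amp_slope = 0.002,
                              modality_beta0 = -4.5,
                              modality_beta0_sd = 2.5,
                              modality_beta1 = 0.03,
                              intensity_intercept = 2.0,
                              intensity_slope = 0.02,
                              intensity_noise_sd = 1.9,
                              duration_weights = c(short = 225, medium = 122,
                                                   long = 12) / 359,
                              duration_missing_rate = 22 / 381,
                              impedance_meanlog = log(40),
                              impedance_sdlog = 0.35,
                              impedance_session_sdlog = 0.05,
                              descriptor_weights = default_descriptor_weights(),
                              region_concentration = 0.90,
                              region_weights = list(
                                medial = default_region_weights("medial"),
                                lateral = default_region_weights("lateral"))) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (responsive_fraction < 0 || responsive_fraction > 1) {
    stop("`responsive_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (grid_dim < 1 || connected_per_array > grid_dim^2) {
    stop("invalid grid: `connected_per_array` exceeds grid capacity",
         call. = FALSE)
  }
  if (length(duration_weights) != 3L ||
      abs(sum(duration_weights) - 1) > 1e-8 || any(duration_weights < 0)) {
    stop("`duration_weights` must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (duration_missing_rate < 0 || duration_missing_rate > 1) {
    stop("`duration_missing_rate` must lie in [0, 1]", call. = FALSE)
  }
  for (m in c("cutaneous", "proprioceptive")) {
    w <- descriptor_weights[[m]]
    if (is.null(w) || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("`descriptor_weights$", m, "` must be probabilities summing to 1",
           call. = FALSE)
    }
    map <- descriptor_modality_map()
    bad <- names(w)[!(map[names(w)] %in% c(m, "any"))]
    if (length(bad)) {
      stop("descriptor(s) ", paste(bad, collapse = ", "),
           " not in the ", m, " vocabulary", call. = FALSE)
    }
  }
  structure(
    list(
      seed = as.integer(seed),
      n_arrays = as.integer(n_arrays),
      grid_dim = as.integer(grid_dim),
      connected_per_array = as.integer(connected_per_array),
      responsive_fraction = responsive_fraction,
      p_detect_base_mean = p_detect_base_mean,
      p_detect_base_conc = p_detect_base_conc,
      detect_amp_slope = detect_amp_slope,
      modality_beta0 = modality_beta0,
      modality_beta0_sd = modality_beta0_sd,
      modality_beta1 = modality_beta1,
      intensity_intercept = intensity_intercept,
      intensity_slope = intensity_slope,
      intensity_noise_sd = intensity_noise_sd,
      duration_weights = duration_weights,
      duration_missing_rate = duration_missing_rate,
      impedance_meanlog = impedance_meanlog,
      impedance_sdlog = impedance_sdlog,
      impedance_session_sdlog = impedance_session_sdlog,
      descriptor_weights = descriptor_weights,
      region_concentration = region_concentration,
      region_weights = region_weights
    ),
    class = "icms_config"
  )
}

#' @export
print.icms_config <- function(x, ...) {
  cat("<icms_config>\n")
  cat("  electrodes:", x$n_arrays * x$connected_per_array,
      sprintf("(%d arrays, %dx%d grid, %d connected each)\n",
              x$n_arrays, x$grid_dim, x$grid_dim, x$connected_per_array))
  cat(sprintf("  responsive fraction: %.2f\n", x$responsive_fraction))
  cat(sprintf("  detection: base ~ Beta(mean %.3f) + %.4f/uA\n",
              x$p_detect_base_mean, x$detect_amp_slope))
  cat(sprintf("  modality: logit P(prop) = %.2f + %.3f * amplitude\n",
              x$modality_beta0, x$modality_beta1))
  cat(sprintf("  intensity: %.2f + %.3f * amplitude (sd %.2f)\n",
              x$intensity_intercept, x$intensity_slope, x$intensity_noise_sd))
  invisible(x)
}
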