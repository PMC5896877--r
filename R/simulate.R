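#' @importFrom stats plogis rbeta rbinom rlnorm rnorm runif
NULL

region_abbrev <- c(upper_arm = "UA", forearm = "FA", hand = "HD")

# Vectorized percept-report generator. All inputs are per-trial vectors of
# equal length; draws happen in a fixed column order so a seeded run is
# bit-reproducible. Returns a tibble of report columns.
generate_reports <- function(responsive, p_base, amp_slope, beta0, beta1,
                             amplitude, is_catch, region_weights,
                             config) {
  n <- length(is_catch)
  p_detect <- ifelse(is_catch | !responsive, 0,
                     pmin(pmax(p_base + amp_slope * amplitude, 0), 1))
  detected <- runif(n) < p_detect

  modality <- rep("none", n)
  descriptor <- rep(NA_character_, n)
  region <- rep(NA_character_, n)
  plane <- rep(NA_character_, n)
  grid_cell <- rep(NA_character_, n)
  intensity <- rep(NA_integer_, n)
  duration <- rep(NA_character_, n)

  idx <- which(detected)
  if (length(idx)) {
    p_prop <- plogis(beta0[idx] + beta1[idx] * amplitude[idx])
    is_prop <- runif(length(idx)) < p_prop
    modality[idx] <- ifelse(is_prop, "proprioceptive", "cutaneous")

    dw <- config$descriptor_weights
    descriptor[idx] <- vapply(modality[idx], function(m) {
      w <- dw[[m]]
      sample(names(w), 1L, prob = w)
    }, character(1))

    cells <- vapply(idx, function(i) {
      w <- region_weights[[i]]
      sample(names(w), 1L, prob = w)
    }, character(1))
    parts <- strsplit(cells, ":", fixed = TRUE)
    region[idx] <- vapply(parts, `[`, character(1), 1L)
    plane[idx] <- vapply(parts, `[`, character(1), 2L)
    grid_cell[idx] <- sprintf("%s-%s%02d", region_abbrev[region[idx]],
                              toupper(substr(plane[idx], 1, 1)),
                              sample.int(12L, length(idx), replace = TRUE))

    raw <- config$intensity_intercept +
      config$intensity_slope * amplitude[idx] +
      rnorm(length(idx), 0, config$intensity_noise_sd)
    intensity[idx] <- as.integer(pmin(pmax(round(raw), 1), 10))

    recorded <- runif(length(idx)) >= config$duration_missing_rate
    dur <- sample(names(config$duration_weights), length(idx),
                  replace = TRUE, prob = config$duration_weights)
    duration[idx] <- ifelse(recorded, dur, NA_character_)
  }

  tibble::tibble(detected = detected, modality = modality,
                 descriptor = descriptor, region = region, plane = plane,
                 grid_cell = grid_cell, intensity = intensity,
                 duration_category = duration)
}

#' Simulate the percept report for a single trial
#'
#' Draws one subject report for a stimulation (or catch) trial using the
#' caller's RNG state. Catch trials and non-responsive electrodes never
#' yield a detection, so the simulated catch false-positive rate is exactly
#' zero by construction. On detected trials the modality is proprioceptive
#' with probability `plogis(beta0 + beta1 * amplitude)`, the descriptor is
#' drawn from the modality-consistent vocabulary, the receptive field from
#' the electrode's (region, plane) weights, intensity from a rounded and
#' clipped linear-in-amplitude model, and duration from the configured
#' category weights (with a recorded-at-all probability).
#'
#' @param profile One electrode profile (single row of
#'   [make_electrode_population()] output).
#' @param stim A [stim_params()] object or list with `amplitude_uA`.
#' @param is_catch Whether the trial delivers no stimulation.
#' @param config An [simulation_config()].
#' @return One-row tibble with `detected`, `modality`, `descriptor`,
#'   `region`, `plane`, `grid_cell`, `intensity`, `duration_category`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1)
#' pop <- make_electrode_population(cfg)
#' set.seed(9)
#' simulate_response(pop[1, ], stim_params(80), config = cfg)
simulate_response <- function(profile, stim, is_catch = FALSE,
                              config = simulation_config()) {
  stopifnot(nrow(profile) == 1L)
  amp <- stim$amplitude_uA
  if (!is_catch && (is.null(amp) || amp <= 0)) {
    stop("stimulation trial needs a positive amplitude", call. = FALSE)
  }
  generate_reports(profile$responsive, profile$p_detect_base,
                   profile$detect_amp_slope, profile$modality_beta0,
                   profile$modality_beta1,
                   if (is_catch) NA_real_ else amp, is_catch,
                   profile$region_weights, config)
}

#' Simulate a full experiment over a trial schedule
#'
#' Runs the report generator over every trial of a schedule, in order, and
#' attaches a per-session impedance snapshot (each electrode's baseline
#' impedance with multiplicative session-to-session jitter, measured at the
#' start of every session). Randomness is drawn from streams derived from
#' `config$seed` (or `seed`), so repeated calls are bit-identical.
#'
#' @param schedule Trial tibble from [build_exp1_schedule()],
#'   [build_exp1_block()] or [build_exp2_schedule()].
#' @param profiles Electrode tibble from [make_electrode_population()].
#' @param config An [simulation_config()].
#' @param seed Optional master seed overriding `config$seed`.
#' @return Session tibble: the schedule columns joined with electrode
#'   geometry, the report columns, and `impedance_kohm` for the trial's
#'   session.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 3)
#' pop <- make_electrode_population(cfg)
#' sched <- build_exp2_schedule(pop$electrode_id[1:5], days = 1, seed = 3)
#' sess <- simulate_experiment(sched, pop, cfg)
#' mean(sess$detected)
simulate_experiment <- function(schedule, profiles,
                                config = simulation_config(),
                                seed = NULL) {
  if (nrow(schedule) == 0) {
    return(empty_session_table())
  }
  used <- unique(schedule$electrode_id[!schedule$is_catch])
  unknown <- setdiff(used, profiles$electrode_id)
  if (length(unknown)) {
    stop("schedule references unknown electrode id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  seed <- if (is.null(seed)) config$seed else seed

  pi <- match(schedule$electrode_id, profiles$electrode_id)

  # per-session impedance snapshot for every electrode
  days <- sort(unique(schedule$session_day))
  imp <- with_stream(derive_seed(seed, "impedance"), {
    dplyr::bind_rows(lapply(days, function(d) {
      tibble::tibble(
        session_day = d,
        electrode_id = profiles$electrode_id,
        impedance_kohm = profiles$impedance_kohm *
          rlnorm(nrow(profiles), 0, config$impedance_session_sdlog)
      )
    }))
  })

  reports <- with_stream(derive_seed(seed, "responses"), {
    generate_reports(
      responsive = profiles$responsive[pi] %in% TRUE,
      p_base = ifelse(is.na(pi), 0, profiles$p_detect_base[pi]),
      amp_slope = ifelse(is.na(pi), 0, profiles$detect_amp_slope[pi]),
      beta0 = profiles$modality_beta0[pi],
      beta1 = profiles$modality_beta1[pi],
      amplitude = schedule$amplitude_uA,
      is_catch = schedule$is_catch,
      region_weights = profiles$region_weights[pmax(pi, 1L)],
      config = config
    )
  })

  out <- dplyr::bind_cols(
    schedule,
    tibble::tibble(array = profiles$array[pi],
                   row = profiles$row[pi], col = profiles$col[pi]),
    reports
  )
  out <- dplyr::left_join(out, imp,
                          by = c("session_day", "electrode_id"))
  out <- dplyr::rename(out, trial_index = "order_index")
  out[, session_columns()]
}
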