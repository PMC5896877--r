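# Hand-built fixtures. make_session_rows() fills a complete session-schema
# tibble from a few per-trial vectors so analysis tests can state their
# inputs compactly.
make_session_rows <- function(n,
                              electrode_id = 1L,
                              amplitude_uA = 60,
                              frequency_hz = 150,
                              session_day = 1L,
                              block = 1L,
                              detected = TRUE,
                              modality = NA_character_,
                              descriptor = NA_character_,
                              region = NA_character_,
                              plane = NA_character_,
                              intensity = NA_integer_,
                              duration_category = NA_character_,
                              impedance_kohm = 40,
                              is_catch = FALSE,
                              array = "medial",
                              trial_index = NULL) {
  rep_n <- function(x) rep_len(x, n)
  detected <- rep_n(detected)
  modality <- rep_n(modality)
  modality[is.na(modality)] <- ifelse(detected[is.na(modality)],
                                      "cutaneous", "none")
  tibble::tibble(
    experiment = "exp1",
    session_day = as.integer(rep_n(session_day)),
    block = as.integer(rep_n(block)),
    trial_index = if (is.null(trial_index)) seq_len(n) else
      as.integer(rep_n(trial_index)),
    electrode_id = as.integer(rep_n(electrode_id)),
    array = rep_n(array),
    row = 0L, col = 0L,
    amplitude_uA = rep_n(amplitude_uA),
    frequency_hz = rep_n(frequency_hz),
    pulse_width_us = 200, interphase_us = 53, duration_s = 1,
    is_catch = rep_n(is_catch),
    detected = detected,
    modality = modality,
    descriptor = rep_n(descriptor),
    region = ifelse(detected, rep_n(region), NA_character_),
    plane = ifelse(detected, rep_n(plane), NA_character_),
    grid_cell = NA_character_,
    intensity = as.integer(ifelse(detected, rep_n(intensity), NA)),
    duration_category = ifelse(detected, rep_n(duration_category),
                               NA_character_),
    impedance_kohm = rep_n(impedance_kohm)
  )
}

# A small fully connected single-array grid for adjacency tests.
make_grid_profiles <- function(dim = 7L, array = "medial") {
  g <- expand.grid(row = 0:(dim - 1), col = 0:(dim - 1))
  tibble::tibble(electrode_id = seq_len(nrow(g)), array = array,
                 row = g$row, col = g$col)
}

# Default-config simulated Experiment-1 dataset, memoised per seed so
# several test files can reuse the same run cheaply.
sim_exp1_cache <- new.env(parent = emptyenv())
simulate_default_exp1 <- function(seed) {
  key <- as.character(seed)
  if (is.null(sim_exp1_cache[[key]])) {
    cfg <- simulation_config(seed = seed)
    pop <- make_electrode_population(cfg)
    sched <- build_exp1_schedule(pop, seed = derive_seed(seed, "schedule"))
    sim_exp1_cache[[key]] <- list(
      config = cfg, profiles = pop, schedule = sched,
      sessions = simulate_experiment(sched, pop, cfg)
    )
  }
  sim_exp1_cache[[key]]
}
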