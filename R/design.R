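#' Standard stimulation parameter sets
#'
#' The primary amplitude-mapping task (Experiment 1) tests eight amplitudes
#' at a fixed 150 Hz; the parameter-wide task (Experiment 2) crosses five
#' amplitudes with six pulse frequencies.
#'
#' @return Numeric vectors of amplitudes (microamps) or frequencies (Hz).
#' @export
exp1_amplitudes <- function() c(20, 30, 40, 60, 70, 80, 90, 100)

#' @rdname exp1_amplitudes
#' @export
exp2_amplitudes <- function() c(20, 40, 60, 80, 100)

#' @rdname exp1_amplitudes
#' @export
exp2_frequencies <- function() c(50, 100, 150, 200, 250, 300)

#' Charge delivered per pulse phase
#'
#' For a charge-balanced biphasic pulse the charge per phase is
#' `amplitude (uA) * phase width (us) / 1000` nanocoulombs. A hard safety
#' ceiling of 20 nC per phase bounds the stimulation dose; parameter sets
#' above it are rejected rather than silently clipped.
#'
#' @param amplitude_uA Pulse amplitude in microamps (> 0).
#' @param pulse_width_us Phase width in microseconds (> 0).
#' @param max_nC Safety ceiling in nC; set to `Inf` to compute without
#'   enforcement.
#' @return Charge per phase in nC.
#' @export
#' @examples
#' charge_per_phase(100, 200) # 20 nC, at the safety ceiling
#' charge_per_phase(60, 200)  # 12 nC
charge_per_phase <- function(amplitude_uA, pulse_width_us = 200,
                             max_nC = 20) {
  if (!is.numeric(amplitude_uA) || !is.numeric(pulse_width_us) ||
      any(amplitude_uA <= 0) || any(pulse_width_us <= 0)) {
    stop("amplitude and pulse width must be positive", call. = FALSE)
  }
  q <- amplitude_uA * pulse_width_us / 1000
  if (any(q > max_nC + 1e-12)) {
    stop(sprintf("charge per phase %.3g nC exceeds the %.3g nC safety limit",
                 max(q), max_nC), call. = FALSE)
  }
  q
}

#' Construct a validated stimulus parameter set
#'
#' Encodes one biphasic, charge-balanced, cathodic-leading pulse train and
#' validates the charge-per-phase safety ceiling on construction.
#'
#' @param amplitude_uA Amplitude in microamps.
#' @param frequency_hz Pulse frequency in Hz.
#' @param pulse_width_us Phase width in microseconds.
#' @param interphase_us Interphase gap in microseconds.
#' @param train_duration_s Stimulus train duration in seconds.
#' @return A list of class `icms_stim`.
#' @export
stim_params <- function(amplitude_uA, frequency_hz = 150,
                        pulse_width_us = 200, interphase_us = 53,
                        train_duration_s = 1.0) {
  if (!is.numeric(frequency_hz) || frequency_hz <= 0) {
    stop("frequency must be positive", call. = FALSE)
  }
  charge_per_phase(amplitude_uA, pulse_width_us) # validates sign + safety
  structure(
    list(amplitude_uA = amplitude_uA, frequency_hz = frequency_hz,
         pulse_width_us = pulse_width_us, interphase_us = interphase_us,
         train_duration_s = train_duration_s,
         polarity = "cathodic-leading biphasic charge-balanced"),
    class = "icms_stim"
  )
}

#' Electrode adjacency on the array grids
#'
#' Two electrodes are adjacent when they sit on the same array at Chebyshev
#' distance 1 (8-neighbourhood, diagonals included). The relation is
#' symmetric and irreflexive; electrodes on different arrays are never
#' adjacent.
#'
#' @param profiles Electrode tibble with `electrode_id`, `array`, `row`,
#'   `col`.
#' @return Logical matrix with electrode ids as dimnames.
#' @export
electrode_adjacency <- function(profiles) {
  stopifnot(all(c("electrode_id", "array", "row", "col") %in%
                  names(profiles)))
  n <- nrow(profiles)
  same_array <- outer(profiles$array, profiles$array, `==`)
  dr <- abs(outer(profiles$row, profiles$row, `-`))
  dc <- abs(outer(profiles$col, profiles$col, `-`))
  adj <- same_array & pmax(dr, dc) == 1
  diag(adj) <- FALSE
  dimnames(adj) <- list(profiles$electrode_id, profiles$electrode_id)
  adj
}

# TRUE when consecutive stimulation on (prev, next) is forbidden: same
# electrode, or adjacent on the grid.
forbidden_succession <- function(adj, prev_id, next_id) {
  if (is.na(prev_id)) return(FALSE)
  prev_id == next_id ||
    isTRUE(adj[as.character(prev_id), as.character(next_id)])
}

#' Build one Experiment-1 amplitude-mapping block
#'
#' A block stimulates each electrode of a subset at each amplitude
#' `reps_per_param` times, in a pseudorandom order constrained so that no
#' two consecutive stimulation trials use the same or adjacent electrodes.
#' Catch trials (identical cues, no stimulation) numbering
#' `round(catch_fraction * n_stimulation)` are interleaved uniformly at
#' random; they deliver no current and are exempt from the adjacency
#' constraint.
#'
#' The order is found by randomized sequential construction: the next trial
#' is drawn from the remaining multiset, restricted to electrodes neither
#' identical nor adjacent to the previous stimulation electrode and weighted
#' by remaining count; dead ends trigger a restart (bounded).
#'
#' @param profiles Electrode tibble (for grid coordinates).
#' @param electrode_ids Electrode subset for the block.
#' @param amplitudes Amplitude levels (microamps).
#' @param reps_per_param Replicates per (electrode, amplitude) pair.
#' @param catch_fraction Catch trials as a fraction of stimulation trials.
#' @param frequency_hz Fixed pulse frequency.
#' @param session_day,block Bookkeeping labels stamped on every trial.
#' @param seed Optional stream seed; `NULL` uses the current RNG.
#' @param max_restarts Bound on sequencing restarts before a scheduling
#'   error is raised.
#' @return Trial tibble: `experiment`, `session_day`, `block`,
#'   `order_index`, `electrode_id`, `amplitude_uA`, `frequency_hz`,
#'   `pulse_width_us`, `interphase_us`, `duration_s`, `is_catch`.
#' @export
#' @examples
#' pop <- make_electrode_population(simulation_config(seed = 1))
#' blk <- build_exp1_block(pop, electrode_ids = c(1, 10, 30, 60), seed = 2)
#' nrow(blk) # 4 electrodes x 8 amplitudes x 3 reps + 10 catch
build_exp1_block <- function(profiles, electrode_ids,
                             amplitudes = exp1_amplitudes(),
                             reps_per_param = 3, catch_fraction = 0.10,
                             frequency_hz = 150, session_day = 1L,
                             block = 1L, seed = NULL,
                             max_restarts = 10000L) {
  if (length(electrode_ids) == 0) {
    stop("electrode subset must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(electrode_ids)) {
    stop("duplicated electrode ids in subset", call. = FALSE)
  }
  missing_ids <- setdiff(electrode_ids, profiles$electrode_id)
  if (length(missing_ids)) {
    stop("unknown electrode id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  charge_per_phase(amplitudes) # safety gate on the whole level set
  sub <- profiles[match(electrode_ids, profiles$electrode_id), ]
  adj <- electrode_adjacency(sub)

  items <- expand.grid(electrode_id = electrode_ids,
                       amplitude_uA = amplitudes)
  n_stim <- nrow(items) * reps_per_param
  n_catch <- round(catch_fraction * n_stim)

  with_stream(seed, {
    order <- sequence_with_constraint(items, reps_per_param, adj,
                                      max_restarts)
    stim <- tibble::tibble(
      electrode_id = items$electrode_id[order],
      amplitude_uA = items$amplitude_uA[order],
      is_catch = FALSE
    )
    out <- stim
    if (n_catch > 0) {
      pos <- sample.int(n_stim + n_catch, n_catch)
      is_catch_slot <- logical(n_stim + n_catch)
      is_catch_slot[pos] <- TRUE
      out <- tibble::tibble(electrode_id = NA_integer_,
                            amplitude_uA = NA_real_,
                            is_catch = is_catch_slot)
      out$electrode_id[!is_catch_slot] <- stim$electrode_id
      out$amplitude_uA[!is_catch_slot] <- stim$amplitude_uA
    }
    tibble::tibble(
      experiment = "exp1",
      session_day = as.integer(session_day),
      block = as.integer(block),
      order_index = seq_len(nrow(out)),
      electrode_id = out$electrode_id,
      amplitude_uA = out$amplitude_uA,
      frequency_hz = ifelse(out$is_catch, NA_real_, frequency_hz),
      pulse_width_us = ifelse(out$is_catch, NA_real_, 200),
      interphase_us = ifelse(out$is_catch, NA_real_, 53),
      duration_s = ifelse(out$is_catch, NA_real_, 1.0),
      is_catch = out$is_catch
    )
  })
}

# Randomized sequential ordering of the (electrode, amplitude) multiset so
# that consecutive items never share the same or an adjacent electrode.
# At each step the next electrode is drawn uniformly among the feasible
# electrodes with the largest remaining load (keeping loads balanced so no
# pocket of mutually adjacent electrodes is left stranded at the end), and
# the amplitude uniformly among that electrode's remaining items. Dead ends
# trigger a bounded restart. Returns item row indices.
sequence_with_constraint <- function(items, reps, adj, max_restarts) {
  n_items <- nrow(items)
  elec <- unique(items$electrode_id)
  e_of_item <- match(items$electrode_id, elec)
  adj_e <- adj[as.character(elec), as.character(elec), drop = FALSE]
  for (attempt in seq_len(max_restarts)) {
    remaining <- rep(reps, n_items)
    load <- tapply(remaining, e_of_item, sum)
    order <- integer(n_items * reps)
    prev <- NA_integer_
    ok <- TRUE
    for (k in seq_along(order)) {
      feas_e <- which(load > 0)
      if (!is.na(prev)) {
        feas_e <- feas_e[feas_e != prev & !adj_e[prev, feas_e]]
      }
      if (!length(feas_e)) { ok <- FALSE; break }
      top <- feas_e[load[feas_e] == max(load[feas_e])]
      e <- if (length(top) == 1L) top else sample(top, 1L)
      cand <- which(e_of_item == e & remaining > 0)
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      order[k] <- pick
      remaining[pick] <- remaining[pick] - 1L
      load[e] <- load[e] - 1L
      prev <- e
    }
    if (ok) return(order)
    # Dead end, usually with one or two stranded items whose electrode is
    # adjacent to the tail of the sequence: try to splice each leftover
    # into any position whose neighbours allow it before restarting.
    seq_so_far <- order[seq_len(k - 1L)]
    leftovers <- rep(seq_len(n_items), remaining)
    repaired <- TRUE
    for (item in leftovers[sample.int(length(leftovers))]) {
      e <- e_of_item[item]
      es <- e_of_item[seq_so_far]
      left_ok <- c(TRUE, es != e & !adj_e[e, es]) # predecessor of slot i
      right_ok <- c(es != e & !adj_e[e, es], TRUE) # successor of slot i
      slots <- which(left_ok & right_ok)
      if (!length(slots)) { repaired <- FALSE; break }
      at <- if (length(slots) == 1L) slots else sample(slots, 1L)
      seq_so_far <- append(seq_so_far, item, after = at - 1L)
    }
    if (repaired) return(seq_so_far)
  }
  stop("could not order block within ", max_restarts,
       " restarts: adjacency constraint unsatisfiable for this subset",
       call. = FALSE)
}

#' Build a full Experiment-1 schedule
#'
#' Partitions the stimulable electrodes into pseudorandom subsets of
#' `subset_size` and emits one constrained block per subset, each on its own
#' session day, so that every electrode is evaluated at every amplitude
#' `reps_per_param` times over the schedule.
#'
#' A random partition occasionally hands a block a subset dominated by one
#' clique of mutually adjacent electrodes, for which no valid ordering
#' exists (or none is found within the restart budget); the builder then
#' re-draws the whole partition, up to `partition_retries` times.
#'
#' @inheritParams build_exp1_block
#' @param subset_size Electrodes per block.
#' @param partition_retries Bound on partition re-draws.
#' @return Trial tibble spanning all blocks.
#' @export
build_exp1_schedule <- function(profiles, amplitudes = exp1_amplitudes(),
                                subset_size = 8, reps_per_param = 3,
                                catch_fraction = 0.10, frequency_hz = 150,
                                seed = NULL, max_restarts = 500L,
                                partition_retries = 50L) {
  ids <- profiles$electrode_id
  with_stream(seed, {
    for (try in seq_len(partition_retries)) {
      shuffled <- sample(ids)
      groups <- split(shuffled, ceiling(seq_along(shuffled) / subset_size))
      blocks <- tryCatch(
        lapply(seq_along(groups), function(b) {
          build_exp1_block(profiles, groups[[b]], amplitudes = amplitudes,
                           reps_per_param = reps_per_param,
                           catch_fraction = catch_fraction,
                           frequency_hz = frequency_hz,
                           session_day = b, block = b, seed = NULL,
                           max_restarts = max_restarts)
        }),
        error = function(e) NULL
      )
      if (!is.null(blocks)) return(dplyr::bind_rows(blocks))
    }
    stop("could not partition electrodes into schedulable blocks after ",
         partition_retries, " attempts", call. = FALSE)
  })
}

#' Build the Experiment-2 multi-day schedule
#'
#' Crosses a subset of electrodes with amplitude and frequency levels. Each
#' day, every (electrode, amplitude, frequency) triple is stimulated
#' `reps_per_day` times in a pseudorandom order; over `days` days every
#' triple accrues `days * reps_per_day` replicates (six under the
#' defaults).
#'
#' @param electrode_ids Electrode subset (default-sized to five).
#' @param amplitudes,frequencies Stimulation levels.
#' @param days Number of consecutive session days.
#' @param reps_per_day Replicates of each triple per day.
#' @param seed Optional stream seed.
#' @return Trial tibble (`experiment = "exp2"`), 5 x 5 x 6 x 2 = 300 rows
#'   per day under the defaults.
#' @export
build_exp2_schedule <- function(electrode_ids,
                                amplitudes = exp2_amplitudes(),
                                frequencies = exp2_frequencies(),
                                days = 3, reps_per_day = 2, seed = NULL) {
  if (anyDuplicated(electrode_ids)) {
    stop("duplicated electrode ids", call. = FALSE)
  }
  charge_per_phase(amplitudes)
  grid <- expand.grid(electrode_id = electrode_ids,
                      amplitude_uA = amplitudes,
                      frequency_hz = frequencies)
  with_stream(seed, {
    day_tables <- lapply(seq_len(days), function(d) {
      idx <- rep(seq_len(nrow(grid)), reps_per_day)
      idx <- sample(idx)
      tibble::tibble(
        experiment = "exp2",
        session_day = as.integer(d),
        block = 1L,
        order_index = seq_along(idx),
        electrode_id = grid$electrode_id[idx],
        amplitude_uA = grid$amplitude_uA[idx],
        frequency_hz = grid$frequency_hz[idx],
        pulse_width_us = 200,
        interphase_us = 53,
        duration_s = 1.0,
        is_catch = FALSE
      )
    })
    dplyr::bind_rows(day_tables)
  })
}

#' Count adjacency violations in a schedule
#'
#' Independent linear scan over the stimulation (non-catch) trials of each
#' block, counting consecutive pairs that use the same or adjacent
#' electrodes. Used as the post-hoc checker for schedule validity.
#'
#' @param trials Trial tibble.
#' @param profiles Electrode tibble (for grid coordinates).
#' @return Integer count of violating consecutive pairs.
#' @export
count_adjacency_violations <- function(trials, profiles) {
  adj <- electrode_adjacency(profiles)
  stim <- trials[!trials$is_catch, ]
  total <- 0L
  for (key in split(seq_len(nrow(stim)),
                    interaction(stim$session_day, stim$block, drop = TRUE))) {
    e <- stim$electrode_id[key[order(stim$order_index[key])]]
    if (length(e) < 2) next
    a <- as.character(e[-length(e)])
    b <- as.character(e[-1])
    total <- total + sum(a == b | adj[cbind(a, b)])
  }
  total
}
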