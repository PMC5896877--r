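# Deterministic session table whose counts embody the headline summary
# structure of the mapping study: 96 tested electrodes of which 46
# responsive (18 cutaneous-only, 6 proprioceptive-only, 22 mixed), 381
# detected responses (79 proprioceptive, 302 cutaneous) among 1229
# non-catch trials, durations 225/122/12 with the remainder unrecorded.
make_printed_structure_fixture <- function() {
  rows <- list()
  add <- function(id, n_cut, n_prop, n_blank) {
    n <- n_cut + n_prop + n_blank
    modality <- c(rep("cutaneous", n_cut), rep("proprioceptive", n_prop),
                  rep("none", n_blank))
    rows[[length(rows) + 1L]] <<- make_session_rows(
      n, electrode_id = id,
      detected = modality != "none",
      modality = modality,
      descriptor = c(rep("squeeze", n_cut), rep("right_movement", n_prop),
                     rep(NA_character_, n_blank)),
      intensity = 5L, region = "upper_arm", plane = "anterior"
    )
  }
  for (id in 1:18) add(id, 10, 0, 0)          # cutaneous-only: 180 cut
  for (id in 19:24) add(id, 0, 5, 0)          # proprioceptive-only: 30 prop
  for (id in 25:46) {                          # mixed: 122 cut + 49 prop
    add(id, 5 + (id <= 36), 2 + (id <= 29), 0)
  }
  blanks <- rep(17L, 50)                       # 848 silent trials
  blanks[1:2] <- 16L
  for (k in seq_along(blanks)) add(46L + k, 0, 0, blanks[k])
  sess <- dplyr::bind_rows(rows)
  sess$trial_index <- seq_len(nrow(sess))
  # duration categories in row order over the detected responses
  det_idx <- which(sess$detected)
  sess$duration_category[det_idx] <-
    rep(c("short", "medium", "long", NA), c(225, 122, 12, 22))
  sess
}
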