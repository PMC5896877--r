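test_that("detection summary counts a hand-built fixture exactly", {
  # 3 electrodes, 10 non-catch trials, 4 detections on 2 electrodes
  sess <- dplyr::bind_rows(
    make_session_rows(4, electrode_id = 1L,
                      detected = c(TRUE, TRUE, FALSE, FALSE)),
    make_session_rows(3, electrode_id = 2L,
                      detected = c(TRUE, TRUE, FALSE), trial_index = 5:7),
    make_session_rows(3, electrode_id = 3L, detected = FALSE,
                      trial_index = 8:10)
  )
  s <- summarize_detection(sess)
  expect_equal(s$n_electrodes_tested, 3)
  expect_equal(s$n_responsive, 2)
  expect_equal(s$pct_responsive, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(s$n_detected, 4)
  expect_equal(s$n_noncatch_trials, 10)
  expect_equal(s$n_catch_trials, 0)
  expect_equal(s$n_catch_false_positives, 0)

  all_catch <- make_session_rows(5, is_catch = TRUE, detected = FALSE)
  all_catch$electrode_id <- NA_integer_
  s2 <- summarize_detection(all_catch)
  expect_equal(s2$n_noncatch_trials, 0)
  expect_true(is.na(s2$pct_responsive))
})

test_that("electrode classes follow the strict-majority rule", {
  fixture <- function(id, n_cut, n_prop) {
    make_session_rows(n_cut + n_prop, electrode_id = id,
                      modality = c(rep("cutaneous", n_cut),
                                   rep("proprioceptive", n_prop)),
                      trial_index = seq_len(n_cut + n_prop))
  }
  sess <- dplyr::bind_rows(
    fixture(1L, 5, 0), fixture(2L, 0, 4), fixture(3L, 3, 3),
    fixture(4L, 2, 5), fixture(5L, 6, 1)
  )
  sess$trial_index <- seq_len(nrow(sess))
  cls <- classify_electrodes(sess)
  expect_equal(cls$class,
               c("cutaneous_only", "proprioceptive_only", "mixed",
                 "mixed", "mixed"))
  expect_equal(cls$mixed_subclass,
               c(NA, NA, "equal", "mostly_proprioceptive",
                 "mostly_cutaneous"))
  # partition property: every classified electrode is in exactly one class
  expect_equal(sum(table(cls$class)), nrow(cls))
})

test_that("descriptor table computes modes and percentiles by hand rules", {
  amps <- c(40, 40, 40, 80, 80, 90, 100, 100)
  sess <- make_session_rows(8, descriptor = "squeeze",
                            amplitude_uA = amps, intensity = 7L)
  tab <- descriptor_table(sess)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pct_of_total, 100)
  expect_equal(tab$amplitude_mode, 40)
  # linear interpolation on 8 order statistics
  expect_equal(tab$amplitude_q25, 40)
  expect_equal(tab$amplitude_q75, 92.5)
  expect_equal(tab$intensity_mode, 7)

  # low-prevalence descriptors pool into "other"
  sess2 <- make_session_rows(
    20,
    descriptor = c(rep("squeeze", 14), rep("tap", 5), "goosebumps"),
    amplitude_uA = 60, intensity = 3L
  )
  tab2 <- descriptor_table(sess2, coverage = 0.9)
  expect_setequal(tab2$descriptor, c("squeeze", "tap", "other"))
  expect_equal(tab2$n[tab2$descriptor == "other"], 1)
  expect_lte(sum(tab2$pct_of_total), 100 + 1e-9)
})

test_that("modality-parameter test separates and errors as specified", {
  sep <- make_session_rows(
    40, modality = c(rep("cutaneous", 20), rep("proprioceptive", 20)),
    amplitude_uA = c(rep(20, 20), rep(100, 20))
  )
  res <- modality_parameter_tests(sep, "amplitude")
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$df, 1L)

  only_cut <- make_session_rows(5, modality = "cutaneous")
  expect_error(modality_parameter_tests(only_cut, "amplitude"),
               "both modalities")
})

test_that("impedance tests detect a constructed shift and flag no-variance", {
  # responsive electrodes shifted +50 kOhm, 48 + 48 electrodes
  resp_rows <- make_session_rows(48, electrode_id = 1:48,
                                 impedance_kohm = 90, detected = TRUE)
  non_rows <- make_session_rows(48, electrode_id = 49:96,
                                impedance_kohm = 40, detected = FALSE,
                                trial_index = 49:96)
  sess <- dplyr::bind_rows(resp_rows, non_rows)
  sess$modality <- ifelse(sess$detected,
                          rep(c("cutaneous", "proprioceptive"), 48),
                          "none")
  res <- impedance_tests(sess)
  expect_lt(res$ks_responsive$p_value, 0.01)
  expect_equal(res$ks_responsive$statistic, 1)
  # identical impedances within modality groups: KW degenerates to p = 1
  expect_equal(res$kw_modality$p_value, 1)
  expect_equal(res$pearson_response_rate$note, NULL)

  flat <- sess
  flat$impedance_kohm <- 40
  res_flat <- impedance_tests(flat)
  expect_equal(res_flat$ks_responsive$statistic, 0)
  expect_identical(res_flat$pearson_response_rate$note, "no-variance")

  miss <- sess
  miss$impedance_kohm[miss$electrode_id == 7] <- NA
  expect_error(impedance_tests(miss), "missing impedance.*7")
})

test_that("impedance carries no signal under the default generator", {
  pvals <- vapply(c(101, 202), function(s) {
    run <- simulate_default_exp1(s)
    impedance_tests(run$sessions)$ks_responsive$p_value
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("intensity normalization maps sessions onto [0, 1]", {
  sess <- make_session_rows(10, intensity = 1:10,
                            amplitude_uA = seq(20, 100, length.out = 10))
  res <- intensity_analysis(sess)
  expect_equal(res$pearson$statistic, 1) # intensity exactly linear in A
  norm_vals <- sort(unique(res$sd_by_amplitude$amplitude_uA))
  expect_equal(length(norm_vals), 10)

  # explicit check of the min-max map on a two-session fixture
  sess2 <- dplyr::bind_rows(
    make_session_rows(10, session_day = 1, intensity = 1:10,
                      amplitude_uA = rep(c(20, 60), 5)),
    make_session_rows(10, session_day = 2, intensity = rep(c(2L, 6L), 5),
                      amplitude_uA = rep(c(20, 60), 5))
  )
  det <- sess2[sess2$detected, ]
  res2 <- intensity_analysis(sess2)
  expect_equal(nrow(res2$sd_by_amplitude), 2)
  # a constant-intensity session is flagged and excluded
  sess3 <- dplyr::bind_rows(
    make_session_rows(10, session_day = 1, intensity = 1:10,
                      amplitude_uA = rep(c(20, 60), 5)),
    make_session_rows(6, session_day = 2, intensity = 5L,
                      amplitude_uA = 40)
  )
  res3 <- intensity_analysis(sess3)
  expect_equal(res3$degenerate_sessions, 2L)

  # literal variant: divide the min-subtracted rating by the session max
  res_lit <- intensity_analysis(sess, normalization = "literal")
  expect_s3_class(res_lit$pearson, "icms_test")
})

test_that("duration analysis counts categories and detects a plant", {
  sess <- make_session_rows(
    60,
    duration_category = c(rep("short", 30), rep("medium", 15),
                          rep("long", 15)),
    amplitude_uA = c(rep(c(20, 40, 60), 15), rep(100, 15))
  )
  res <- duration_analysis(sess)
  expect_equal(unname(res$counts), c(30, 15, 15))
  expect_equal(res$n_missing, 0)
  expect_lt(res$kw_amplitude$p_value, 0.05) # long only at 100 uA
  expect_null(res$kw_frequency) # constant frequency design

  all_na <- make_session_rows(7, duration_category = NA_character_)
  res2 <- duration_analysis(all_na)
  expect_equal(unname(res2$counts), c(0, 0, 0))
  expect_equal(res2$n_missing, 7)
  expect_null(res2$kw_amplitude)
})

test_that("receptive-field consistency follows the region/plane rule", {
  sess <- dplyr::bind_rows(
    make_session_rows(4, electrode_id = 1L, region = "upper_arm",
                      plane = "anterior"),
    make_session_rows(4, electrode_id = 2L, region = "upper_arm",
                      plane = c("anterior", "posterior", "anterior",
                                "posterior"), trial_index = 5:8),
    make_session_rows(4, electrode_id = 3L,
                      region = c("upper_arm", "forearm", "hand",
                                 "forearm"),
                      plane = c("anterior", "posterior", "posterior",
                                "posterior"), trial_index = 9:12)
  )
  rf <- receptive_field_consistency(sess)
  e <- rf$electrodes
  expect_true(e$consistent_region[e$electrode_id == 1] &&
                e$consistent_plane[e$electrode_id == 1])
  expect_true(e$consistent_region[e$electrode_id == 2])
  expect_false(e$consistent_plane[e$electrode_id == 2])
  expect_false(e$consistent_region[e$electrode_id == 3])
  expect_false(e$consistent_plane[e$electrode_id == 3])
  expect_equal(rf$n_consistent, 2)
  expect_equal(rf$arrays$modal_field, "upper_arm:anterior")
})

test_that("array-level receptive-field shares converge to the weights", {
  run <- simulate_default_exp1(55)
  rf <- receptive_field_consistency(run$sessions)
  med <- rf$arrays[rf$arrays$array == "medial", ]
  lat <- rf$arrays[rf$arrays$array == "lateral", ]
  # modal cells mirror the configured across-array somatotopy; shares are
  # noisy at one run's n, so allow a wide band around 46% / 51%
  expect_equal(med$modal_field, "upper_arm:anterior")
  expect_equal(lat$modal_field, "forearm:posterior")
  expect_gt(med$modal_share, 0.30)
  expect_gt(lat$modal_share, 0.30)
})

test_that("pipeline count conservation holds on simulated data", {
  run <- simulate_default_exp1(21)
  sess <- run$sessions
  s <- summarize_detection(sess)
  cls <- classify_electrodes(sess)
  dur <- duration_analysis(sess)
  expect_equal(s$n_detected,
               sum(cls$n_cutaneous) + sum(cls$n_proprioceptive))
  expect_equal(s$n_detected, sum(dur$counts) + dur$n_missing)
  expect_equal(nrow(cls), s$n_responsive)
  expect_equal(s$n_catch_false_positives, 0)
})
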