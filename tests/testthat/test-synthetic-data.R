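test_that("electrode population has the implant geometry", {
  cfg <- simulation_config(seed = 11)
  pop <- make_electrode_population(cfg)
  expect_equal(nrow(pop), 96)
  expect_equal(as.vector(table(pop$array)), c(48L, 48L))
  expect_true(all(pop$row %in% 0:6) && all(pop$col %in% 0:6))
  expect_true(all(pop$impedance_kohm > 0))
  expect_true(all(pop$p_detect_base >= 0 & pop$p_detect_base <= 1))
  # grid positions unique within an array
  expect_false(any(duplicated(pop[, c("array", "row", "col")])))
  # per-electrode region weights are probability vectors
  expect_true(all(vapply(pop$region_weights,
                         function(w) abs(sum(w) - 1) < 1e-9, logical(1))))
})

test_that("population generation is deterministic and honours the fraction", {
  cfg <- simulation_config(seed = 7)
  expect_identical(make_electrode_population(cfg),
                   make_electrode_population(cfg))
  none <- make_electrode_population(simulation_config(seed = 7,
                                                      responsive_fraction = 0))
  expect_false(any(none$responsive))
  all_resp <- make_electrode_population(simulation_config(
    seed = 7, responsive_fraction = 1))
  expect_true(all(all_resp$responsive))
  expect_error(simulation_config(responsive_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(grid_dim = 3, connected_per_array = 48),
               "grid")
  expect_error(simulation_config(duration_weights = c(0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("catch trials and unresponsive electrodes never yield reports", {
  cfg <- simulation_config(seed = 2)
  pop <- make_electrode_population(cfg)
  set.seed(1)
  for (i in 1:50) {
    r <- simulate_response(pop[sample.int(96, 1), ], stim_params(100),
                           is_catch = TRUE, config = cfg)
    expect_false(r$detected)
    expect_equal(r$modality, "none")
    expect_true(is.na(r$intensity) && is.na(r$duration_category) &&
                  is.na(r$region))
  }
  dead <- pop[1, ]
  dead$responsive <- FALSE
  set.seed(2)
  for (i in 1:20) {
    expect_false(simulate_response(dead, stim_params(100),
                                   config = cfg)$detected)
  }
})

test_that("simulated modality frequencies converge to the logistic model", {
  # profile with certain detection and known modality coefficients
  cfg <- simulation_config(seed = 5)
  prof <- make_electrode_population(cfg)[1, ]
  prof$responsive <- TRUE
  prof$p_detect_base <- 1
  prof$detect_amp_slope <- 0
  prof$modality_beta0 <- -3.5
  prof$modality_beta1 <- 0.03
  n <- 10000
  for (A in c(20, 100)) {
    sched <- tibble::tibble(
      experiment = "exp1", session_day = 1L, block = 1L,
      order_index = seq_len(n), electrode_id = prof$electrode_id,
      amplitude_uA = A, frequency_hz = 150, pulse_width_us = 200,
      interphase_us = 53, duration_s = 1, is_catch = FALSE
    )
    sess <- simulate_experiment(sched, prof, cfg, seed = 100 + A)
    p_true <- stats::plogis(-3.5 + 0.03 * A) # 0.0522 at 20, 0.3775 at 100
    p_hat <- mean(sess$modality == "proprioceptive")
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 4 * se)
    expect_true(all(sess$detected))
    # reports carry valid fields
    expect_true(all(sess$intensity %in% 1:10))
    expect_true(all(sess$descriptor %in% names(descriptor_modality_map())))
    map <- descriptor_modality_map()
    expect_true(all(map[sess$descriptor] %in% c(sess$modality, "any") |
                      map[sess$descriptor] == sess$modality))
  }
})

test_that("duration frequencies match the configured weights", {
  cfg <- simulation_config(seed = 6, duration_missing_rate = 0)
  prof <- make_electrode_population(cfg)[1, ]
  prof$responsive <- TRUE
  prof$p_detect_base <- 1
  prof$detect_amp_slope <- 0
  n <- 10000
  sched <- tibble::tibble(
    experiment = "exp1", session_day = 1L, block = 1L,
    order_index = seq_len(n), electrode_id = prof$electrode_id,
    amplitude_uA = 60, frequency_hz = 150, pulse_width_us = 200,
    interphase_us = 53, duration_s = 1, is_catch = FALSE
  )
  sess <- simulate_experiment(sched, prof, cfg, seed = 61)
  counts <- table(factor(sess$duration_category,
                         c("short", "medium", "long")))
  gof <- stats::chisq.test(counts, p = cfg$duration_weights)
  expect_gt(gof$p.value, 0.01)
})

test_that("an experiment reproduces itself bit-for-bit under one seed", {
  run1 <- simulate_default_exp1(31)
  cfg <- run1$config
  sess2 <- simulate_experiment(run1$schedule, run1$profiles, cfg)
  expect_identical(run1$sessions, sess2)
})

test_that("empty and all-catch schedules follow their contracts", {
  cfg <- simulation_config(seed = 8)
  pop <- make_electrode_population(cfg)
  empty <- simulate_experiment(pop[0, 0], pop, cfg)
  expect_equal(nrow(empty), 0)
  expect_named(empty, session_columns())

  catch_sched <- tibble::tibble(
    experiment = "exp1", session_day = 1L, block = 1L,
    order_index = 1:100, electrode_id = NA_integer_,
    amplitude_uA = NA_real_, frequency_hz = NA_real_,
    pulse_width_us = NA_real_, interphase_us = NA_real_,
    duration_s = NA_real_, is_catch = TRUE
  )
  sess <- simulate_experiment(catch_sched, pop, cfg)
  expect_equal(sum(sess$detected), 0)

  bad <- catch_sched
  bad$is_catch <- FALSE
  bad$electrode_id <- 9999L
  expect_error(simulate_experiment(bad, pop, cfg), "unknown electrode")
})

test_that("detected counts sit within binomial error of the model", {
  run <- simulate_default_exp1(77)
  sched <- run$schedule
  pop <- run$profiles
  pi <- match(sched$electrode_id, pop$electrode_id)
  p <- ifelse(sched$is_catch | !(pop$responsive[pi] %in% TRUE), 0,
              pmin(pmax(pop$p_detect_base[pi] +
                          pop$detect_amp_slope[pi] * sched$amplitude_uA,
                        0), 1))
  expected <- sum(p)
  sd3 <- 3 * sqrt(sum(p * (1 - p)))
  expect_lt(abs(sum(run$sessions$detected) - expected), sd3)
})

test_that("the modality amplitude effect is recoverable by ML at study n", {
  # replicates sized to the study's detected-response count
  cfg <- simulation_config(seed = 1)
  prof <- make_electrode_population(cfg)[5, ]
  prof$responsive <- TRUE
  prof$p_detect_base <- 1
  prof$detect_amp_slope <- 0
  prof$modality_beta0 <- -3.5
  prof$modality_beta1 <- 0.03
  n <- 384 # 8 amplitudes x 48
  sched <- tibble::tibble(
    experiment = "exp1", session_day = 1L, block = 1L,
    order_index = seq_len(n), electrode_id = prof$electrode_id,
    amplitude_uA = rep(exp1_amplitudes(), each = 48),
    frequency_hz = 150, pulse_width_us = 200, interphase_us = 53,
    duration_s = 1, is_catch = FALSE
  )
  correct_sign <- vapply(1:200, function(i) {
    sess <- simulate_experiment(sched, prof, cfg, seed = 5000 + i)
    fit <- suppressWarnings(stats::glm(
      (modality == "proprioceptive") ~ amplitude_uA,
      data = sess, family = stats::binomial()))
    unname(stats::coef(fit)[2]) > 0
  }, logical(1))
  expect_gte(mean(correct_sign), 0.95)
})
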