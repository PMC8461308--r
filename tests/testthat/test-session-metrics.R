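test_that("session segmentation follows the windowed pulse amplitude", {
  w <- data.frame(window_index = 1:7, rms_x = 1, rms_y = 1, rms_z = 1,
                  i_t = c(0, 0, 1, 2, 2, 0, 0), section = "x")
  b <- segment_session(w)
  expect_identical(b$before, 1:2)
  expect_identical(b$during, 3:5)
  expect_identical(b$after, 6:7)
  expect_false(b$no_stimulation)

  w$i_t <- 0
  b0 <- segment_session(w)
  expect_identical(b0$before, 1:7)
  expect_length(b0$during, 0)
  expect_true(b0$no_stimulation)
})

test_that("simulated auto-ramp during length matches the schedule", {
  prof <- patient_profile(response_threshold = 4.2)
  cfg <- session_config(before_s = 40, after_s = 30)
  sched <- auto_ramp_schedule(prof, cfg)
  s <- simulate_session(prof, cfg)
  b <- segment_session(rms_windows(s))
  expect_lte(abs(length(b$during) - length(sched)), 1)
})

test_that("baseline reference is the per-axis median and resists outliers", {
  w <- data.frame(window_index = 1:40, rms_x = 5, rms_y = 7, rms_z = 2,
                  i_t = 0, section = "before")
  ref <- baseline_rms(w)
  expect_equal(as.numeric(ref), c(5, 7, 2))
  expect_equal(attr(ref, "magnitude"), sqrt(25 + 49 + 4))

  w_out <- w
  w_out$rms_x[c(3, 17, 31)] <- 500   # movement artefacts
  expect_equal(baseline_rms(w_out)[["x"]], 5)          # median unmoved
  expect_gt(mean(w_out$rms_x), 5 + 1)                   # mean oracle moves
  expect_error(baseline_rms(w[1:10, ]), "at least 30")
})

test_that("reduction state requires persistence and uses hysteresis", {
  base <- c(x = 3, y = 4, z = 0)
  attr(base, "magnitude") <- 5
  mk <- function(mag) data.frame(window_index = seq_along(mag),
                                 rms_x = mag, rms_y = 0, rms_z = 0,
                                 i_t = 0, section = "during")
  crit <- reduction_criteria(persistence_k = 3)
  # all at baseline -> never reduced
  expect_false(any(detect_reduction_state(mk(rep(5, 10)), base, crit)))
  # 0.4 x baseline throughout -> reduced from the start of the run
  expect_true(all(detect_reduction_state(mk(rep(2, 10)), base, crit)))
  # a 2-window dip is rejected; a 3-window dip flips the state
  st <- detect_reduction_state(mk(c(5, 5, 2, 2, 5, 2, 2, 2, 5, 5, 5)),
                               base, crit)
  expect_identical(st, c(rep(FALSE, 5), rep(TRUE, 3), rep(FALSE, 3)))
})

test_that("detected suppression interval tracks the generator truth", {
  prof <- patient_profile(tremor_freq = 5, baseline_rms = 10,
                          response_threshold = 3, suppression_floor = 0.2,
                          reset_hold = 40, reemergence_ramp = 10,
                          noise_sd = 0.4)
  cfg <- session_config(before_s = 60, after_s = 80)
  s <- simulate_session(prof, cfg, seed = 17)
  w <- rms_windows(s)
  b <- segment_session(w)
  crit <- reduction_criteria()
  base <- baseline_rms(w[b$before, ])
  red <- detect_reduction_state(w, base, crit)
  truth <- attr(s, "truth")
  onset_est <- (which(red)[1] - 1)
  offset_est <- max(which(red))
  t_back <- truth$t_off + prof$reset_hold +
    prof$reemergence_ramp * (0.5 - 0.2) / 0.8
  expect_lte(abs(onset_est - truth$t_eff), crit$persistence_k + 1)
  expect_lte(abs(offset_est - t_back), crit$persistence_k + 1)
})

test_that("reset summary decomposes and matches the generator closed form", {
  prof <- patient_profile(tremor_freq = 5, baseline_rms = 12,
                          response_threshold = 5, suppression_floor = 0.25,
                          reset_hold = 120, reemergence_ramp = 20,
                          noise_sd = 0)
  cfg <- session_config(before_s = 60, after_s = 300)
  s <- simulate_session(prof, cfg)
  w <- rms_windows(s)
  summ <- compute_reset_summary(w, criteria = reduction_criteria())
  truth <- reset_time_truth(s)
  expect_equal(summ$reset_time_D,
               summ$reduction_during_B + summ$continuing_after_C)
  expect_lte(abs(summ$reset_time_D - truth$D), 2)
  expect_lte(summ$reduction_during_B, summ$stim_duration_A)
  expect_false(summ$censored)
  expect_gte(summ$max_amplitude, summ$avg_amplitude)
})

test_that("reset summary under noise stays within persistence tolerance", {
  prof <- patient_profile(tremor_freq = 4.6, baseline_rms = c(14, 9, 6),
                          response_threshold = 6, suppression_floor = 0.3,
                          reset_hold = 90, reemergence_ramp = 16,
                          noise_sd = 0.8, phase = c(0.5, 1.5, 2.5))
  cfg <- session_config(before_s = 60, after_s = 240)
  s <- simulate_session(prof, cfg, seed = 5)
  summ <- compute_reset_summary(rms_windows(s))
  truth <- reset_time_truth(s)
  k <- reduction_criteria()$persistence_k
  expect_lte(abs(summ$reset_time_D - truth$D), k + 2)
})

test_that("increasing reset_hold strictly increases the estimated C", {
  est_C <- vapply(c(30, 60, 90), function(h) {
    prof <- patient_profile(tremor_freq = 5, response_threshold = 3,
                            suppression_floor = 0.2, reset_hold = h,
                            reemergence_ramp = 10, noise_sd = 0)
    s <- simulate_session(prof, session_config(before_s = 40, after_s = 150))
    compute_reset_summary(rms_windows(s))$continuing_after_C
  }, numeric(1))
  expect_true(all(diff(est_C) > 0))
})

test_that("sessions with no reduction or no after section are handled", {
  # stimulation never reaches the threshold: B = C = D = 0
  prof <- patient_profile(response_threshold = 10, noise_sd = 0)
  s <- simulate_session(prof, session_config(before_s = 40, after_s = 60),
                        protocol = rep(2, 30))
  summ <- compute_reset_summary(rms_windows(s))
  expect_equal(summ$reduction_during_B, 0)
  expect_equal(summ$continuing_after_C, 0)
  expect_equal(summ$reset_time_D, 0)

  # suppressed at off but session ends immediately: censored, C = 0
  prof2 <- patient_profile(response_threshold = 2, suppression_floor = 0.2,
                           reset_hold = 100, noise_sd = 0)
  s2 <- simulate_session(prof2, session_config(before_s = 40, after_s = 0))
  summ2 <- compute_reset_summary(rms_windows(s2))
  expect_true(summ2$censored)

  w <- rms_windows(s2)
  w$i_t <- 0
  expect_error(compute_reset_summary(w), "during")
})

test_that("reset summary constructor enforces additivity and ordering", {
  rs <- reset_summary(A = 440.7, B = 200.35, C = 129.55,
                      max_amplitude = 9.45, avg_amplitude = 6.25)
  expect_equal(rs$reset_time_D, 329.90)
  expect_error(reset_summary(A = 10, B = 12, C = 0), "B <= A")
  expect_error(reset_summary(A = 10, B = 5, C = 3, max_amplitude = 2,
                             avg_amplitude = 5), "max_amplitude")
})

test_that("stopping rule needs a 2.5x drop on both x and y", {
  crit <- reduction_criteria()
  ref <- list(rms_x = 10, rms_y = 10)
  expect_false(stop_criterion_met(list(rms_x = 5, rms_y = 5), ref, crit))
  expect_true(stop_criterion_met(list(rms_x = 4, rms_y = 4), ref, crit))
  expect_false(stop_criterion_met(list(rms_x = 10 / 3, rms_y = 5), ref, crit))
  # zero current RMS is guarded, not a division error
  expect_true(stop_criterion_met(list(rms_x = 0, rms_y = 0), ref, crit))
})
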