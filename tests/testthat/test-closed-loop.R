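test_that("controller ramps by one step towards the predicted class maximum", {
  model <- constant_model(2)   # target 10 mA
  cfg <- controller_config()
  state <- controller_init()
  state$current_amplitude <- 7
  state$phase <- "ramping"
  state$stim_start_reference <- list(rms_x = 10, rms_y = 10, rms_z = 10)
  w <- list(rms_x = 9, rms_y = 9, rms_z = 9)  # criterion not met
  res <- controller_step(state, w, model, cfg)
  expect_equal(res$command, 8)
  expect_identical(res$state$predicted_class, 2L)
})

test_that("the stopping rule switches stimulation off and latches", {
  model <- constant_model(3)
  cfg <- controller_config()
  state <- controller_init()
  state$current_amplitude <- 9
  state$phase <- "ramping"
  state$stim_start_reference <- list(rms_x = 10, rms_y = 10, rms_z = 10)
  w <- list(rms_x = 2, rms_y = 2, rms_z = 2)  # 5x reduction
  res <- controller_step(state, w, model, cfg)
  expect_equal(res$command, 0)
  expect_identical(res$state$phase, "stopped")
  # stays stopped regardless of later predictions
  res2 <- controller_step(res$state, list(rms_x = 20, rms_y = 20,
                                          rms_z = 20), model, cfg)
  expect_equal(res2$command, 0)
  expect_identical(res2$state$phase, "stopped")
})

test_that("a class-0 prediction keeps the controller idle", {
  res <- controller_step(controller_init(),
                         list(rms_x = 5, rms_y = 5, rms_z = 5),
                         constant_model(0), controller_config())
  expect_equal(res$command, 0)
  expect_identical(res$state$phase, "idle")
  expect_error(controller_step(controller_init(), list(rms_x = 1,
                                                       rms_y = 1,
                                                       rms_z = 1),
                               NULL), "untrained")
})

test_that("oracle-driven closed loop reaches the stop criterion and resets", {
  prof <- patient_profile(tremor_freq = c(5, 4.4, 5.6),
                          baseline_rms = c(12, 15, 8),
                          response_threshold = 7, suppression_floor = 0.3,
                          reset_hold = 60, reemergence_ramp = 20,
                          noise_sd = 0.3, phase = c(0, 1, 2))
  cfg <- session_config(before_s = 60, max_during_s = 300, after_s = 200)
  res <- run_closed_loop(prof, oracle_model(prof), cfg, seed = 3)
  expect_identical(res$trace$phase[nrow(res$trace)], "stopped")
  expect_gt(res$summary$reset_time_D, 0)
  # while stimulating, the amplitude never moves more than 1 mA per step
  active <- res$trace$command[res$trace$phase != "stopped"]
  expect_true(all(abs(diff(c(0, active))) <= 1))
  # ramping never jumps classes: consecutive commanded classes differ by <= 1
  cls <- amplitude_to_class(active)
  expect_true(all(abs(diff(cls)) <= 1))
})

test_that("stop criterion fires iff the suppression floor is deep enough", {
  run_floor <- function(floor_v) {
    prof <- patient_profile(tremor_freq = 5, baseline_rms = 10,
                            response_threshold = 4,
                            suppression_floor = floor_v,
                            reset_hold = 40, noise_sd = 0)
    cfg <- session_config(before_s = 40, max_during_s = 120, after_s = 60)
    res <- run_closed_loop(prof, oracle_model(prof), cfg, seed = 1)
    any(res$trace$phase == "stopped")
  }
  expect_true(run_floor(0.3))    # 1/0.3 > 2.5
  expect_false(run_floor(0.45))  # 1/0.45 < 2.5
})

test_that("an always-off model produces no stimulation and zero reset time", {
  prof <- patient_profile(noise_sd = 0.2)
  cfg <- session_config(before_s = 40, max_during_s = 60, after_s = 30)
  res <- run_closed_loop(prof, constant_model(0), cfg, seed = 2)
  expect_true(all(res$trace$command == 0))
  expect_equal(res$summary$reset_time_D, 0)
})

test_that("closed-loop reset time increases with the patient's reset hold", {
  d <- vapply(c(30, 90), function(h) {
    prof <- patient_profile(tremor_freq = 5, baseline_rms = 10,
                            response_threshold = 4,
                            suppression_floor = 0.25, reset_hold = h,
                            reemergence_ramp = 10, noise_sd = 0)
    cfg <- session_config(before_s = 40, max_during_s = 120, after_s = 200)
    run_closed_loop(prof, oracle_model(prof), cfg,
                    seed = 1)$summary$reset_time_D
  }, numeric(1))
  expect_gt(d[2], d[1])
})

test_that("a trained band-task model can drive the loop free-running", {
  recs <- synthetic_band_cohort(6, 150, seed = 13)
  spec <- model_spec("logistic_regression", seed = 2)
  model <- fit_stim_model(spec, recs)
  prof <- patient_profile(tremor_freq = 5, baseline_rms = c(12, 9, 7),
                          response_threshold = 4, suppression_floor = 0.3,
                          reset_hold = 40, noise_sd = 0.3)
  cfg <- session_config(before_s = 40, max_during_s = 120, after_s = 100)
  res <- run_closed_loop(prof, model, cfg, seed = 4)
  expect_s3_class(res$summary, "reset_summary")
  expect_gt(nrow(res$trace), 0)
  expect_true(all(abs(diff(c(0, res$trace$command[
    res$trace$phase != "stopped"]))) <= 1))
  # gyro-only models are rejected for closed-loop control
  model_g <- fit_stim_model(model_spec("logistic_regression",
                                       feature_set = "gyro_only",
                                       seed = 2), recs)
  expect_error(run_closed_loop(prof, model_g, cfg, seed = 4),
               "gyro_plus_prev")
})
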