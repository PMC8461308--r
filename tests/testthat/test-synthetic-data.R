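test_that("patient generation is deterministic and respects invariants", {
  p1 <- generate_patient(seed = 1)
  p2 <- generate_patient(seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_patient(seed = 2)))

  cohort <- generate_cohort(334, seed = 42)
  freqs <- unlist(lapply(cohort, `[[`, "tremor_freq"))  # ~1000 draws
  expect_true(all(freqs > 2 & freqs < 12))
  floors <- vapply(cohort, `[[`, numeric(1), "suppression_floor")
  expect_true(all(floors > 0 & floors < 0.5))
  expect_true(all(vapply(cohort, `[[`, numeric(1), "response_threshold") > 0))
  expect_true(all(vapply(cohort, `[[`, numeric(1), "reset_hold") >= 0))
})

test_that("tremor-frequency draws match the generator's truncated-normal mean", {
  d <- patient_distributions()
  cohort <- generate_cohort(334, seed = 7, dist = d)
  freqs <- unlist(lapply(cohort, `[[`, "tremor_freq"))
  mu <- truncnorm_mean(d$freq_mean, d$freq_sd, d$freq_range[1],
                       d$freq_range[2])
  se <- stats::sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - mu), 3 * se)
})

test_that("invalid distribution bounds are a configuration error", {
  expect_error(patient_distributions(floor_range = c(0.2, 0.7)),
               "floor_range")
  expect_error(patient_distributions(freq_range = c(1, 12)), "freq_range")
  expect_error(patient_distributions(threshold_range = c(5, 3)),
               "threshold_range")
})

test_that("auto-ramp protocol reaches and holds the response threshold", {
  prof <- patient_profile(response_threshold = 5, noise_sd = 0)
  cfg <- session_config(before_s = 40, after_s = 30)
  s <- simulate_session(prof, cfg)
  expect_equal(max(s$pulse_ma), 5)
  hold_samples <- sum(s$pulse_ma == 5)
  # 10 s dwell at the top step plus the 30 s hold
  expect_equal(hold_samples / attr(s, "sample_rate"),
               cfg$ramp_dwell + cfg$hold_s)
  expect_true(all(s$pulse_ma[s$section != "during"] == 0))
})

test_that("noise-free unstimulated tremor has RMS = amplitude/sqrt(2) per axis", {
  # 5 Hz: integer cycles per 1-s window, so the sine RMS identity is exact
  prof <- patient_profile(tremor_freq = 5, baseline_rms = c(8, 12, 4),
                          noise_sd = 0)
  s <- simulate_session(prof, session_config(before_s = 60, after_s = 0),
                        protocol = rep(0.5, 1))
  w <- rms_windows(s)
  before <- w[w$section == "before", ]
  # generator targets baseline_rms as the window RMS (amplitude/sqrt(2))
  expect_equal(before$rms_x, rep(8, nrow(before)), tolerance = 1e-6)
  expect_equal(before$rms_y, rep(12, nrow(before)), tolerance = 1e-6)
  expect_equal(before$rms_z, rep(4, nrow(before)), tolerance = 1e-6)
})

test_that("suppression ratio equals the suppression floor when noise-free", {
  prof <- patient_profile(tremor_freq = 4, baseline_rms = 10,
                          response_threshold = 3, suppression_floor = 0.3,
                          reset_hold = 50, noise_sd = 0)
  s <- simulate_session(prof, session_config(before_s = 60, after_s = 60))
  w <- rms_windows(s)
  before_rms <- stats::median(w$rms_x[w$section == "before"])
  # stimulation held at/above threshold towards the end of during
  during <- w[w$section == "during" & w$i_t >= 3, ]
  held <- during[nrow(during) - 2, ]  # well past the onset smoothing
  expect_equal(held$rms_x / before_rms, 0.3, tolerance = 1e-3)
})

test_that("envelope change-points are recovered by per-cycle peak tracing", {
  prof <- patient_profile(tremor_freq = 5, baseline_rms = 10,
                          response_threshold = 2, suppression_floor = 0.2,
                          reset_hold = 30, reemergence_ramp = 10,
                          noise_sd = 0)
  cfg <- session_config(before_s = 40, after_s = 80)
  s <- simulate_session(prof, cfg)
  fs <- attr(s, "sample_rate")
  period <- round(fs / 5)
  n_cyc <- nrow(s) %/% period
  peaks <- vapply(seq_len(n_cyc), function(k) {
    max(abs(s$gx[((k - 1) * period + 1):(k * period)]))
  }, numeric(1))
  t_cyc <- (seq_len(n_cyc) - 0.5) * period / fs
  amp0 <- sqrt(2) * 10
  low <- peaks < 0.5 * amp0
  truth <- attr(s, "truth")
  # first suppressed cycle within one tremor period of effective onset
  expect_lt(abs(t_cyc[which(low)[1]] - truth$t_eff), 2 * period / fs + 0.3)
  # last suppressed cycle near the end of hold + half the ramp
  t_half <- truth$t_off + prof$reset_hold +
    prof$reemergence_ramp * (0.5 - 0.2) / 0.8
  expect_lt(abs(t_cyc[max(which(low))] - t_half), 2 * period / fs + 0.3)
})

test_that("session simulation rejects invalid protocols", {
  prof <- patient_profile()
  cfg <- session_config(before_s = 10, max_during_s = 20, after_s = 10)
  expect_error(simulate_session(prof, cfg, protocol = rep(1, 30)),
               "longer")
  expect_error(simulate_session(prof, cfg, protocol = c(1, -2)),
               "non-negative")
})

test_that("glove CSV writing and reading round-trips the stream", {
  prof <- generate_patient(seed = 3)
  s <- simulate_session(prof, session_config(before_s = 20, after_s = 20),
                        protocol = rep(c(1, 2), each = 5), seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_glove_csv(s, f)
  s2 <- read_glove_csv(f)
  expect_equal(nrow(s2), nrow(s))
  for (cl in c("time", "gx", "gy", "gz", "pulse_ma")) {
    expect_equal(s2[[cl]], s[[cl]], tolerance = 1e-6)
  }
  expect_identical(s2$section, s$section)
  # featurization is invariant to the round trip
  expect_equal(rms_windows(s2)$rms_x, rms_windows(s)$rms_x,
               tolerance = 1e-6)
})

test_that("malformed glove CSVs fail with a line number", {
  prof <- patient_profile()
  s <- simulate_session(prof, session_config(before_s = 5, after_s = 5),
                        protocol = rep(1, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_glove_csv(s, f)
  lines <- readLines(f)
  shuffled <- c(lines[1], lines[c(4, 3, 2)], lines[-(1:4)])
  writeLines(shuffled, f)
  expect_error(read_glove_csv(f), "line")

  write_glove_csv(s, f)
  lines <- readLines(f)
  lines[3] <- sub("^[0-9.]+", "not_a_number", lines[3])
  writeLines(lines, f)
  expect_error(read_glove_csv(f), "line 3")
})

test_that("a 10-minute session at 50 Hz has 30,000 rows", {
  prof <- patient_profile(response_threshold = 5)
  # 600 s total: 300 before + 100 during + 200 after
  cfg <- session_config(sample_rate = 50, before_s = 300, after_s = 200)
  s <- simulate_session(prof, cfg, protocol = rep(1:5, each = 20))
  expect_identical(nrow(s), 30000L)
})
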