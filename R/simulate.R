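#' Stimulation session configuration
#'
#' Timing and sampling settings for a simulated stimulation session. The
#' defaults reproduce the manual protocol: a 5-min baseline before
#' stimulation, a during-stimulation section in which pulse amplitude is
#' raised by 1 mA approximately every 10 s until suppression, then held
#' ~30 s, and a 10-min post-stimulation observation section.
#'
#' @param sample_rate Sampling rate (Hz); must be at least 25 so the
#'   <= 12 Hz tremor band is below Nyquist.
#' @param before_s Duration (s) of the pre-stimulation baseline section.
#' @param max_during_s Maximum duration (s) of the stimulation section.
#' @param after_s Duration (s) of the post-stimulation section.
#' @param ramp_step Amplitude increment per ramp step (mA).
#' @param ramp_dwell Seconds spent at each amplitude step.
#' @param hold_s Seconds of continued stimulation at the effective
#'   amplitude before switching off.
#' @param onset_smooth_s Seconds over which the tremor envelope slews into
#'   suppression once stimulation becomes effective (avoids an unphysical
#'   discontinuity; immaterial at the 1-s feature scale).
#' @return A `session_config` list.
#' @export
session_config <- function(sample_rate = 50,
                           before_s = 300,
                           max_during_s = 900,
                           after_s = 600,
                           ramp_step = 1,
                           ramp_dwell = 10,
                           hold_s = 30,
                           onset_smooth_s = 0.5) {
  cfg <- list(sample_rate = sample_rate, before_s = before_s,
              max_during_s = max_during_s, after_s = after_s,
              ramp_step = ramp_step, ramp_dwell = ramp_dwell,
              hold_s = hold_s, onset_smooth_s = onset_smooth_s)
  if (sample_rate < 25) {
    stop("sample_rate must be >= 25 Hz (Nyquist for a <= 12 Hz tremor)",
         call. = FALSE)
  }
  if (before_s < 0 || max_during_s <= 0 || after_s < 0) {
    stop("section durations must be non-negative (during > 0)", call. = FALSE)
  }
  if (ramp_step <= 0 || ramp_dwell <= 0) {
    stop("ramp_step and ramp_dwell must be positive", call. = FALSE)
  }
  class(cfg) <- "session_config"
  cfg
}

# --- tremor amplitude envelope state machine -------------------------------
#
# The envelope multiplies the baseline oscillation amplitude: 1 at baseline,
# dropping to the patient's suppression_floor while stimulation is effective
# (pulse amplitude >= response_threshold), held at the floor for reset_hold
# seconds after withdrawal, then returning linearly to 1 over
# reemergence_ramp seconds. The downward transition is slew-limited so the
# full drop takes onset_smooth_s seconds.

envelope_state_init <- function() {
  list(env = 1, last_eff = -Inf, ever_eff = FALSE)
}

# Advance the envelope over a block of samples. Returns the envelope values
# and the updated state, so batch simulation and the closed-loop controller
# share one set of dynamics.
envelope_advance <- function(state, times, amps, profile,
                             onset_smooth_s = 0.5) {
  n <- length(times)
  env <- numeric(n)
  floor_v <- profile$suppression_floor
  hold <- profile$reset_hold
  ramp <- profile$reemergence_ramp
  thr <- profile$response_threshold
  dt <- if (n > 1) times[2] - times[1] else 1
  down_step <- (1 - floor_v) * dt / max(onset_smooth_s, dt)
  e <- state$env
  last_eff <- state$last_eff
  ever_eff <- state$ever_eff
  for (i in seq_len(n)) {
    eff <- amps[i] >= thr
    if (eff) {
      last_eff <- times[i]
      ever_eff <- TRUE
      target <- floor_v
    } else if (!ever_eff) {
      target <- 1
    } else {
      since <- times[i] - last_eff
      if (since <= hold) {
        target <- floor_v
      } else if (ramp > 0 && since < hold + ramp) {
        target <- floor_v + (1 - floor_v) * (since - hold) / ramp
      } else {
        target <- 1
      }
    }
    if (target < e) {
      e <- max(target, e - down_step)
    } else {
      e <- target
    }
    env[i] <- e
  }
  list(env = env,
       state = list(env = e, last_eff = last_eff, ever_eff = ever_eff))
}

# Synthesize gyroscope samples for a block: per-axis sinusoid at the
# patient's frequency, amplitude sqrt(2) * baseline_rms * envelope, plus
# additive Gaussian noise (drawn from the current RNG stream).
synth_block <- function(times, env, profile) {
  ax <- c("x", "y", "z")
  out <- lapply(ax, function(a) {
    amp <- sqrt(2) * profile$baseline_rms[[a]]
    sig <- amp * env * sin(2 * pi * profile$tremor_freq[[a]] * times +
                             profile$phase[[a]])
    if (profile$noise_sd > 0) {
      sig <- sig + stats::rnorm(length(times), 0, profile$noise_sd)
    }
    sig
  })
  names(out) <- c("gx", "gy", "gz")
  out
}

#' Amplitude schedule for the manual ramp protocol
#'
#' Builds the per-second pulse-amplitude schedule of the during-stimulation
#' section for a given patient: amplitude rises by `ramp_step` mA every
#' `ramp_dwell` seconds (1, 2, 3, ... mA) until it reaches the patient's
#' response threshold, is then held for `hold_s` seconds, and is switched
#' off.
#'
#' @param profile A `patient_profile`.
#' @param config A `session_config`.
#' @return Numeric vector: pulse amplitude (mA) for each second of the
#'   during section.
#' @export
auto_ramp_schedule <- function(profile, config = session_config()) {
  top <- ceiling(profile$response_threshold / config$ramp_step) *
    config$ramp_step
  levels <- seq(config$ramp_step, top, by = config$ramp_step)
  sched <- rep(levels, each = config$ramp_dwell)
  sched <- c(sched, rep(top, config$hold_s))
  if (length(sched) > config$max_during_s) {
    sched <- sched[seq_len(config$max_during_s)]
  }
  sched
}

#' Simulate a full stimulation session
#'
#' Generates a raw gyroscope stream for one patient over the three protocol
#' sections (before / during / after stimulation). The tremor is a per-axis
#' sinusoid at the patient's dominant frequency whose amplitude follows the
#' suppression envelope: baseline until the pulse amplitude reaches the
#' patient's response threshold, suppressed to `suppression_floor` while
#' stimulation is effective, held suppressed for `reset_hold` seconds after
#' withdrawal, then returning linearly to baseline over `reemergence_ramp`
#' seconds. Additive Gaussian noise is applied everywhere.
#'
#' @param profile A `patient_profile`.
#' @param config A `session_config`.
#' @param protocol `"auto_ramp"` for the manual stepped protocol
#'   ([auto_ramp_schedule()]), or a numeric vector giving the pulse
#'   amplitude (mA) for each second of the during section.
#' @param seed Optional seed for the noise stream (set before synthesis).
#' @return A `gyro_stream` data frame with columns `time`, `gx`, `gy`,
#'   `gz`, `pulse_ma`, `section`, carrying attributes `sample_rate` and
#'   `truth` (stimulation-effective onset/offset times and the profile,
#'   for closed-form checks).
#' @export
simulate_session <- function(profile, config = session_config(),
                             protocol = "auto_ramp", seed = NULL) {
  validate_patient_profile(profile)
  if (!is.null(seed)) set.seed(seed)
  if (identical(protocol, "auto_ramp")) {
    sched <- auto_ramp_schedule(profile, config)
  } else {
    sched <- as.numeric(protocol)
    if (length(sched) > config$max_during_s) {
      stop("protocol schedule longer than the during section", call. = FALSE)
    }
    if (any(sched < 0)) {
      stop("pulse amplitudes must be non-negative", call. = FALSE)
    }
  }
  fs <- config$sample_rate
  dt <- 1 / fs
  during_s <- length(sched)
  total_s <- config$before_s + during_s + config$after_s
  times <- seq(0, total_s - dt, by = dt)
  n <- length(times)
  sec_of <- function(t) {
    ifelse(t < config$before_s, "before",
           ifelse(t < config$before_s + during_s, "during", "after"))
  }
  section <- sec_of(times)
  amps <- numeric(n)
  idx_during <- section == "during"
  sec_index <- floor(times[idx_during] - config$before_s) + 1
  amps[idx_during] <- sched[sec_index]

  envr <- envelope_advance(envelope_state_init(), times, amps, profile,
                           config$onset_smooth_s)
  sig <- synth_block(times, envr$env, profile)

  eff <- amps >= profile$response_threshold
  t_eff <- if (any(eff)) times[which(eff)[1]] else NA_real_
  t_off <- if (during_s > 0) config$before_s + during_s else NA_real_

  stream <- data.frame(time = times, gx = sig$gx, gy = sig$gy, gz = sig$gz,
                       pulse_ma = amps, section = section,
                       stringsAsFactors = FALSE)
  attr(stream, "sample_rate") <- fs
  attr(stream, "truth") <- list(t_eff = t_eff, t_off = t_off,
                                t_stim_on = config$before_s,
                                profile = profile, config = config)
  class(stream) <- c("gyro_stream", "data.frame")
  validate_gyro_stream(stream)
  stream
}

validate_gyro_stream <- function(stream) {
  need <- c("time", "gx", "gy", "gz", "pulse_ma", "section")
  miss <- setdiff(need, names(stream))
  if (length(miss)) {
    stop("gyro stream missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dtime <- diff(stream$time)
  if (any(dtime <= 0)) {
    stop(sprintf("timestamps not strictly increasing at row %d",
                 which(dtime <= 0)[1] + 1L), call. = FALSE)
  }
  if (any(stream$pulse_ma < 0)) {
    stop("pulse amplitudes must be non-negative", call. = FALSE)
  }
  if (any(stream$pulse_ma[stream$section != "during"] > 0)) {
    stop("pulse amplitude must be zero outside the during section",
         call. = FALSE)
  }
  invisible(stream)
}

#' @export
print.gyro_stream <- function(x, ...) {
  fs <- attr(x, "sample_rate")
  cat(sprintf("Gyroscope stream: %d samples at %g Hz (%.1f s)\n",
              nrow(x), fs, nrow(x) / fs))
  tb <- table(x$section)
  cat("  sections (s):",
      paste(sprintf("%s %.0f", names(tb), tb / fs), collapse = ", "), "\n")
  cat(sprintf("  max pulse amplitude: %g mA\n", max(x$pulse_ma)))
  invisible(x)
}

#' Closed-form tremor reset time of a simulated session
#'
#' Computes the generator-truth reset-time components implied by a
#' simulated session's envelope dynamics and a set of measurement criteria:
#' \describe{
#'   \item{B}{time in suppressed state during stimulation: from the moment
#'     the envelope crosses the 50% reduction level (shortly after the
#'     pulse amplitude first reaches the response threshold) until
#'     stimulation is switched off;}
#'   \item{C}{time from switch-off until the re-emerging envelope crosses
#'     the re-emergence level: `reset_hold + ramp * (thr - floor) / (1 - floor)`
#'     with `thr` the re-emergence fraction of baseline;}
#'   \item{D}{`B + C`.}
#' }
#'
#' @param stream A `gyro_stream` produced by [simulate_session()] (its
#'   `truth` attribute is used), or the truth list itself.
#' @param criteria A [reduction_criteria()] object supplying the reduction
#'   and re-emergence fractions.
#' @return List with components `B`, `C`, `D` (seconds).
#' @export
reset_time_truth <- function(stream, criteria = reduction_criteria()) {
  truth <- if (inherits(stream, "gyro_stream")) attr(stream, "truth") else stream
  p <- truth$profile
  cfg <- truth$config
  f <- p$suppression_floor
  if (is.na(truth$t_eff)) {
    return(list(B = 0, C = 0, D = 0))
  }
  # envelope slews from 1 towards the floor over onset_smooth_s; the 50%
  # level is crossed part-way down the slew
  drop_frac <- (1 - (1 - criteria$gyro_reduction_fraction)) / (1 - f)
  t_cross <- truth$t_eff + drop_frac * cfg$onset_smooth_s
  B <- max(0, truth$t_off - t_cross)
  thr <- criteria$reemergence_fraction
  C <- p$reset_hold + p$reemergence_ramp * (thr - f) / (1 - f)
  list(B = B, C = C, D = B + C)
}
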