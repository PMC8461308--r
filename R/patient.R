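#' Distribution settings for virtual tremor patients
#'
#' Returns the sampling distributions from which [generate_patient()] draws
#' patient-specific tremor parameters. Defaults are calibrated to the
#' summary statistics of a 20-patient clinical EMS-glove cohort: per-axis
#' baseline RMS angular velocity (right-skewed, modelled log-normal with the
#' reported mean/SD per axis), dominant resting-tremor frequency (normal,
#' mean 5.5 Hz, SD 1.7 Hz, truncated to the 2-12 Hz physiological band),
#' and the pulse amplitude at which suppression occurs (normal, mean
#' 9.45 mA, SD 4.29 mA, truncated to the observed 3-17 mA range).
#'
#' @param freq_mean,freq_sd Mean and SD (Hz) of the per-axis tremor
#'   frequency before truncation to `freq_range`.
#' @param freq_range Allowed tremor-frequency interval (Hz).
#' @param rms_mean,rms_sd Named numeric vectors (`x`, `y`, `z`) giving the
#'   target mean and SD of baseline per-axis RMS angular velocity
#'   (gyro units); draws are log-normal with these moments.
#' @param threshold_mean,threshold_sd,threshold_range Truncated-normal
#'   settings (mA) for the patient's suppression threshold.
#' @param floor_range Interval for the suppression floor, the fraction of
#'   baseline tremor amplitude remaining under effective stimulation. The
#'   upper bound must stay below 0.5 so that effective stimulation always
#'   satisfies the >50% reduction criterion.
#' @param hold_mean,hold_sd,hold_range Log-normal (by moments) settings
#'   for `reset_hold`, the seconds of continued suppression after
#'   stimulation withdrawal, truncated to `hold_range`.
#' @param ramp_range Interval (s) for the linear re-emergence ramp duration.
#' @param noise_range Interval for the additive Gaussian noise SD
#'   (gyro units).
#' @return A list of distribution settings, class `"patient_distributions"`.
#' @seealso [generate_patient()], [generate_cohort()]
#' @export
patient_distributions <- function(freq_mean = 5.5,
                                  freq_sd = 1.7,
                                  freq_range = c(2, 12),
                                  rms_mean = c(x = 13.19, y = 16.04, z = 8.25),
                                  rms_sd = c(x = 19.46, y = 30.45, z = 12.80),
                                  threshold_mean = 9.45,
                                  threshold_sd = 4.29,
                                  threshold_range = c(3, 17),
                                  floor_range = c(0.1, 0.4),
                                  hold_mean = 129.55,
                                  hold_sd = 226.71,
                                  hold_range = c(5, 480),
                                  ramp_range = c(10, 30),
                                  noise_range = c(0.2, 1.0)) {
  d <- list(
    freq_mean = freq_mean, freq_sd = freq_sd, freq_range = freq_range,
    rms_mean = rms_mean, rms_sd = rms_sd,
    threshold_mean = threshold_mean, threshold_sd = threshold_sd,
    threshold_range = threshold_range,
    floor_range = floor_range,
    hold_mean = hold_mean, hold_sd = hold_sd, hold_range = hold_range,
    ramp_range = ramp_range, noise_range = noise_range
  )
  validate_patient_distributions(d)
  class(d) <- "patient_distributions"
  d
}

validate_patient_distributions <- function(d) {
  chk_range <- function(r, nm) {
    if (length(r) != 2 || !is.numeric(r) || r[1] >= r[2]) {
      stop(sprintf("invalid distribution bounds for '%s'", nm), call. = FALSE)
    }
  }
  chk_range(d$freq_range, "freq_range")
  chk_range(d$threshold_range, "threshold_range")
  chk_range(d$floor_range, "floor_range")
  chk_range(d$hold_range, "hold_range")
  chk_range(d$ramp_range, "ramp_range")
  chk_range(d$noise_range, "noise_range")
  if (d$freq_range[1] < 2 || d$freq_range[2] > 12) {
    stop("freq_range must lie within (2, 12) Hz", call. = FALSE)
  }
  if (d$floor_range[1] <= 0 || d$floor_range[2] >= 0.5) {
    stop("floor_range must lie within (0, 0.5)", call. = FALSE)
  }
  if (d$threshold_range[1] <= 0) {
    stop("threshold_range must be positive", call. = FALSE)
  }
  if (d$hold_range[1] < 0) stop("hold_range must be non-negative", call. = FALSE)
  if (any(d$rms_mean <= 0) || any(d$rms_sd <= 0) ||
      d$freq_sd <= 0 || d$threshold_sd <= 0 || d$hold_sd <= 0) {
    stop("distribution scales must be positive", call. = FALSE)
  }
  invisible(d)
}

# Inverse-CDF truncated-normal sampler (exact, no rejection loop).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Mean of a truncated normal distribution
#'
#' Closed-form expectation of a normal(mean, sd) variate truncated to
#' `[lower, upper]`; used to state the generator's actual moments.
#'
#' @param mean,sd Moments of the untruncated normal.
#' @param lower,upper Truncation bounds.
#' @return The truncated mean.
#' @export
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Log-normal meanlog/sdlog giving a target arithmetic mean and SD.
lnorm_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

rlnorm_trunc <- function(n, mean, sd, lower, upper) {
  p <- lnorm_params(mean, sd)
  pl <- stats::plnorm(lower, p$meanlog, p$sdlog)
  pu <- stats::plnorm(upper, p$meanlog, p$sdlog)
  stats::qlnorm(pl + stats::runif(n) * (pu - pl), p$meanlog, p$sdlog)
}

#' Generate a virtual tremor patient
#'
#' Draws one patient profile from the configured distributions. A profile
#' fully determines the patient's tremor and stimulation-response dynamics:
#' per-axis dominant frequency and baseline RMS amplitude, the pulse
#' amplitude threshold above which EMS suppresses the tremor, the fraction
#' of tremor amplitude remaining under effective stimulation
#' (`suppression_floor`), the post-withdrawal hold (`reset_hold`), the
#' linear re-emergence ramp duration, and the additive noise scale.
#'
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param dist Distribution settings from [patient_distributions()].
#' @param patient_id Identifier stored in the profile.
#' @return A `patient_profile` object (a named list).
#' @examples
#' p <- generate_patient(seed = 1)
#' p$tremor_freq
#' @export
generate_patient <- function(seed,
                             dist = patient_distributions(),
                             patient_id = sprintf("P%03d", seed %% 1000L)) {
  validate_patient_distributions(dist)
  set.seed(seed)
  draw_patient(dist, patient_id)
}

# Draw using the current RNG state (used by generate_cohort for one
# seed-fan-out stream).
draw_patient <- function(dist, patient_id) {
  ax <- c("x", "y", "z")
  freq <- rtruncnorm(3, dist$freq_mean, dist$freq_sd,
                     dist$freq_range[1], dist$freq_range[2])
  names(freq) <- ax
  rms <- vapply(ax, function(a) {
    rlnorm_trunc(1, dist$rms_mean[[a]], dist$rms_sd[[a]], 1e-3, Inf)
  }, numeric(1))
  profile <- list(
    patient_id = patient_id,
    tremor_freq = freq,
    baseline_rms = rms,
    response_threshold = rtruncnorm(1, dist$threshold_mean, dist$threshold_sd,
                                    dist$threshold_range[1],
                                    dist$threshold_range[2]),
    suppression_floor = stats::runif(1, dist$floor_range[1],
                                     dist$floor_range[2]),
    reset_hold = rlnorm_trunc(1, dist$hold_mean, dist$hold_sd,
                              dist$hold_range[1], dist$hold_range[2]),
    reemergence_ramp = stats::runif(1, dist$ramp_range[1], dist$ramp_range[2]),
    noise_sd = stats::runif(1, dist$noise_range[1], dist$noise_range[2]),
    phase = stats::runif(3, 0, 2 * pi)
  )
  names(profile$phase) <- ax
  class(profile) <- "patient_profile"
  validate_patient_profile(profile)
}

#' Construct a patient profile explicitly
#'
#' Builds a `patient_profile` from given parameter values (rather than
#' drawing them); useful for controlled experiments and tests.
#'
#' @param patient_id Identifier.
#' @param tremor_freq Per-axis tremor frequency (Hz); length 1 or 3.
#' @param baseline_rms Per-axis baseline RMS angular velocity; length 1 or 3.
#' @param response_threshold Suppression threshold (mA).
#' @param suppression_floor Fraction of baseline amplitude remaining under
#'   effective stimulation, in (0, 0.5).
#' @param reset_hold Seconds of continued suppression after withdrawal.
#' @param reemergence_ramp Seconds of linear return to baseline.
#' @param noise_sd Additive Gaussian noise SD (gyro units).
#' @param phase Per-axis oscillation phase (radians); length 1 or 3.
#' @return A `patient_profile` object.
#' @export
patient_profile <- function(patient_id = "P001",
                            tremor_freq = 5,
                            baseline_rms = 10,
                            response_threshold = 5,
                            suppression_floor = 0.25,
                            reset_hold = 60,
                            reemergence_ramp = 20,
                            noise_sd = 0,
                            phase = 0) {
  ax <- c("x", "y", "z")
  rep3 <- function(v) {
    v <- rep_len(as.numeric(v), 3)
    names(v) <- ax
    v
  }
  profile <- list(
    patient_id = patient_id,
    tremor_freq = rep3(tremor_freq),
    baseline_rms = rep3(baseline_rms),
    response_threshold = response_threshold,
    suppression_floor = suppression_floor,
    reset_hold = reset_hold,
    reemergence_ramp = reemergence_ramp,
    noise_sd = noise_sd,
    phase = rep3(phase)
  )
  class(profile) <- "patient_profile"
  validate_patient_profile(profile)
}

validate_patient_profile <- function(p) {
  stopifnot(is.list(p))
  if (any(p$tremor_freq <= 2) || any(p$tremor_freq >= 12)) {
    stop("tremor_freq must lie within (2, 12) Hz", call. = FALSE)
  }
  if (p$suppression_floor <= 0 || p$suppression_floor >= 0.5) {
    stop("suppression_floor must lie within (0, 0.5)", call. = FALSE)
  }
  if (p$response_threshold <= 0) {
    stop("response_threshold must be positive", call. = FALSE)
  }
  if (p$reset_hold < 0) stop("reset_hold must be >= 0", call. = FALSE)
  if (p$reemergence_ramp < 0) {
    stop("reemergence_ramp must be >= 0", call. = FALSE)
  }
  if (any(p$baseline_rms <= 0)) {
    stop("baseline_rms must be positive", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("Virtual tremor patient", x$patient_id, "\n")
  cat(sprintf("  tremor frequency (Hz):  x %.2f  y %.2f  z %.2f\n",
              x$tremor_freq["x"], x$tremor_freq["y"], x$tremor_freq["z"]))
  cat(sprintf("  baseline RMS:           x %.2f  y %.2f  z %.2f\n",
              x$baseline_rms["x"], x$baseline_rms["y"], x$baseline_rms["z"]))
  cat(sprintf("  response threshold:     %.2f mA\n", x$response_threshold))
  cat(sprintf("  suppression floor:      %.2f\n", x$suppression_floor))
  cat(sprintf("  reset hold / ramp:      %.1f s / %.1f s\n",
              x$reset_hold, x$reemergence_ramp))
  cat(sprintf("  noise SD:               %.2f\n", x$noise_sd))
  invisible(x)
}

#' Generate a cohort of virtual patients
#'
#' @param n Number of patients.
#' @param seed Master seed; patient draws consume one RNG stream
#'   deterministically.
#' @param dist Distribution settings from [patient_distributions()].
#' @return A list of `patient_profile` objects with ids `P001..Pnnn`.
#' @export
generate_cohort <- function(n, seed, dist = patient_distributions()) {
  stopifnot(n >= 1)
  validate_patient_distributions(dist)
  set.seed(seed)
  lapply(seq_len(n), function(i) draw_patient(dist, sprintf("P%03d", i)))
}
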