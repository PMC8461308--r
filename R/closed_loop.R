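#' Closed-loop controller configuration
#'
#' Settings for the simulated automatic stimulation controller: one
#' decision per 1-s feature window, amplitude slewed by at most
#' `ramp_step` mA per step towards the maximum amplitude of the
#' model-predicted class, with the 2.5x stopping rule terminating
#' stimulation. `dwell` reproduces the manual protocol's slower ramp (one
#' step per `dwell` windows); `hold_s` optionally continues stimulation
#' for that many seconds after the stopping criterion before switching
#' off (the manual protocol held ~30 s; the default stops immediately).
#'
#' @param ramp_step Maximum amplitude change per decision step (mA).
#' @param dwell Decision steps between amplitude changes.
#' @param hold_s Seconds of continued stimulation after the stopping
#'   criterion is met.
#' @param criteria [reduction_criteria()] supplying the stopping ratio.
#' @return A `controller_config` list.
#' @export
controller_config <- function(ramp_step = 1, dwell = 1, hold_s = 0,
                              criteria = reduction_criteria()) {
  stopifnot(ramp_step > 0, dwell >= 1, hold_s >= 0)
  structure(list(ramp_step = ramp_step, dwell = dwell, hold_s = hold_s,
                 criteria = criteria),
            class = "controller_config")
}

#' Initial controller state
#'
#' @return A `controller_state` list: zero amplitude, predicted class 0,
#'   idle phase, no stimulation-start reference.
#' @export
controller_init <- function() {
  structure(list(current_amplitude = 0, predicted_class = 0L,
                 windows_at_level = 0L, stim_start_reference = NULL,
                 phase = "idle", model_state = NULL, hold_left = 0),
            class = "controller_state")
}

#' One controller decision step
#'
#' Feeds the current window's RMS features and the controller's own
#' previous predicted class (free-running, no teacher forcing) to the
#' model, then slews the commanded amplitude by at most `ramp_step` mA
#' towards the predicted class's maximum amplitude. When the 2.5x
#' stopping criterion (x and y RMS versus the reference captured at
#' stimulation onset) is met, stimulation is switched off (after the
#' configured hold, if any) and the controller remains stopped for the
#' session.
#'
#' @param state A `controller_state`.
#' @param window A single `feature_windows` row.
#' @param model A fitted `stim_model` (trained with the
#'   `gyro_plus_prev` feature set) or an oracle/constant model.
#' @param config A [controller_config()].
#' @return List with `state` (updated) and `command` (amplitude in mA for
#'   the next window).
#' @export
controller_step <- function(state, window, model,
                            config = controller_config()) {
  if (is.null(model)) stop("untrained model", call. = FALSE)
  if (inherits(model, "stim_model") && !model$degenerate &&
      is.null(model$fit)) {
    stop("untrained model", call. = FALSE)
  }
  if (inherits(model, "stim_model") &&
      model$spec$feature_set != "gyro_plus_prev") {
    stop("closed-loop control requires a model trained with gyro_plus_prev",
         call. = FALSE)
  }
  stp <- model_step(model, window$rms_x, window$rms_y, window$rms_z,
                    prev_class = state$predicted_class,
                    state = state$model_state)
  state$model_state <- stp$state
  state$predicted_class <- as.integer(stp$class)
  target <- class_to_max_amplitude(state$predicted_class)

  if (state$phase == "stopped") {
    state$current_amplitude <- 0
    return(list(state = state, command = 0))
  }

  # capture the stimulation-onset reference the first time amplitude
  # becomes positive
  if (state$phase == "idle" && target > 0) {
    state$phase <- "ramping"
    state$stim_start_reference <- list(rms_x = window$rms_x,
                                       rms_y = window$rms_y,
                                       rms_z = window$rms_z)
  }

  if (state$phase %in% c("ramping", "holding") &&
      !is.null(state$stim_start_reference) &&
      state$current_amplitude > 0 &&
      stop_criterion_met(window, state$stim_start_reference,
                         config$criteria)) {
    if (config$hold_s > 0 && state$hold_left == 0 &&
        state$phase != "holding") {
      state$phase <- "holding"
      state$hold_left <- config$hold_s
    } else if (config$hold_s == 0) {
      state$phase <- "stopped"
      state$current_amplitude <- 0
      return(list(state = state, command = 0))
    }
  }
  if (state$phase == "holding") {
    if (state$hold_left <= 0) {
      state$phase <- "stopped"
      state$current_amplitude <- 0
      return(list(state = state, command = 0))
    }
    state$hold_left <- state$hold_left - 1L
    return(list(state = state, command = state$current_amplitude))
  }

  state$windows_at_level <- state$windows_at_level + 1L
  command <- state$current_amplitude
  if (state$windows_at_level >= config$dwell) {
    delta <- max(-config$ramp_step,
                 min(config$ramp_step, target - state$current_amplitude))
    command <- state$current_amplitude + delta
    if (delta != 0) state$windows_at_level <- 0L
  }
  state$current_amplitude <- command
  list(state = state, command = command)
}

#' Run a closed-loop stimulation session against a virtual patient
#'
#' Simulates a full session with the controller in the loop: a baseline
#' section with no stimulation, a controlled section in which each 1-s
#' window's features are fed to the model and the commanded amplitude is
#' applied to the next window, and a post-stimulation section after the
#' controller stops (or the during budget is exhausted). The resulting
#' stream is summarized with the same session metrics as a manual
#' session.
#'
#' @param profile A `patient_profile`.
#' @param model A fitted `stim_model` (gyro_plus_prev) or oracle model.
#' @param config A [session_config()] (section durations, sampling).
#' @param control A [controller_config()].
#' @param seed Seed for the noise stream.
#' @return List with `summary` (a `reset_summary`), `trace` (per-window
#'   command log: window, command, predicted class, phase), `windows`,
#'   and `stream`.
#' @export
run_closed_loop <- function(profile, model, config = session_config(),
                            control = controller_config(), seed = 1) {
  validate_patient_profile(profile)
  set.seed(seed)
  fs <- config$sample_rate
  dt <- 1 / fs
  n_per <- round(fs)

  env_state <- envelope_state_init()
  make_window <- function(t0, amp, section) {
    times <- t0 + seq(0, 1 - dt, by = dt)
    envr <- envelope_advance(env_state, times, rep(amp, n_per), profile,
                             config$onset_smooth_s)
    env_state <<- envr$state
    sig <- synth_block(times, envr$env, profile)
    data.frame(time = times, gx = sig$gx, gy = sig$gy, gz = sig$gz,
               pulse_ma = amp, section = section, stringsAsFactors = FALSE)
  }
  window_features <- function(blk) {
    list(rms_x = sqrt(mean(blk$gx^2)), rms_y = sqrt(mean(blk$gy^2)),
         rms_z = sqrt(mean(blk$gz^2)))
  }

  blocks <- vector("list", 0)
  # baseline section
  for (w in seq_len(config$before_s)) {
    blocks[[length(blocks) + 1]] <- make_window((w - 1), 0, "before")
  }

  state <- controller_init()
  command <- 0
  trace <- list()
  t0 <- config$before_s
  n_during <- 0
  for (w in seq_len(config$max_during_s)) {
    blk <- make_window(t0 + (w - 1), command, "during")
    blocks[[length(blocks) + 1]] <- blk
    n_during <- n_during + 1
    feats <- window_features(blk)
    res <- controller_step(state, feats, model, control)
    state <- res$state
    trace[[length(trace) + 1]] <- data.frame(
      window = w, command = res$command,
      predicted_class = state$predicted_class,
      phase = state$phase, stringsAsFactors = FALSE)
    command <- res$command
    if (state$phase == "stopped") break
  }
  # post-stimulation observation
  t0 <- config$before_s + n_during
  for (w in seq_len(config$after_s)) {
    blocks[[length(blocks) + 1]] <- make_window(t0 + (w - 1), 0, "after")
  }

  stream <- do.call(rbind, blocks)
  attr(stream, "sample_rate") <- fs
  class(stream) <- c("gyro_stream", "data.frame")
  windows <- rms_windows(stream)
  boundaries <- segment_session(windows)
  summary <- if (length(boundaries$during)) {
    compute_reset_summary(windows, boundaries, control$criteria)
  } else {
    reset_summary(A = 0.0, B = 0, C = 0)
  }
  list(summary = summary, trace = do.call(rbind, trace),
       windows = windows, stream = stream)
}

#' Oracle stimulation-class model for a known virtual patient
#'
#' Predicts, regardless of input, the stimulation class whose amplitude
#' range contains the patient's (integer-rounded-up) response threshold —
#' the class an omniscient controller would request. Useful as a
#' ground-truth upper bound for closed-loop experiments.
#'
#' @param profile A `patient_profile`.
#' @return An `oracle_model` usable wherever a `stim_model` is.
#' @export
oracle_model <- function(profile) {
  structure(list(class = amplitude_to_class(ceiling(profile$response_threshold))),
            class = "oracle_model")
}

#' Constant-class model
#'
#' Always predicts the given stimulation class; `constant_model(0)` never
#' stimulates.
#'
#' @param class Stimulation class 0-4.
#' @return A `constant_model`.
#' @export
constant_model <- function(class) {
  stopifnot(class %in% 0:4)
  structure(list(class = as.integer(class)), class = "constant_model")
}

#' @export
model_step.oracle_model <- function(model, rms_x, rms_y, rms_z, prev_class,
                                    state = NULL) {
  list(class = model$class, state = NULL)
}

#' @export
model_step.constant_model <- function(model, rms_x, rms_y, rms_z,
                                      prev_class, state = NULL) {
  list(class = model$class, state = NULL)
}
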