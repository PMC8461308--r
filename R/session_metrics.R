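#' Tremor-reduction measurement criteria
#'
#' Thresholds governing how tremor suppression is detected and summarized:
#' the >50% gyroscope reduction criterion, the 2.5x stopping rule applied
#' to the x and y axes, the persistence (in consecutive 1-s windows)
#' required before a state change is accepted, and the fraction of
#' baseline magnitude at which the tremor is considered to have re-emerged
#' to pre-stimulation levels.
#'
#' @param gyro_reduction_fraction Fractional reduction defining "reduced"
#'   (default 0.5: magnitude below 50% of baseline).
#' @param stop_ratio Ratio by which `rms_x` and `rms_y` must both fall
#'   versus the value at stimulation start for the stopping rule
#'   (default 2.5).
#' @param persistence_k Consecutive windows required to enter or leave a
#'   state (debouncing; default 3 rejects single-window noise at the 1-s
#'   resolution).
#' @param reemergence_fraction Fraction of the baseline magnitude at which
#'   re-emergence is declared (default 0.75; the protocol's verbal
#'   "re-emerged to the pre-stimulation level" gives no number).
#' @return A `reduction_criteria` list.
#' @export
reduction_criteria <- function(gyro_reduction_fraction = 0.5,
                               stop_ratio = 2.5,
                               persistence_k = 3,
                               reemergence_fraction = 0.75) {
  if (gyro_reduction_fraction <= 0 || gyro_reduction_fraction >= 1) {
    stop("gyro_reduction_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (stop_ratio <= 1) stop("stop_ratio must exceed 1", call. = FALSE)
  if (persistence_k < 1) stop("persistence_k must be >= 1", call. = FALSE)
  if (reemergence_fraction <= 0 || reemergence_fraction > 1) {
    stop("reemergence_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(gyro_reduction_fraction = gyro_reduction_fraction,
                 stop_ratio = stop_ratio,
                 persistence_k = persistence_k,
                 reemergence_fraction = reemergence_fraction),
            class = "reduction_criteria")
}

#' Segment a session into before / during / after stimulation
#'
#' Sections are derived from the windowed pulse amplitude: `before` is all
#' windows with zero amplitude preceding the first stimulated window,
#' `during` runs from the first to the last window with positive
#' amplitude, `after` is the remainder. If no window is stimulated the
#' whole session is `before` and the result is flagged.
#'
#' @param windows A `feature_windows` data frame.
#' @return List with integer index vectors `before`, `during`, `after`
#'   and the logical flag `no_stimulation`.
#' @export
segment_session <- function(windows) {
  stim <- which(windows$i_t > 0)
  n <- nrow(windows)
  if (!length(stim)) {
    return(list(before = seq_len(n), during = integer(0), after = integer(0),
                no_stimulation = TRUE))
  }
  first <- min(stim)
  last <- max(stim)
  list(before = seq_len(first - 1L),
       during = first:last,
       after = if (last < n) (last + 1L):n else integer(0),
       no_stimulation = FALSE)
}

#' Baseline per-axis RMS reference
#'
#' The per-axis median RMS over the before-stimulation windows. The median
#' is robust to occasional movement-artifact windows in the baseline
#' section.
#'
#' @param windows The before-section `feature_windows` (at least 30
#'   windows, i.e. 30 s of baseline).
#' @param min_windows Minimum number of baseline windows required.
#' @return Named numeric vector with components `x`, `y`, `z` and the
#'   attribute `magnitude` (Euclidean norm of the three medians).
#' @export
baseline_rms <- function(windows, min_windows = 30) {
  if (nrow(windows) < min_windows) {
    stop(sprintf("need at least %d baseline windows, got %d", min_windows,
                 nrow(windows)), call. = FALSE)
  }
  ref <- c(x = stats::median(windows$rms_x),
           y = stats::median(windows$rms_y),
           z = stats::median(windows$rms_z))
  attr(ref, "magnitude") <- sqrt(sum(ref^2))
  ref
}

# Debounced state sequence: raw per-window booleans are accepted as a
# state change only when sustained for k consecutive windows; the change
# is then labelled from the start of the sustaining run. Same persistence
# applies for entry and exit.
debounce_state <- function(raw, k, init = FALSE) {
  if (!length(raw)) return(logical(0))
  r <- rle(raw)
  state <- init
  out <- logical(0)
  for (j in seq_along(r$lengths)) {
    if (r$values[j] != state && r$lengths[j] >= k) state <- r$values[j]
    out <- c(out, rep(state, r$lengths[j]))
  }
  out
}

#' Per-window tremor-reduction state
#'
#' A window is marked "reduced" when its three-axis RMS magnitude falls
#' below `(1 - gyro_reduction_fraction)` times the baseline magnitude,
#' sustained for `persistence_k` consecutive windows (hysteresis with the
#' same persistence on exit).
#'
#' @param windows A `feature_windows` data frame (any subset of a
#'   session, in order).
#' @param baseline Baseline reference from [baseline_rms()].
#' @param criteria A [reduction_criteria()] object.
#' @return Logical vector, one element per window.
#' @export
detect_reduction_state <- function(windows, baseline,
                                   criteria = reduction_criteria()) {
  base_mag <- attr(baseline, "magnitude")
  if (is.null(base_mag)) base_mag <- sqrt(sum(baseline^2))
  raw <- rms_magnitude(windows) <
    (1 - criteria$gyro_reduction_fraction) * base_mag
  debounce_state(raw, criteria$persistence_k)
}

#' Summarize tremor suppression for one session
#'
#' Computes the reset-time decomposition of a stimulation session:
#' \describe{
#'   \item{A (`stim_duration_A`)}{length of the during-stimulation
#'     section;}
#'   \item{B (`reduction_during_B`)}{time spent in the reduced state
#'     within the during section;}
#'   \item{C (`continuing_after_C`)}{time from stimulation switch-off
#'     until the tremor first re-emerges (magnitude at or above the
#'     re-emergence fraction of baseline, sustained `persistence_k`
#'     windows); zero if the tremor was not reduced at switch-off;
#'     censored at session end if re-emergence is never observed;}
#'   \item{D (`reset_time_D`)}{the tremor reset time, `B + C`.}
#' }
#' Also reports the maximum and mean pulse amplitude over the during
#' section.
#'
#' @param windows The full session's `feature_windows`.
#' @param boundaries Section boundaries from [segment_session()]; computed
#'   if `NULL`.
#' @param criteria A [reduction_criteria()] object.
#' @param baseline Baseline reference from [baseline_rms()]; computed from
#'   the before section if `NULL`.
#' @return A `reset_summary` list with components `stim_duration_A`,
#'   `reduction_during_B`, `continuing_after_C`, `reset_time_D`,
#'   `max_amplitude`, `avg_amplitude`, `baseline_rms`, `censored`,
#'   `reduced_at_off`.
#' @export
compute_reset_summary <- function(windows, boundaries = NULL,
                                  criteria = reduction_criteria(),
                                  baseline = NULL) {
  if (is.null(boundaries)) boundaries <- segment_session(windows)
  if (!length(boundaries$during)) {
    stop("during section is empty: no stimulation present", call. = FALSE)
  }
  w_s <- attr(windows, "window_s")
  if (is.null(w_s)) w_s <- 1
  if (is.null(baseline)) {
    baseline <- baseline_rms(windows[boundaries$before, , drop = FALSE])
  }
  base_mag <- attr(baseline, "magnitude")

  reduced <- detect_reduction_state(windows, baseline, criteria)
  A <- length(boundaries$during) * w_s
  B <- sum(reduced[boundaries$during]) * w_s

  after <- boundaries$after
  reduced_at_off <- length(boundaries$during) > 0 &&
    reduced[max(boundaries$during)]
  censored <- FALSE
  if (!reduced_at_off || !length(after)) {
    C <- 0
    censored <- !length(after) && reduced_at_off
  } else {
    raw_re <- rms_magnitude(windows[after, , drop = FALSE]) >=
      criteria$reemergence_fraction * base_mag
    re_state <- debounce_state(raw_re, criteria$persistence_k)
    if (any(re_state)) {
      C <- (which(re_state)[1] - 1L) * w_s
    } else {
      C <- length(after) * w_s
      censored <- TRUE
    }
  }

  during_amp <- windows$i_t[boundaries$during]
  out <- list(stim_duration_A = A,
              reduction_during_B = B,
              continuing_after_C = C,
              reset_time_D = B + C,
              max_amplitude = max(during_amp),
              avg_amplitude = mean(during_amp),
              baseline_rms = baseline,
              censored = censored,
              reduced_at_off = reduced_at_off)
  class(out) <- "reset_summary"
  out
}

#' Assemble a reset summary from known durations
#'
#' Constructs a `reset_summary` directly from the durations of tremor
#' reduction during stimulation (B) and of continuing reduction after
#' withdrawal (C); the reset time D is their sum by definition.
#'
#' @param A Stimulation duration (s).
#' @param B Reduction time during stimulation (s); must not exceed `A`.
#' @param C Continuing reduction after withdrawal (s).
#' @param max_amplitude,avg_amplitude Pulse-amplitude statistics (mA).
#' @return A `reset_summary` list.
#' @export
reset_summary <- function(A, B, C, max_amplitude = NA_real_,
                          avg_amplitude = NA_real_) {
  if (B < 0 || C < 0 || B > A) {
    stop("require 0 <= B <= A and C >= 0", call. = FALSE)
  }
  if (!is.na(max_amplitude) && !is.na(avg_amplitude) &&
      max_amplitude < avg_amplitude) {
    stop("max_amplitude must be >= avg_amplitude", call. = FALSE)
  }
  structure(list(stim_duration_A = A, reduction_during_B = B,
                 continuing_after_C = C, reset_time_D = B + C,
                 max_amplitude = max_amplitude,
                 avg_amplitude = avg_amplitude,
                 baseline_rms = NULL, censored = FALSE,
                 reduced_at_off = B > 0),
            class = "reset_summary")
}

#' @export
print.reset_summary <- function(x, ...) {
  cat("Tremor reset summary\n")
  cat(sprintf("  stimulation duration (A):          %8.1f s\n",
              x$stim_duration_A))
  cat(sprintf("  reduction during stimulation (B):  %8.1f s\n",
              x$reduction_during_B))
  cat(sprintf("  continuing reduction after (C):    %8.1f s%s\n",
              x$continuing_after_C, if (x$censored) " [censored]" else ""))
  cat(sprintf("  tremor reset time (D = B + C):     %8.1f s\n",
              x$reset_time_D))
  if (!is.na(x$max_amplitude)) {
    cat(sprintf("  pulse amplitude max / mean:        %.1f / %.2f mA\n",
                x$max_amplitude, x$avg_amplitude))
  }
  invisible(x)
}

#' Stimulation stopping rule (2.5x reduction on x and y)
#'
#' TRUE once the RMS on both the x and y axes has fallen by at least
#' `stop_ratio` (default 2.5) times relative to the reference captured at
#' stimulation start. Division is guarded by flooring the current RMS at
#' machine epsilon.
#'
#' @param window A single `feature_windows` row (or list with `rms_x`,
#'   `rms_y`).
#' @param reference Reference RMS at stimulation start (named `rms_x`,
#'   `rms_y`, or a row with those columns).
#' @param criteria A [reduction_criteria()] object.
#' @return Logical scalar.
#' @export
stop_criterion_met <- function(window, reference,
                               criteria = reduction_criteria()) {
  eps <- .Machine$double.eps
  rx <- reference$rms_x / max(window$rms_x, eps)
  ry <- reference$rms_y / max(window$rms_y, eps)
  isTRUE(rx >= criteria$stop_ratio && ry >= criteria$stop_ratio)
}
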