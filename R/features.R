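#' Windowed RMS features of a gyroscope stream
#'
#' Aggregates a raw gyroscope stream into non-overlapping windows (1 s by
#' default) anchored at the session start, computing the root mean square
#' of angular velocity per axis over each half-open interval
#' `[k, k+window_s)`. Each window also carries the pulse amplitude applied
#' within it (the modal sample value; ties resolved to the later value,
#' matching a stepped protocol where changes within a window are rare) and
#' the protocol section. A trailing partial window is dropped.
#'
#' @param stream A `gyro_stream`.
#' @param window_s Window length in seconds.
#' @param demean If `TRUE`, remove the within-window mean before squaring
#'   (for real logs with sensor offset; the simulator is zero-mean by
#'   construction).
#' @return A `feature_windows` data frame with columns `window_index`,
#'   `rms_x`, `rms_y`, `rms_z`, `i_t`, `section`.
#' @export
rms_windows <- function(stream, window_s = 1, demean = FALSE) {
  if (!nrow(stream)) stop("empty stream", call. = FALSE)
  fs <- attr(stream, "sample_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(stream$time))
  n_per <- round(window_s * fs)
  if (n_per < 2) {
    stop("window_s x sample_rate must be at least 2 samples", call. = FALSE)
  }
  k <- nrow(stream) %/% n_per
  if (k < 1) stop("stream shorter than one window", call. = FALSE)
  idx <- seq_len(k * n_per)
  win <- rep(seq_len(k), each = n_per)

  rms_of <- function(x) {
    x <- x[idx]
    if (demean) {
      mu <- tapply(x, win, mean)
      x <- x - mu[win]
    }
    m <- matrix(x^2, nrow = n_per)
    sqrt(colMeans(m))
  }

  modal_one <- function(v) {
    # most frequent value; ties broken in favour of the later-appearing one
    ch <- as.character(v)
    tb <- table(ch)
    cand <- names(tb)[tb == max(tb)]
    pos <- vapply(cand, function(cc) max(which(ch == cc)), integer(1))
    v[max(pos)]
  }
  modal_last <- function(x) {
    x <- x[idx]
    unname(vapply(split(x, win), modal_one, x[1]))
  }

  out <- data.frame(
    window_index = seq_len(k),
    rms_x = rms_of(stream$gx),
    rms_y = rms_of(stream$gy),
    rms_z = rms_of(stream$gz),
    i_t = as.numeric(modal_last(stream$pulse_ma)),
    section = as.character(modal_last(as.character(stream$section))),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "window_s") <- window_s
  attr(out, "sample_rate") <- fs
  class(out) <- c("feature_windows", "data.frame")
  out
}

#' Euclidean magnitude of a per-axis RMS triple
#'
#' `sqrt(rms_x^2 + rms_y^2 + rms_z^2)`, vectorized over windows. Used by
#' the tremor-reduction criteria, which assess the three-axis magnitude.
#'
#' @param windows A `feature_windows` data frame (or any data frame with
#'   `rms_x`, `rms_y`, `rms_z` columns), or a numeric vector of length 3.
#' @return Numeric vector of magnitudes.
#' @export
rms_magnitude <- function(windows) {
  if (is.numeric(windows) && length(windows) == 3) {
    return(sqrt(sum(windows^2)))
  }
  sqrt(windows$rms_x^2 + windows$rms_y^2 + windows$rms_z^2)
}

#' Dominant tremor frequency of a stream segment
#'
#' Estimates the dominant oscillation frequency of one gyroscope axis by
#' the maximum of a zero-padded periodogram restricted to a frequency band
#' (2-12 Hz by default, the resting-tremor range). Padding guarantees a
#' grid resolution of 0.0625 Hz or finer.
#'
#' @param stream A `gyro_stream` (or data frame with the axis column).
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param band Search band in Hz, `c(low, high)`.
#' @param resolution Maximum frequency-grid spacing (Hz).
#' @return A `spectrum_estimate` list: `axis`, `dominant_freq`,
#'   `peak_power`.
#' @export
dominant_frequency <- function(stream, axis = "x", band = c(2, 12),
                               resolution = 0.0625) {
  fs <- attr(stream, "sample_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(stream$time))
  col <- paste0("g", axis)
  if (!col %in% names(stream)) stop("unknown axis: ", axis, call. = FALSE)
  x <- stream[[col]]
  n <- length(x)
  if (n < 2 * fs) stop("segment must be at least 2 s long", call. = FALSE)
  if (fs <= 2 * band[2]) {
    stop("sample rate must exceed twice the band maximum", call. = FALSE)
  }
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(max(n, fs / resolution)))
  sp <- Mod(stats::fft(c(x, numeric(nfft - n))))^2 / n
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("empty frequency band", call. = FALSE)
  i <- which(keep)[which.max(sp[keep])]
  out <- list(axis = axis, dominant_freq = freqs[i], peak_power = sp[i])
  class(out) <- "spectrum_estimate"
  out
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("Dominant frequency (%s axis): %.3f Hz (peak power %.3g)\n",
              x$axis, x$dominant_freq, x$peak_power))
  invisible(x)
}
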