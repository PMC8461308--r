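#' Write a gyroscope stream to a glove-log CSV file
#'
#' The on-disk dialect mirrors the glove's cloud logs: a comma-separated
#' UTF-8 file with a header row and columns `timestamp`, `gx`, `gy`, `gz`,
#' `pulse_amplitude_mA`, `section`.
#'
#' @param stream A `gyro_stream`.
#' @param path Output file path.
#' @param digits Number of significant digits written for numeric columns.
#' @return `path`, invisibly.
#' @export
write_glove_csv <- function(stream, path, digits = 8) {
  validate_gyro_stream(stream)
  out <- data.frame(
    timestamp = signif(stream$time, digits),
    gx = signif(stream$gx, digits),
    gy = signif(stream$gy, digits),
    gz = signif(stream$gz, digits),
    pulse_amplitude_mA = signif(stream$pulse_ma, digits),
    section = stream$section,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a glove-log CSV file
#'
#' Parses a glove log written by [write_glove_csv()] (or an equivalently
#' formatted device export) and validates it: required columns, numeric
#' fields, strictly increasing timestamps. Parse failures report the
#' offending line number.
#'
#' @param path Input file path.
#' @return A `gyro_stream` data frame; the sampling rate is inferred from
#'   the median timestamp spacing.
#' @export
read_glove_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("timestamp", "gx", "gy", "gz", "pulse_amplitude_mA", "section")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("glove CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("timestamp", "gx", "gy", "gz", "pulse_amplitude_mA")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad)) {
      # +1 for the header row
      stop(sprintf("malformed value in column '%s' at line %d", cl,
                   bad[1] + 1L), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' at line %d", cl,
                   which(is.na(v))[1] + 1L), call. = FALSE)
    }
    raw[[cl]] <- v
  }
  dtime <- diff(raw$timestamp)
  if (any(dtime <= 0)) {
    stop(sprintf("timestamps not strictly increasing at line %d",
                 which(dtime <= 0)[1] + 2L), call. = FALSE)
  }
  stream <- data.frame(time = raw$timestamp, gx = raw$gx, gy = raw$gy,
                       gz = raw$gz, pulse_ma = raw$pulse_amplitude_mA,
                       section = raw$section, stringsAsFactors = FALSE)
  attr(stream, "sample_rate") <- 1 / stats::median(dtime)
  class(stream) <- c("gyro_stream", "data.frame")
  validate_gyro_stream(stream)
  stream
}
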