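#' Synthetic band-task cohort for learning-sanity benchmarks
#'
#' Generates a labelled multiclass cohort in which the stimulation class
#' is a deterministic function of the gyroscope RMS band and the previous
#' stimulation level: at each 1-s step a direction d in \{-1, 0, +1\} is
#' drawn and encoded in `rms_x` (disjoint bands 0-5, 10-15 and 20-25 for
#' down, stay and up), and the target class is the previous class plus d,
#' clamped to 0-4; `rms_y` and `rms_z` are uninformative noise. A model
#' given the previous stimulation level can therefore recover the target
#' exactly, while a gyroscope-only model can at best infer the direction —
#' the construction isolates the contribution of the
#' previous-stimulation-level feature.
#'
#' @param n_patients Number of patients.
#' @param windows_per_patient Sequence length per patient (1-s windows).
#' @param seed RNG seed.
#' @param p_move Probability of an up (and, symmetrically, down) move;
#'   the clamped symmetric walk makes all five classes well represented.
#' @return A labelled record data frame (`patient_id`, `window_index`,
#'   `rms_x`, `rms_y`, `rms_z`, `prev_class`, `target_class`).
#' @export
synthetic_band_cohort <- function(n_patients = 20,
                                  windows_per_patient = 600,
                                  seed = 1, p_move = 0.35) {
  stopifnot(p_move > 0, p_move < 0.5)
  set.seed(seed)
  bands <- list(`-1` = c(0, 5), `0` = c(10, 15), `1` = c(20, 25))
  out <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    Tn <- windows_per_patient
    d <- sample(c(-1L, 0L, 1L), Tn, replace = TRUE,
                prob = c(p_move, 1 - 2 * p_move, p_move))
    target <- integer(Tn)
    prev <- integer(Tn)
    cur <- 0L
    for (t in seq_len(Tn)) {
      prev[t] <- cur
      cur <- max(0L, min(4L, cur + d[t]))
      target[t] <- cur
    }
    rms_x <- vapply(d, function(dd) {
      b <- bands[[as.character(dd)]]
      stats::runif(1, b[1], b[2])
    }, numeric(1))
    out[[p]] <- data.frame(
      patient_id = sprintf("S%03d", p),
      window_index = seq_len(Tn),
      rms_x = rms_x,
      rms_y = stats::runif(Tn, 0, 25),
      rms_z = stats::runif(Tn, 0, 25),
      prev_class = prev,
      target_class = target,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
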