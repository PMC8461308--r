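#' Map pulse amplitude (mA) to stimulation class
#'
#' Discretizes pulse amplitude into the five stimulation classes used as
#' the prediction target: 0 mA -> class 0, 1-5 mA -> 1, 6-10 mA -> 2,
#' 11-15 mA -> 3, >= 16 mA -> 4. Non-integer amplitudes are floored to the
#' nearest lower integer before the lookup (the protocol uses integer
#' steps; the floor guards real logs).
#'
#' @param amplitude Numeric vector of pulse amplitudes (mA), non-negative.
#' @return Integer vector of classes 0-4.
#' @export
amplitude_to_class <- function(amplitude) {
  if (any(amplitude < 0)) {
    stop("pulse amplitude must be non-negative", call. = FALSE)
  }
  a <- floor(amplitude)
  findInterval(a, c(1, 6, 11, 16))
}

#' Maximum pulse amplitude of a stimulation class
#'
#' The amplitude ceiling the controller ramps towards for each class:
#' 0, 5, 10, 15, 20 mA for classes 0-4.
#'
#' @param class Integer vector of classes 0-4.
#' @return Numeric vector of amplitudes (mA).
#' @export
class_to_max_amplitude <- function(class) {
  if (any(class != floor(class)) || any(class < 0) || any(class > 4)) {
    stop("stimulation class must be an integer in 0..4", call. = FALSE)
  }
  c(0, 5, 10, 15, 20)[class + 1L]
}

#' Build labelled records for one patient's session
#'
#' One record per (retained) 1-s feature window, with the stimulation
#' class of the window as the prediction target and the observed class of
#' the previous window as the teacher-forcing feature `prev_class` (the
#' first record of each patient is padded with class 0).
#'
#' @param windows A `feature_windows` data frame, ordered by time.
#' @param patient_id Identifier stored with each record.
#' @return Data frame with columns `patient_id`, `window_index`, `rms_x`,
#'   `rms_y`, `rms_z`, `prev_class`, `target_class`, `section`.
#' @export
build_records <- function(windows, patient_id = "P001") {
  target <- amplitude_to_class(windows$i_t)
  prev <- c(0L, target[-length(target)])
  data.frame(patient_id = patient_id,
             window_index = windows$window_index,
             rms_x = windows$rms_x, rms_y = windows$rms_y,
             rms_z = windows$rms_z,
             prev_class = prev, target_class = target,
             section = windows$section,
             stringsAsFactors = FALSE)
}

#' Filter out manual-adjustment artefact records
#'
#' Removes during-section windows in which the tremor is present (not in
#' the reduced state) yet no pulse amplitude is applied — the signature of
#' a manual mid-exploration switch-off, which makes a misleading training
#' example (the correct stimulation for a visible tremor is not "off").
#' The rule is criteria-driven: tremor presence reuses the configured
#' reduction criterion.
#'
#' @param records Labelled records from [build_records()].
#' @param windows The session's `feature_windows`.
#' @param reduced Per-window reduction state from
#'   [detect_reduction_state()]; computed if `NULL` (requires a baseline
#'   section of at least 30 windows).
#' @param boundaries Section boundaries from [segment_session()]; computed
#'   if `NULL`.
#' @param criteria A [reduction_criteria()] object.
#' @return List with `records` (retained rows) and `removed` (a removal
#'   log data frame with `window_index` and `reason`).
#' @export
filter_records <- function(records, windows, reduced = NULL,
                           boundaries = NULL,
                           criteria = reduction_criteria()) {
  if (is.null(boundaries)) boundaries <- segment_session(windows)
  if (is.null(reduced)) {
    base <- baseline_rms(windows[boundaries$before, , drop = FALSE])
    reduced <- detect_reduction_state(windows, base, criteria)
  }
  in_during <- seq_len(nrow(windows)) %in% boundaries$during
  drop <- in_during & !reduced & windows$i_t == 0
  drop_idx <- windows$window_index[drop]
  removed <- data.frame(
    window_index = drop_idx,
    reason = rep("tremor present but no amplitude assigned (manual adjustment)",
                 length(drop_idx)),
    stringsAsFactors = FALSE
  )
  list(records = records[!records$window_index %in% drop_idx, , drop = FALSE],
       removed = removed)
}

#' Patient-wise fold assignment
#'
#' Assigns whole patients to `k` folds for grouped cross-validation:
#' patients are shuffled by the seed then split as evenly as possible
#' (e.g. 20 patients into 3 folds of 7, 7 and 6), so no patient
#' contributes records to more than one fold.
#'
#' @param patient_ids Character vector of patient identifiers (duplicates
#'   allowed; the unique set is assigned).
#' @param k Number of folds.
#' @param seed Shuffling seed.
#' @return A `fold_assignment` list with elements `k`, `assignment`
#'   (named integer vector patient -> fold) and `sizes`.
#' @export
grouped_folds <- function(patient_ids, k = 3, seed = 1) {
  patients <- sort(unique(as.character(patient_ids)))
  n <- length(patients)
  if (k > n) stop("more folds than patients", call. = FALSE)
  set.seed(seed)
  shuffled <- sample(patients)
  k <- as.integer(k)
  sizes <- as.integer(n %/% k + (seq_len(k) <= n %% k))
  fold <- rep(seq_len(k), times = sizes)
  assignment <- stats::setNames(fold, shuffled)
  assignment <- assignment[order(names(assignment))]
  structure(list(k = k, assignment = assignment, sizes = sizes, seed = seed),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Patient-wise %d-fold assignment (%d patients; sizes %s)\n",
              x$k, length(x$assignment),
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Per-fold class counts and percentages
#'
#' Tabulates stimulation-class counts per fold, with percentages
#' recomputed as `count / fold total * 100`, plus a totals row summed over
#' folds. Folds with no records of a class report a zero percentage.
#'
#' @param records Labelled records (rows with `patient_id`,
#'   `target_class`).
#' @param folds A `fold_assignment`.
#' @return List with matrices `counts` and `percentages`
#'   (rows = folds + `"total"`, columns = classes 0-4) and vector
#'   `fold_totals`.
#' @export
fold_summary <- function(records, folds) {
  miss <- setdiff(unique(records$patient_id), names(folds$assignment))
  if (length(miss)) {
    stop("records contain patients absent from the fold assignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fold_of <- folds$assignment[records$patient_id]
  cls <- factor(records$target_class, levels = 0:4)
  counts <- table(factor(fold_of, levels = seq_len(folds$k)), cls)
  counts <- matrix(as.integer(counts), nrow = folds$k,
                   dimnames = list(paste0("fold", seq_len(folds$k)),
                                   paste0("class", 0:4)))
  totals <- rowSums(counts)
  pct <- counts / ifelse(totals > 0, totals, 1) * 100
  counts_all <- rbind(counts, total = colSums(counts))
  grand <- sum(counts)
  pct_all <- rbind(pct, total = colSums(counts) / max(grand, 1) * 100)
  list(counts = counts_all, percentages = pct_all,
       fold_totals = c(totals, total = grand))
}
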