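# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths wherever they serve as
# a cross-check.

# brute-force RMS of a numeric vector
brute_rms <- function(x) sqrt(sum(x^2) / length(x))

# brute-force one-vs-rest macro metrics from a confusion matrix, written
# with explicit loops and scalar arithmetic
brute_macro <- function(cm) {
  K <- nrow(cm)
  P <- R <- F1 <- acc <- numeric(K)
  present <- logical(K)
  for (c in seq_len(K)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    P[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    R[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    F1[c] <- if (P[c] + R[c] > 0) 2 * R[c] * P[c] / (R[c] + P[c]) else 0
    present[c] <- sum(cm[c, ]) > 0
    acc[c] <- if (present[c]) tp / sum(cm[c, ]) else NA_real_
  }
  list(macro_precision = mean(P[present]), macro_recall = mean(R[present]),
       macro_f1 = mean(F1[present]),
       accuracy = sum(diag(cm)) / sum(cm), per_class_accuracy = acc)
}

# exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# patterns (no ties in |d| assumed)
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% rk
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# assemble a gyro_stream from raw channel vectors
make_stream <- function(gx, gy = gx, gz = gx, fs = 50, pulse = 0,
                        section = "before") {
  n <- length(gx)
  s <- data.frame(time = seq(0, by = 1 / fs, length.out = n),
                  gx = gx, gy = gy, gz = gz,
                  pulse_ma = rep_len(pulse, n),
                  section = rep_len(section, n),
                  stringsAsFactors = FALSE)
  attr(s, "sample_rate") <- fs
  class(s) <- c("gyro_stream", "data.frame")
  s
}

# labelled records where the target simply copies the prev_class feature
copy_task_records <- function(n_patients = 4, n = 120, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_patients), function(p) {
    prev <- sample(0:4, n, replace = TRUE)
    data.frame(patient_id = sprintf("C%02d", p),
               window_index = seq_len(n),
               rms_x = runif(n), rms_y = runif(n), rms_z = runif(n),
               prev_class = prev, target_class = prev,
               stringsAsFactors = FALSE)
  }))
}

# labelled records whose targets are independent of every feature
null_task_records <- function(n_patients = 4, n = 150, seed = 1,
                              prob = c(0.5, 0.2, 0.15, 0.1, 0.05)) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_patients), function(p) {
    data.frame(patient_id = sprintf("N%02d", p),
               window_index = seq_len(n),
               rms_x = runif(n), rms_y = runif(n), rms_z = runif(n),
               prev_class = sample(0:4, n, replace = TRUE),
               target_class = sample(0:4, n, replace = TRUE, prob = prob),
               stringsAsFactors = FALSE)
  }))
}

# a hand-built fold assignment (patient -> fold), bypassing the shuffler
manual_folds <- function(assignment) {
  structure(list(k = max(assignment), assignment = assignment,
                 sizes = as.integer(table(assignment)), seed = NA),
            class = "fold_assignment")
}
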