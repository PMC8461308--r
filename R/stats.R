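#' Paired Wilcoxon signed-rank test
#'
#' Compares paired before/during measurements (e.g. per-axis RMS before
#' versus during stimulation). Zero differences are dropped; with 5-25
#' informative pairs and no tied absolute differences the exact
#' signed-rank distribution is used, otherwise the normal approximation
#' with tie correction. All-zero differences are a flagged degenerate
#' result, not an error.
#'
#' @param x,y Paired numeric vectors (`y` omitted if `x` is already a
#'   vector of differences).
#' @param min_pairs Minimum informative pairs required.
#' @return List with `statistic` (V), `p_value`, `n` (informative pairs),
#'   `exact` (logical), `degenerate` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, min_pairs = 5) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0,
                exact = FALSE, degenerate = TRUE))
  }
  if (n < min_pairs) {
    stop(sprintf("need at least %d non-zero paired differences, got %d",
                 min_pairs, n), call. = FALSE)
  }
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- n <= 25 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = !use_exact)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value, n = n,
       exact = use_exact, degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Rank correlation between two vectors with midranks for ties; the
#' p-value uses the t approximation. A constant input is a flagged
#' undefined result.
#'
#' @param x,y Numeric vectors.
#' @return List with `rho`, `p_value`, `n`, `degenerate`.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                degenerate = TRUE))
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(res$estimate), p_value = res$p.value, n = n,
       degenerate = FALSE)
}

#' Chi-square test for categorical data
#'
#' Thin wrapper over the Pearson chi-square test with an optional Yates
#' continuity correction for 2x2 tables.
#'
#' @param tab A contingency table or matrix.
#' @param yates Apply the continuity correction.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab, yates = FALSE) {
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Stepwise multiple linear regression (p-value entry/removal)
#'
#' Forward-entry, backward-removal stepwise selection in the SPSS style:
#' at each step the candidate with the smallest partial p-value enters if
#' p <= `entry`, then fitted terms with p >= `removal` are removed, until
#' neither rule fires. Perfectly collinear candidates are dropped with a
#' warning.
#'
#' @param data Data frame of the cohort outcomes.
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate predictor names.
#' @param entry Entry significance threshold.
#' @param removal Removal significance threshold.
#' @return A `regression_fit` list: `selected`, `coefficients`, `R`,
#'   `R2`, `model` (the `lm` fit), `steps` (selection log).
#' @export
stepwise_ols <- function(data, outcome, candidates, entry = 0.05,
                         removal = 0.10) {
  if (!outcome %in% names(data)) stop("unknown outcome column", call. = FALSE)
  miss <- setdiff(candidates, names(data))
  if (length(miss)) {
    stop("unknown candidates: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  selected <- character(0)
  remaining <- candidates
  steps <- list()
  term_p <- function(vars, term) {
    fml <- stats::reformulate(vars, response = outcome)
    fit <- stats::lm(fml, data = data)
    ct <- summary(fit)$coefficients
    if (!term %in% rownames(ct)) return(NA_real_)  # collinear: NA coef
    p <- ct[term, "Pr(>|t|)"]
    if (is.nan(p)) p <- 0  # zero residual variance: perfect predictor
    p
  }
  repeat {
    changed <- FALSE
    if (length(remaining)) {
      pvals <- vapply(remaining, function(v) {
        term_p(c(selected, v), v)
      }, numeric(1))
      drop_col <- remaining[is.na(pvals)]
      if (length(drop_col)) {
        warning("dropping collinear candidates: ",
                paste(drop_col, collapse = ", "), call. = FALSE)
        remaining <- setdiff(remaining, drop_col)
        pvals <- pvals[!is.na(pvals)]
      }
      if (length(pvals) && min(pvals) <= entry) {
        add <- names(pvals)[which.min(pvals)]
        selected <- c(selected, add)
        remaining <- setdiff(remaining, add)
        steps[[length(steps) + 1]] <- list(action = "enter", term = add,
                                           p = min(pvals))
        changed <- TRUE
      }
    }
    if (length(selected)) {
      pv <- vapply(selected, function(v) term_p(selected, v), numeric(1))
      if (length(pv) && max(pv) >= removal) {
        rem <- names(pv)[which.max(pv)]
        selected <- setdiff(selected, rem)
        remaining <- c(remaining, rem)
        steps[[length(steps) + 1]] <- list(action = "remove", term = rem,
                                           p = max(pv))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fml <- if (length(selected)) {
    stats::reformulate(selected, response = outcome)
  } else {
    stats::as.formula(paste(outcome, "~ 1"))
  }
  fit <- stats::lm(fml, data = data)
  r2 <- summary(fit)$r.squared
  out <- list(selected = selected,
              coefficients = stats::coef(fit),
              R = sqrt(max(r2, 0)),
              R2 = r2,
              model = fit,
              steps = steps)
  class(out) <- "regression_fit"
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("Stepwise linear regression fit\n")
  cat("  selected:", if (length(x$selected)) {
    paste(x$selected, collapse = ", ")
  } else "(intercept only)", "\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  R = %.3f, R^2 = %.3f\n", x$R, x$R2))
  invisible(x)
}

#' Reference coefficients of the reset-time regression
#'
#' Coefficients of the stepwise linear model relating tremor reset time D
#' (seconds) to the average pulse amplitude E (mA) and stimulation time A
#' (seconds), as estimated on the original 20-patient clinical cohort:
#' `D = -98.336 + 48.559 E + 0.282 A` (multiple correlation 0.712).
#'
#' @return Named numeric vector `(intercept, E, A)`.
#' @export
reference_reset_model <- function() {
  c(intercept = -98.336, E = 48.559, A = 0.282)
}

#' Predict tremor reset time from stimulation parameters
#'
#' Evaluates the linear reset-time model at an average pulse amplitude
#' `E` (mA) and stimulation time `A` (s). Negative predictions are
#' floored at zero and flagged via the `"floored"` attribute.
#'
#' @param E Average pulse amplitude (mA), non-negative.
#' @param A Stimulation time (s), non-negative.
#' @param fit A `regression_fit` whose selected predictors are `E` and
#'   `A`, or a named coefficient vector `(intercept, E, A)`; defaults to
#'   [reference_reset_model()].
#' @return Predicted reset time(s) in seconds.
#' @export
predict_reset_time <- function(E, A, fit = reference_reset_model()) {
  if (any(E < 0) || any(A < 0)) {
    stop("E and A must be non-negative", call. = FALSE)
  }
  if (inherits(fit, "regression_fit")) {
    co <- fit$coefficients
    cf <- c(intercept = unname(co["(Intercept)"]),
            E = unname(co["E"]), A = unname(co["A"]))
  } else {
    cf <- fit
  }
  d <- cf[["intercept"]] + cf[["E"]] * E + cf[["A"]] * A
  floored <- d < 0
  d[floored] <- 0
  attr(d, "floored") <- floored
  d
}

#' Simulate cohort-level stimulation outcomes
#'
#' Generates one row per patient of the cohort-outcome table used by the
#' regression analyses: average pulse amplitude `E`, stimulation time
#' `A`, a reset time `D` generated from the linear reset-time model plus
#' Gaussian noise, and clinical covariates (age, Hoehn-Yahr stage,
#' levodopa-equivalent dose, disease duration, cognitive score) drawn
#' independently of `D` (pure-noise candidates for selection tests).
#' Default parameter scales follow the clinical cohort summaries.
#'
#' @param n Number of patients.
#' @param seed RNG seed.
#' @param coefs Reset-time model coefficients (named `intercept`, `E`,
#'   `A`).
#' @param noise_sd Residual SD of `D` around the linear model (the
#'   default reproduces an R^2 of roughly 0.5 at the cohort's outcome
#'   spread).
#' @return Data frame with columns `patient_id`, `E`, `A`, `D`, `age`,
#'   `hy`, `led`, `duration`, `tmse`.
#' @export
simulate_cohort_outcomes <- function(n = 20, seed = 1,
                                     coefs = reference_reset_model(),
                                     noise_sd = 240) {
  set.seed(seed)
  E <- rtruncnorm(n, 6.25, 2.84, 2.06, 12.95)
  A <- rlnorm_trunc(n, 440.7, 560.82, 42, 2382)
  D <- coefs[["intercept"]] + coefs[["E"]] * E + coefs[["A"]] * A +
    stats::rnorm(n, 0, noise_sd)
  D <- pmax(D, 0)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             E = E, A = A, D = D,
             age = rtruncnorm(n, 63.40, 9.91, 51, 85),
             hy = rtruncnorm(n, 2.53, 0.85, 1, 4),
             led = rtruncnorm(n, 761.20, 329.69, 300, 1759),
             duration = rtruncnorm(n, 8.45, 3.26, 4, 18),
             tmse = rtruncnorm(n, 26.55, 2.80, 21, 30),
             stringsAsFactors = FALSE)
}
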