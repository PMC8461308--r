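#' Specification of a stimulation-class predictor
#'
#' Describes one of the five model families with its hyperparameters,
#' feature set, normalization and seed. Feature normalization (train-set
#' standard scaling) is always on for the margin/gradient-based families
#' (SVM, neural net, LSTM) and off for logistic regression and random
#' forest; a conflicting request is an error.
#'
#' Family defaults: logistic regression uses all inputs with no grid;
#' random forest uses 100 trees, sqrt(p) features per split and bootstrap
#' resampling; SVM uses an RBF kernel with C = 1; the neural net is a
#' two-hidden-layer (100, 100) perceptron with ReLU and Adam; the LSTM is
#' two layers of 100 hidden units with a dense softmax head, Adam at
#' learning rate 0.001.
#'
#' @param family One of `"logistic_regression"`, `"random_forest"`,
#'   `"svm"`, `"neural_net"`, `"lstm"`.
#' @param hyper Named list of family-specific hyperparameters overriding
#'   the defaults.
#' @param feature_set `"gyro_plus_prev"` (RMS x/y/z plus the previous
#'   stimulation class) or `"gyro_only"`.
#' @param normalization `NULL` for the family default, otherwise must
#'   equal it.
#' @param seed RNG seed for training.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family, hyper = list(),
                       feature_set = c("gyro_plus_prev", "gyro_only"),
                       normalization = NULL, seed = 1) {
  family <- match.arg(family, c("logistic_regression", "random_forest",
                                "svm", "neural_net", "lstm"))
  feature_set <- match.arg(feature_set)
  norm_default <- family %in% c("svm", "neural_net", "lstm")
  if (is.null(normalization)) normalization <- norm_default
  if (!identical(normalization, norm_default)) {
    stop(sprintf("normalization must be %s for %s",
                 if (norm_default) "on" else "off", family), call. = FALSE)
  }
  defaults <- switch(family,
    logistic_regression = list(maxit = 200),
    random_forest = list(n_trees = 100, bootstrap = TRUE, min_leaf = 1,
                         criterion = "gini"),
    svm = list(C = 1, kernel = "rbf"),
    neural_net = list(hidden = c(100, 100), activation = "relu",
                      solver = "adam", lr = 1e-3, epochs = 60, batch = 200,
                      alpha = 1e-4),
    lstm = list(hidden = 100, layers = 2, lr = 1e-3, epochs = 30,
                batch = 32, chunk = 60)
  )
  unknown <- setdiff(names(hyper), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameters for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(hyper)] <- hyper
  structure(list(family = family, hyper = defaults,
                 feature_set = feature_set, normalization = normalization,
                 seed = seed),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s (features: %s, normalization: %s, seed %d)\n",
              x$family, x$feature_set, if (x$normalization) "on" else "off",
              x$seed))
  invisible(x)
}

feature_columns <- function(feature_set) {
  if (feature_set == "gyro_plus_prev") {
    c("rms_x", "rms_y", "rms_z", "prev_class")
  } else {
    c("rms_x", "rms_y", "rms_z")
  }
}

feature_matrix <- function(records, feature_set) {
  as.matrix(records[, feature_columns(feature_set), drop = FALSE])
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

records_to_sequences <- function(records, feature_set, scaler) {
  by_pat <- split(records, records$patient_id)
  lapply(by_pat, function(r) {
    r <- r[order(r$window_index), , drop = FALSE]
    list(x = apply_scaler(feature_matrix(r, feature_set), scaler),
         y = r$target_class)
  })
}

#' Fit a stimulation-class predictor on labelled records
#'
#' Trains one model family on the given records. Teacher forcing: the
#' `prev_class` feature carries the observed previous stimulation class.
#' Normalization parameters, where the family requires them, are fitted on
#' the training records only. A single-class training set yields a flagged
#' degenerate constant predictor rather than an error.
#'
#' @param spec A [model_spec()].
#' @param records Labelled records (columns `patient_id`, `window_index`,
#'   `rms_x`, `rms_y`, `rms_z`, `prev_class`, `target_class`).
#' @return A `stim_model` object with `$spec`, `$fit`, `$scaler`,
#'   `$degenerate`.
#' @export
fit_stim_model <- function(spec, records) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(spec$seed)
  y <- records$target_class
  if (length(unique(y)) < 2) {
    return(structure(list(spec = spec, fit = NULL, scaler = NULL,
                          degenerate = TRUE,
                          constant_class = unique(y)[1]),
                     class = "stim_model"))
  }
  x_raw <- feature_matrix(records, spec$feature_set)
  scaler <- if (spec$normalization) fit_scaler(x_raw) else NULL
  x <- apply_scaler(x_raw, scaler)
  h <- spec$hyper
  fit <- switch(spec$family,
    logistic_regression = {
      df <- data.frame(x_raw, y = factor(y))
      nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = h$maxit)
    },
    random_forest = {
      randomForest::randomForest(
        x = x_raw, y = factor(y), ntree = h$n_trees,
        replace = h$bootstrap, nodesize = h$min_leaf)
    },
    svm = {
      kern <- switch(h$kernel, rbf = "radial", poly = "polynomial",
                     linear = "linear", sigmoid = "sigmoid",
                     stop("unknown kernel: ", h$kernel, call. = FALSE))
      e1071::svm(x = x, y = factor(y), kernel = kern,
                 cost = h$C, scale = FALSE)
    },
    neural_net = {
      mlp_fit(x, y, hidden = h$hidden, activation = h$activation,
              solver = h$solver, lr = h$lr, epochs = h$epochs,
              batch = h$batch, alpha = h$alpha, n_classes = 5,
              seed = spec$seed)
    },
    lstm = {
      seqs <- records_to_sequences(records, spec$feature_set, scaler)
      lstm_fit(seqs, hidden = h$hidden, layers = h$layers, n_classes = 5,
               lr = h$lr, epochs = h$epochs, batch = h$batch,
               chunk = h$chunk, seed = spec$seed)
    }
  )
  structure(list(spec = spec, fit = fit, scaler = scaler,
                 degenerate = FALSE, constant_class = NA_integer_),
            class = "stim_model")
}

#' @export
print.stim_model <- function(x, ...) {
  cat(sprintf("Fitted stimulation-class model: %s (%s)%s\n", x$spec$family,
              x$spec$feature_set,
              if (x$degenerate) " [degenerate single-class fit]" else ""))
  invisible(x)
}

#' Predict stimulation classes for labelled records
#'
#' Evaluation mirrors training: the `prev_class` column of `records`
#' supplies the observed previous stimulation level (teacher forcing).
#' LSTM records are assembled into per-patient chronological sequences
#' with the recurrent state carried across each sequence.
#'
#' @param object A `stim_model`.
#' @param newdata Labelled records.
#' @param ... Unused.
#' @return Integer vector of predicted classes (0-4), aligned to
#'   `newdata` rows.
#' @export
predict.stim_model <- function(object, newdata, ...) {
  if (object$degenerate) {
    return(rep(object$constant_class, nrow(newdata)))
  }
  spec <- object$spec
  if (spec$family == "lstm") {
    ord <- order(newdata$patient_id, newdata$window_index)
    res <- integer(nrow(newdata))
    seqs <- split(seq_len(nrow(newdata))[ord],
                  newdata$patient_id[ord])
    for (rows in seqs) {
      x <- apply_scaler(feature_matrix(newdata[rows, , drop = FALSE],
                                       spec$feature_set), object$scaler)
      res[rows] <- predict(object$fit, x)
    }
    return(res)
  }
  x_raw <- feature_matrix(newdata, spec$feature_set)
  x <- apply_scaler(x_raw, object$scaler)
  switch(spec$family,
    logistic_regression = {
      as.integer(as.character(predict(object$fit,
                                      newdata = data.frame(x_raw))))
    },
    random_forest = {
      as.integer(as.character(predict(object$fit, newdata = x_raw)))
    },
    svm = as.integer(as.character(predict(object$fit, newdata = x))),
    neural_net = predict(object$fit, x)
  )
}

# Single-window prediction with explicit previous class, for the
# closed-loop controller (free-running: prev is the model's own previous
# prediction). Returns the class and an updated recurrent state (NULL for
# stateless families).
model_step <- function(model, rms_x, rms_y, rms_z, prev_class,
                       state = NULL) {
  UseMethod("model_step")
}

#' @export
model_step.stim_model <- function(model, rms_x, rms_y, rms_z, prev_class,
                                  state = NULL) {
  spec <- model$spec
  if (model$degenerate) {
    return(list(class = model$constant_class, state = state))
  }
  feats <- c(rms_x = rms_x, rms_y = rms_y, rms_z = rms_z,
             prev_class = prev_class)
  feats <- feats[feature_columns(spec$feature_set)]
  if (spec$family == "lstm") {
    x <- apply_scaler(matrix(feats, nrow = 1,
                             dimnames = list(NULL, names(feats))),
                      model$scaler)
    stp <- lstm_step(model$fit, x, state)
    return(list(class = stp$class, state = stp$state))
  }
  row <- as.data.frame(as.list(feats))
  row$patient_id <- "step"
  row$window_index <- 1L
  list(class = predict(model, row), state = NULL)
}

#' Train on one set of records and evaluate on another
#'
#' Fits the specified model on the training records and predicts the test
#' records; the two sets must be patient-disjoint (grouped evaluation).
#'
#' @param spec A [model_spec()].
#' @param train,test Labelled record data frames.
#' @return List with `model`, `predictions`, `truth`, `confusion`
#'   (5x5 matrix) and `metrics` ([macro_metrics()] output), plus the
#'   `degenerate` flag.
#' @export
train_predict <- function(spec, train, test) {
  overlap <- intersect(unique(train$patient_id), unique(test$patient_id))
  if (length(overlap)) {
    stop("train and test sets share patients: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  model <- fit_stim_model(spec, train)
  pred <- predict(model, test)
  cm <- confusion_matrix(test$target_class, pred)
  list(model = model, predictions = pred, truth = test$target_class,
       confusion = cm, metrics = macro_metrics(cm),
       degenerate = model$degenerate)
}

#' Hyperparameter grids for the searchable families
#'
#' The exhaustive grids searched for random forest (number of trees,
#' bootstrap on/off, split criterion, minimum leaf size: 120 candidates),
#' SVM (C and kernel: 12 candidates) and the neural net (hidden-layer
#' layout, activation, optimizer: 36 candidates). Logistic regression has
#' no grid (all four inputs are always used) and the LSTM is configured
#' manually. Note: the installed forest backend implements only the Gini
#' impurity; candidates requesting the entropy criterion are fitted with
#' Gini and record the requested value.
#'
#' @param family `"random_forest"`, `"svm"` or `"neural_net"`.
#' @return A data frame of hyperparameter candidates (list-columns where
#'   a value is a vector).
#' @export
default_grid <- function(family) {
  switch(match.arg(family, c("random_forest", "svm", "neural_net")),
    random_forest = expand.grid(
      n_trees = c(50, 100, 200, 300, 400, 500),
      bootstrap = c(TRUE, FALSE),
      criterion = c("gini", "entropy"),
      min_leaf = c(2, 5, 10, 20, 30),
      stringsAsFactors = FALSE),
    svm = expand.grid(
      C = c(0.5, 1, 2),
      kernel = c("linear", "poly", "rbf", "sigmoid"),
      stringsAsFactors = FALSE),
    neural_net = {
      g <- expand.grid(
        hidden_id = 1:6,
        activation = c("tanh", "relu"),
        solver = c("lbfgs", "sgd", "adam"),
        stringsAsFactors = FALSE)
      layouts <- list(50, 100, 200, c(50, 50), c(100, 100), c(200, 200))
      g$hidden <- layouts[g$hidden_id]
      g$hidden_id <- NULL
      g
    })
}

grid_row_to_hyper <- function(family, row) {
  h <- as.list(row)
  if (family == "neural_net") h$hidden <- h$hidden[[1]]
  if (family == "random_forest") {
    # backend limitation: entropy not available; fitted with gini
    h$criterion <- NULL
  }
  h
}

#' Exhaustive grid search with an inner patient-wise validation split
#'
#' Enumerates every candidate in the grid, fits it on an inner
#' patient-wise split of the training records (default 2 folds), and
#' selects the candidate with the highest mean inner macro-F1 (ties go to
#' the earlier candidate).
#'
#' @param family `"random_forest"`, `"svm"` or `"neural_net"`.
#' @param grid Candidate data frame, as from [default_grid()].
#' @param train Training records.
#' @param feature_set Passed to [model_spec()].
#' @param inner_k Inner folds for the patient-wise validation split.
#' @param seed Seed (inner fold shuffling and model fits).
#' @return List with `best` (hyperparameter list), `best_index`, and
#'   `results` (the grid with a `macro_f1` column).
#' @export
grid_search <- function(family, grid = default_grid(family), train,
                        feature_set = "gyro_plus_prev", inner_k = 2,
                        seed = 1) {
  if (!nrow(grid)) stop("empty hyperparameter grid", call. = FALSE)
  folds <- grouped_folds(train$patient_id, k = inner_k, seed = seed)
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    h <- grid_row_to_hyper(family, grid[i, , drop = FALSE])
    spec <- model_spec(family, hyper = h, feature_set = feature_set,
                       seed = seed)
    f1s <- vapply(seq_len(inner_k), function(kk) {
      test_pat <- names(folds$assignment)[folds$assignment == kk]
      te <- train[train$patient_id %in% test_pat, , drop = FALSE]
      tr <- train[!train$patient_id %in% test_pat, , drop = FALSE]
      train_predict(spec, tr, te)$metrics$macro_f1
    }, numeric(1))
    scores[i] <- mean(f1s)
  }
  best <- which.max(scores)
  results <- grid
  results$macro_f1 <- scores
  list(best = grid_row_to_hyper(family, grid[best, , drop = FALSE]),
       best_index = best, results = results)
}

#' Patient-wise k-fold cross-validation of a model spec
#'
#' For each fold, trains on the remaining folds and evaluates on the
#' held-out fold's patients, reporting per-fold macro metrics and their
#' mean and SD, plus the pooled confusion matrix and per-class accuracy
#' across folds.
#'
#' @param spec A [model_spec()].
#' @param records Labelled records.
#' @param folds A [grouped_folds()] assignment covering the records'
#'   patients.
#' @return An `eval_report` list: `per_fold` (data frame), `mean`, `sd`,
#'   `pooled_confusion`, `pooled_metrics`, `spec`.
#' @export
cross_validate <- function(spec, records, folds) {
  miss <- setdiff(unique(records$patient_id), names(folds$assignment))
  if (length(miss)) {
    stop("records contain patients not in the fold assignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  per_fold <- vector("list", folds$k)
  pooled <- matrix(0L, 5, 5)
  for (kk in seq_len(folds$k)) {
    test_pat <- names(folds$assignment)[folds$assignment == kk]
    te <- records[records$patient_id %in% test_pat, , drop = FALSE]
    tr <- records[!records$patient_id %in% test_pat, , drop = FALSE]
    if (!nrow(te)) stop("fold ", kk, " has no test records", call. = FALSE)
    res <- train_predict(spec, tr, te)
    pooled <- pooled + res$confusion
    per_fold[[kk]] <- data.frame(fold = kk,
                                 macro_f1 = res$metrics$macro_f1,
                                 macro_precision = res$metrics$macro_precision,
                                 macro_recall = res$metrics$macro_recall,
                                 accuracy = res$metrics$accuracy,
                                 n = res$metrics$n)
  }
  per_fold <- do.call(rbind, per_fold)
  dimnames(pooled) <- dimnames(confusion_matrix(0, 0))
  out <- list(per_fold = per_fold,
              mean = c(macro_f1 = mean(per_fold$macro_f1),
                       accuracy = mean(per_fold$accuracy)),
              sd = c(macro_f1 = stats::sd(per_fold$macro_f1),
                     accuracy = stats::sd(per_fold$accuracy)),
              pooled_confusion = pooled,
              pooled_metrics = macro_metrics(pooled),
              spec = spec)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Patient-wise CV of %s (%s): macro-F1 %.3f +- %.3f, accuracy %.3f +- %.3f\n",
              x$spec$family, x$spec$feature_set,
              x$mean["macro_f1"], x$sd["macro_f1"],
              x$mean["accuracy"], x$sd["accuracy"]))
  invisible(x)
}
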