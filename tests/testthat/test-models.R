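test_that("model specs enforce the per-family normalization convention", {
  expect_true(model_spec("svm")$normalization)
  expect_true(model_spec("lstm")$normalization)
  expect_false(model_spec("random_forest")$normalization)
  expect_error(model_spec("svm", normalization = FALSE), "normalization")
  expect_error(model_spec("logistic_regression", normalization = TRUE),
               "normalization")
  expect_error(model_spec("svm", hyper = list(gamma = 1)), "unknown")
})

test_that("every tabular family solves the prev-class copy task perfectly", {
  recs <- copy_task_records(n_patients = 4, n = 120, seed = 2)
  tr <- recs[recs$patient_id %in% c("C01", "C02", "C03"), ]
  te <- recs[recs$patient_id == "C04", ]
  for (fam in c("logistic_regression", "random_forest", "svm",
                "neural_net")) {
    hyper <- if (fam == "neural_net") {
      list(hidden = c(20, 20), epochs = 150, batch = 60)
    } else {
      list()
    }
    res <- train_predict(model_spec(fam, hyper = hyper, seed = 4), tr, te)
    expect_equal(res$metrics$accuracy, 1,
                 label = paste(fam, "copy-task accuracy"))
  }
})

test_that("the LSTM solves the copy task and is deterministic", {
  recs <- copy_task_records(n_patients = 4, n = 120, seed = 5)
  tr <- recs[recs$patient_id != "C04", ]
  te <- recs[recs$patient_id == "C04", ]
  spec <- model_spec("lstm", hyper = list(hidden = 16, epochs = 150,
                                          lr = 0.01, chunk = 30,
                                          batch = 8), seed = 6)
  res1 <- train_predict(spec, tr, te)
  res2 <- train_predict(spec, tr, te)
  expect_gte(res1$metrics$accuracy, 0.97)
  expect_identical(res1$predictions, res2$predictions)
})

test_that("training is deterministic under a fixed seed", {
  recs <- copy_task_records(n_patients = 4, n = 80, seed = 9)
  tr <- recs[recs$patient_id != "C04", ]
  te <- recs[recs$patient_id == "C04", ]
  for (fam in c("random_forest", "neural_net")) {
    r1 <- train_predict(model_spec(fam, seed = 3), tr, te)
    r2 <- train_predict(model_spec(fam, seed = 3), tr, te)
    expect_identical(r1$predictions, r2$predictions,
                     label = paste(fam, "determinism"))
  }
})

test_that("gyro-only accuracy on feature-independent targets is chance level", {
  recs <- null_task_records(n_patients = 6, n = 200, seed = 12)
  tr <- recs[!recs$patient_id %in% c("N05", "N06"), ]
  te <- recs[recs$patient_id %in% c("N05", "N06"), ]
  res <- train_predict(model_spec("logistic_regression",
                                  feature_set = "gyro_only", seed = 1),
                       tr, te)
  majority <- max(table(te$target_class)) / nrow(te)
  expect_lt(abs(res$metrics$accuracy - majority), 0.08)
})

test_that("patient overlap between train and test is rejected", {
  recs <- copy_task_records(n_patients = 3, n = 30)
  expect_error(train_predict(model_spec("svm"), recs, recs[1:10, ]),
               "share patients")
})

test_that("single-class training data yields a flagged degenerate fit", {
  recs <- copy_task_records(n_patients = 3, n = 40, seed = 1)
  tr <- recs[recs$patient_id != "C03", ]
  tr$target_class <- 2L
  te <- recs[recs$patient_id == "C03", ]
  res <- train_predict(model_spec("svm"), tr, te)
  expect_true(res$degenerate)
  expect_true(all(res$predictions == 2L))
})

test_that("grids match the searchable ranges and a size-1 grid is returned", {
  expect_identical(nrow(default_grid("random_forest")), 120L)  # 6 x 2 x 2 x 5
  expect_identical(nrow(default_grid("svm")), 12L)
  expect_identical(nrow(default_grid("neural_net")), 36L)
  expect_error(default_grid("lstm"))

  recs <- copy_task_records(n_patients = 4, n = 60, seed = 3)
  g1 <- data.frame(C = 2, kernel = "linear", stringsAsFactors = FALSE)
  gs <- grid_search("svm", g1, recs, seed = 2)
  expect_equal(gs$best$C, 2)
  expect_equal(gs$best$kernel, "linear")
  expect_error(grid_search("svm", g1[0, ], recs), "empty")
})

test_that("grid search selects the kernel that separates a planted task", {
  # radial classes: inseparable linearly, trivial for an RBF kernel
  set.seed(31)
  mk <- function(p, n = 150) {
    r <- sqrt(runif(n, 0, 4))
    th <- runif(n, 0, 2 * pi)
    data.frame(patient_id = p, window_index = seq_len(n),
               rms_x = r * cos(th), rms_y = r * sin(th), rms_z = runif(n),
               prev_class = 0L, target_class = as.integer(r > 1),
               stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, lapply(c("A", "B", "C", "D"), mk))
  grid <- expand.grid(C = 1, kernel = c("linear", "rbf"),
                      stringsAsFactors = FALSE)
  gs <- grid_search("svm", grid, recs, feature_set = "gyro_only", seed = 5)
  expect_equal(gs$best$kernel, "rbf")
})

test_that("cross-validation reports fold means, SDs and improvement", {
  recs <- copy_task_records(n_patients = 6, n = 60, seed = 8)
  folds <- grouped_folds(recs$patient_id, k = 3, seed = 1)
  rep1 <- cross_validate(model_spec("random_forest", seed = 2), recs,
                         folds)
  expect_equal(unname(rep1$mean["accuracy"]), 1)
  expect_equal(unname(rep1$sd["accuracy"]), 0)
  expect_identical(nrow(rep1$per_fold), 3L)
  expect_equal(sum(rep1$pooled_confusion), nrow(recs))

  # records from a patient missing in the assignment are rejected
  extra <- recs[1:5, ]
  extra$patient_id <- "ZZZ"
  expect_error(cross_validate(model_spec("svm"), rbind(recs, extra), folds),
               "not in the fold assignment")
})

test_that("adding the prev-class feature helps when targets depend on it", {
  recs <- synthetic_band_cohort(6, 150, seed = 3)
  folds <- grouped_folds(recs$patient_id, k = 3, seed = 2)
  with_prev <- cross_validate(model_spec("logistic_regression",
                                         feature_set = "gyro_plus_prev",
                                         seed = 1), recs, folds)
  gyro_only <- cross_validate(model_spec("logistic_regression",
                                         feature_set = "gyro_only",
                                         seed = 1), recs, folds)
  expect_gt(with_prev$mean["macro_f1"], gyro_only$mean["macro_f1"])
  expect_gt(improvement_pct(gyro_only$mean["macro_f1"],
                            with_prev$mean["macro_f1"]), 0)
})

test_that("MLP solvers all learn a separable task", {
  set.seed(44)
  x <- matrix(rnorm(400), 200, 2)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  for (solver in c("adam", "sgd", "lbfgs")) {
    lr <- if (solver == "sgd") 0.05 else 1e-2
    fit <- mlp_fit(x, y, hidden = 8, activation = "tanh", solver = solver,
                   lr = lr, epochs = 200, batch = 50, n_classes = 2,
                   seed = 2)
    expect_gt(mean(predict(fit, x) == y), 0.95,
              label = paste("mlp", solver))
  }
})
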