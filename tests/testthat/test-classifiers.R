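small_protocol <- function(...) {
  eval_protocol(elm_hidden_grid = c(30, 60), rf_n_trees = 25,
                rf_depth_grid = c(3, 6), svm_c_grid = c(1, 100),
                svm_gamma_grid = c(0.01, 1), cv_folds = 3, ...)
}

test_that("ELM interpolates when hidden units >= samples", {
  set.seed(41)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- factor(sample(c("a", "b", "c"), 20, replace = TRUE))
  m <- elm_train(X, y, n_hidden = 25, seed = 7)
  expect_equal(mean(predict(m, X) == y), 1)

  # contradictory duplicated samples cannot be interpolated
  X2 <- rbind(X[1, ], X[1, ])
  y2 <- factor(c("a", "b"))
  m2 <- elm_train(X2, y2, n_hidden = 10, seed = 7)
  expect_lt(mean(predict(m2, X2) == y2), 1)

  # seed determinism
  m3 <- elm_train(X, y, n_hidden = 25, seed = 7)
  expect_identical(predict(m, X), predict(m3, X))
  expect_error(elm_train(X[1, , drop = FALSE], y[1], 5), "2 samples")
})

test_that("random forest and SVM separate well-separated classes", {
  sep <- separable_data(n_per_class = 25, d = 4, gap = 6, seed = 43)
  rf <- rf_train(sep$X, sep$y, n_trees = 25, max_depth = 4, seed = 1)
  expect_equal(mean(predict(rf, sep$X) == sep$y), 1)
  rf2 <- rf_train(sep$X, sep$y, n_trees = 25, max_depth = 4, seed = 1)
  expect_identical(predict(rf2, sep$X), predict(rf, sep$X))

  sv <- svm_train(sep$X, sep$y, cost = 10, gamma = 0.1)
  expect_equal(mean(predict(sv, sep$X) == sep$y), 1)
  expect_error(svm_train(sep$X, rep("one", 50)), "2 classes")
})

test_that("compute_metrics matches hand-computed confusion cases", {
  y <- factor(c("a", "a", "b", "b"))
  perfect <- compute_metrics(y, y)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  # TP=1, FP=1, FN=1, TN=1 for each class symmetrically
  pred <- factor(c("a", "b", "a", "b"))
  m <- compute_metrics(y, pred)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)

  # a never-predicted class has precision 0, not NaN
  m2 <- compute_metrics(factor(c("a", "b")), factor(c("a", "a")))
  expect_equal(m2$per_class$precision[m2$per_class$class == "b"], 0)
  expect_false(anyNA(unlist(m2[c("accuracy", "precision", "recall", "f1")])))
  expect_error(compute_metrics(y, pred[1:3]), "equal length")
})

test_that("grid search picks from the stated grids and refits", {
  expect_equal(eval_protocol()$elm_hidden_grid, seq(30L, 100L, 10L))
  expect_equal(eval_protocol()$rf_depth_grid, 1:20)
  expect_equal(eval_protocol()$rf_n_trees, 300L)
  expect_equal(eval_protocol()$cv_folds, 5L)
  expect_equal(eval_protocol()$test_fraction, 0.2)

  sep <- separable_data(n_per_class = 15, d = 3, gap = 6, seed = 44)
  proto <- small_protocol()
  for (kind in c("elm", "rf", "svm")) {
    gs <- grid_search_classifier(kind, sep$X, sep$y, proto, seed = 2)
    expect_gte(gs$cv_accuracy, 0.95)
    expect_equal(mean(predict(gs$model, sep$X) == sep$y), 1)
  }
  # grid of size 1 returns that configuration
  p1 <- eval_protocol(elm_hidden_grid = 40L, cv_folds = 3)
  gs1 <- grid_search_classifier("elm", sep$X, sep$y, p1, seed = 2)
  expect_equal(gs1$best_params$n_hidden, 40L)
})

test_that("experiment grid keeps the test partition out of training", {
  g <- generate_seed_spectra(synthetic_spec(n_per_class = 20, d = 20,
                                            n_informative = 5,
                                            effect_size = 0.08, seed = 45))
  proto <- small_protocol()
  res <- run_experiment_grid(
    g$spectra, proto, preprocessors = c("raw", "msc"),
    selectors = list(none = NULL,
                     eiao = selector_spec("eiao", n_pop = 6, max_iter = 6,
                                          seed = 45)),
    classifiers = c("elm", "rf"),
    fitness_cfg = fitness_config(seed = 45), seed = 45)
  expect_s3_class(res, "results_table")
  expect_equal(nrow(res), 2 * 2 * 2)
  metr <- as.matrix(res[, c("train_accuracy", "test_accuracy", "precision",
                            "recall", "f1")])
  expect_true(all(metr >= 0 & metr <= 1))
  # selected masks are applied: column count equals popcount
  masks <- attr(res, "masks")
  expect_lt(sum(masks[["raw-eiao"]]), 20)
  expect_true(all(res$n_selected[res$selector == "none"] == 20))
  # reruns are deterministic
  res2 <- run_experiment_grid(
    g$spectra, proto, preprocessors = c("raw", "msc"),
    selectors = list(none = NULL,
                     eiao = selector_spec("eiao", n_pop = 6, max_iter = 6,
                                          seed = 45)),
    classifiers = c("elm", "rf"),
    fitness_cfg = fitness_config(seed = 45), seed = 45)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})
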