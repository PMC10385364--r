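# Synthetic feature sets for the pipeline tests.
make_toy <- function(n = 120, seed = 2, shift = 3) {
  set.seed(seed)
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n),
             e = rnorm(n), f = rnorm(n), g = rnorm(n), h = rnorm(n))
  y <- rep(c("nonfaller", "faller"), each = n / 2)
  X[y == "faller", "a"] <- X[y == "faller", "a"] + shift
  X[y == "faller", "b"] <- X[y == "faller", "b"] - shift
  list(X = X, y = y)
}

test_that("every fitted pipeline retains at most the feature budget", {
  toy <- make_toy()
  for (mid in c("logistic_regression", "random_forest", "knn", "svm")) {
    fit <- suppressMessages(fit_pipeline(build_pipeline(mid, max_features = 6,
                                                        seed = 1),
                                         toy$X, toy$y))
    expect_lte(length(fit$features), 6, label = mid)
  }
  expect_error(build_pipeline("nonsense"), "valid ids")
})

test_that("standardisation yields mean 0 and SD 1 on the training matrix", {
  toy <- make_toy()
  fit <- suppressMessages(fit_pipeline(build_pipeline("lda", seed = 1),
                                       toy$X, toy$y))
  Xs <- scale(toy$X, center = fit$center, scale = fit$scale)
  expect_equal(colMeans(Xs), rep(0, ncol(Xs)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(Xs, 2, sd), rep(1, ncol(Xs)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("RFE recovers a planted signal pair", {
  hits <- 0L
  n_runs <- 25L
  for (s in seq_len(n_runs)) {
    toy <- make_toy(n = 80, seed = 100 + s, shift = 2.5)
    fit <- suppressMessages(
      fit_pipeline(build_pipeline("logistic_regression", max_features = 2,
                                  seed = s), toy$X, toy$y))
    if (all(c("a", "b") %in% fit$features)) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("all fifteen model families fit and predict both label sets", {
  toy <- make_toy(n = 90)
  set.seed(4)
  y6 <- sample(as.character(1:6), 90, replace = TRUE)
  X6 <- toy$X
  X6[, "a"] <- X6[, "a"] + 2 * as.integer(y6)
  for (mid in MODEL_IDS) {
    fit2 <- suppressMessages(fit_pipeline(build_pipeline(mid, seed = 1),
                                          toy$X, toy$y))
    p2 <- predict_pipeline(fit2, toy$X)
    expect_true(all(p2 %in% toy$y), label = paste(mid, "2-class"))
    expect_gte(accuracy_score(toy$y, p2), 0.8, label = paste(mid, "2-class"))
    fit6 <- suppressMessages(fit_pipeline(build_pipeline(mid, seed = 1),
                                          X6, y6))
    p6 <- predict_pipeline(fit6, X6)
    expect_true(all(p6 %in% y6), label = paste(mid, "6-class"))
  }
})

test_that("the bank report is Table-shaped with metrics in [0, 1]", {
  toy <- make_toy()
  models <- c("logistic_regression", "lda", "decision_tree", "perceptron")
  rep <- suppressWarnings(evaluate_bank(toy$X, toy$y, seed = 9,
                                        models = models,
                                        cv_k = 4, cv_repeats = 1))
  expect_equal(nrow(rep), length(models))
  expect_equal(names(rep), c("model_id", "acc_train", "cv_mean", "acc_test",
                             "g_mean", "f1"))
  metrics <- as.matrix(rep[, -1])
  expect_true(all(metrics >= 0 & metrics <= 1))
  # well-separated classes: strong test accuracy across the board
  expect_true(all(rep$acc_test >= 0.8))
})
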