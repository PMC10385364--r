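# A tiny instance of the full two-branch topology used throughout.
tiny_hyper <- function() {
  nn_config(conv1d_filters = c(3L, 4L), lstm_units = c(5L, 4L),
            branch1_dense = c(6L, 5L), conv2d_filters = c(2L, 3L),
            head_dense = c(6L), dropout = 0)
}

tiny_model <- function(n_classes = 2L, seed = 3) {
  build_model(n_classes, hyper = tiny_hyper(), input_time = 8L,
              input_channels = 2L, img_dim = c(9L, 5L), seed = seed)
}

test_that("backpropagation matches numerical gradients everywhere", {
  m <- tiny_model()
  # nudge all parameters off exact ReLU kinks (zero biases with zero-padded
  # dead inputs put pre-activations exactly at the kink)
  set.seed(5)
  for (nm in names(m$params)) {
    m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]), 0, 0.01)
  }
  set.seed(1)
  B <- 4
  xt <- array(rnorm(B * 8 * 2), c(B, 8, 2))
  xs <- array(rnorm(B * 9 * 5), c(B, 9, 5))
  y <- diag(2)[sample(1:2, B, replace = TRUE), ]
  fw <- tugfall:::nn_forward(m, xt, xs, train = FALSE)
  gr <- tugfall:::nn_backward(m, fw, y)
  lossfn <- function(mm) {
    tugfall:::cross_entropy(tugfall:::nn_forward(mm, xt, xs, FALSE)$probs, y)
  }
  h <- 1e-6
  set.seed(2)
  for (nm in names(m$params)) {
    for (probe in seq_len(min(length(m$params[[nm]]), 4))) {
      i <- sample(length(m$params[[nm]]), 1)
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - h
      num <- (lossfn(mp) - lossfn(mn)) / (2 * h)
      expect_lt(abs(num - gr[[nm]][i]), 1e-6, label = nm)
    }
  }
})

test_that("softmax outputs form a probability simplex for both versions", {
  for (ncl in c(2L, 6L)) {
    m <- build_model(ncl, hyper = tiny_hyper(), input_time = 8L,
                     input_channels = 2L, img_dim = c(9L, 5L), seed = 4)
    expect_equal(ncol(m$params$out_W), ncl)
    set.seed(8)
    fw <- tugfall:::nn_forward(m, array(rnorm(3 * 8 * 2), c(3, 8, 2)),
                               array(rnorm(3 * 9 * 5), c(3, 9, 5)))
    expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-6)
    expect_true(all(fw$probs >= 0))
  }
  expect_error(build_model(4L), "2 or 6")
})

test_that("the published filter counts read back from the default build", {
  m <- build_model(2L, hyper = nn_config(), seed = 1)
  expect_equal(m$spec$hyper$conv1d_filters, c(64L, 128L, 512L, 1024L))
  expect_equal(ncol(m$params$c1_W4), 1024L)
  expect_equal(length(m$spec$hyper$lstm_units), 2L)
  expect_equal(m$spec$hyper$head_dense, c(128L, 64L))
  expect_gt(m$n_params, 1e6)
})

test_that("training reduces the loss and separates easy classes", {
  set.seed(7)
  n <- 96
  labs <- rep(c("lo", "hi"), length.out = n)
  w <- array(0, c(n, 64, 6))
  t64 <- (0:63) / 100
  for (i in 1:n) {
    f <- if (labs[i] == "lo") 1.5 else 3.2
    for (ch in 1:6) {
      w[i, , ch] <- sin(2 * pi * f * t64 + runif(1, 0, 2 * pi)) *
        runif(1, 0.5, 1.5) + rnorm(64, 0, 0.1)
    }
  }
  sp <- spectrogram_batch(w)
  m <- build_model(2L, hyper = nn_config_reduced(), seed = 11)
  m <- train_model(m, w, sp, labs, epochs = 12, seed = 12, early_stop = 0.99)
  expect_true(all(m$history$loss >= 0))
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  expect_gte(tail(m$history$accuracy, 1), 0.9)
  # same seed reproduces the first-epoch loss exactly
  m2 <- build_model(2L, hyper = nn_config_reduced(), seed = 11)
  m2 <- train_model(m2, w, sp, labs, epochs = 1, seed = 12)
  expect_equal(m2$history$loss[1], m$history$loss[1], tolerance = 1e-12)
  # per-window probabilities form a simplex and yield labels
  pr <- predict_windows(m, w, sp)
  expect_equal(rowSums(pr), rep(1, n), tolerance = 1e-6)
  expect_gte(accuracy_score(labs, colnames(pr)[max.col(pr)]), 0.9)
})

test_that("trial prediction equals the brute-force window average", {
  trials <- make_contrast_cohort(n_per_class = 1, seed = 21,
                                 standing_duration = 12)
  cw <- cohort_windows(trials[1], n_classes = 2)
  m <- build_model(2L, hyper = tiny_hyper(), input_time = 64L,
                   input_channels = 6L, img_dim = c(183L, 11L), seed = 2)
  m$classes <- c("faller", "nonfaller")
  pt <- predict_trial(m, trials[[1]])
  manual <- colMeans(predict_windows(m, cw$windows, cw$spectrograms))
  expect_equal(pt$probs, manual, tolerance = 1e-12)
  expect_true(pt$label %in% c("faller", "nonfaller"))
  # single-window input: trial probabilities equal the window's
  one <- cw$windows[1, , , drop = FALSE]
  ones <- cw$spectrograms[1, , , drop = FALSE]
  expect_equal(colMeans(predict_windows(m, one, ones)),
               predict_windows(m, one, ones)[1, ], tolerance = 1e-12)
})

test_that("grid search returns the argmax configuration", {
  set.seed(9)
  n <- 48
  labs <- rep(c("a", "b"), each = n / 2)
  w <- array(rnorm(n * 64 * 6), c(n, 64, 6))
  w[labs == "b", , ] <- w[labs == "b", , ] + 1.5
  sp <- spectrogram_batch(w)
  data <- list(windows = w, spectrograms = sp, labels = labs)
  hyper_base <- nn_config_reduced(conv1d_filters = c(4L, 4L, 4L, 4L),
                                  lstm_units = c(6L, 4L),
                                  branch1_dense = c(8L, 6L, 6L),
                                  conv2d_filters = c(2L, 2L, 2L),
                                  head_dense = c(8L, 6L), epochs = 2L)
  grid <- data.frame(lr = c(1e-3, 1e-2))
  hs <- hyper_search(grid, data, data, n_classes = 2, base = hyper_base,
                     seed = 13)
  expect_equal(nrow(hs$results), 2)
  expect_true(all(hs$results$val_accuracy <= max(hs$results$val_accuracy)))
  expect_equal(hs$best$lr, grid$lr[which.max(hs$results$val_accuracy)])
  # a single-point grid returns that point
  hs1 <- hyper_search(grid[1, , drop = FALSE], data, data, n_classes = 2,
                      base = hyper_base, seed = 13)
  expect_equal(hs1$best$lr, 1e-3)
})
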