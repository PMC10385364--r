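# The feature-based classifier bank: fifteen model families behind a common
# pipeline of standardisation -> recursive feature elimination -> fit.

#' Model families available in the classifier bank
#' @export
MODEL_IDS <- c("logistic_regression", "ridge", "lasso", "knn", "naive_bayes",
               "lda", "decision_tree", "perceptron", "mlp", "sgd",
               "gradient_boosting", "xgboost", "svm", "random_forest",
               "adaboost")

# ---- individual model backends ---------------------------------------------
# Each backend is a list of fit(X, y, seed) -> object,
# predict(object, X) -> character labels, and importance(object) -> named
# numeric vector or NULL (NULL means RFE falls back to a surrogate ranker).

model_backend <- function(model_id) {
  switch(model_id,
    logistic_regression = list(
      fit = function(X, y, seed) {
        df <- data.frame(X)
        df$.y <- factor(y)
        if (nlevels(df$.y) == 2) {
          fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                             family = stats::binomial()))
          list(kind = "glm", fit = fit, levels = levels(df$.y))
        } else {
          fit <- with_seed(seed, nnet::multinom(.y ~ ., data = df,
                                                trace = FALSE, maxit = 300))
          list(kind = "multinom", fit = fit, levels = levels(df$.y))
        }
      },
      predict = function(obj, X) {
        df <- data.frame(X)
        if (obj$kind == "glm") {
          p <- stats::predict(obj$fit, newdata = df, type = "response")
          obj$levels[1 + (p > 0.5)]
        } else {
          as.character(stats::predict(obj$fit, newdata = df))
        }
      },
      importance = function(obj) {
        co <- stats::coef(obj$fit)
        if (is.matrix(co)) colSums(abs(co[, -1, drop = FALSE]))
        else abs(co[-1])
      }
    ),
    ridge = glmnet_backend(alpha = 0, lambda = 0.1),
    lasso = glmnet_backend(alpha = 1, lambda = 0.01),
    knn = list(
      fit = function(X, y, seed) list(X = X, y = factor(y), k = 5),
      predict = function(obj, X) {
        as.character(class::knn(obj$X, X, obj$y, k = obj$k))
      },
      importance = NULL
    ),
    naive_bayes = list(
      fit = function(X, y, seed) e1071::naiveBayes(data.frame(X), factor(y)),
      predict = function(obj, X) as.character(stats::predict(obj, data.frame(X))),
      importance = NULL
    ),
    lda = list(
      fit = function(X, y, seed) suppressWarnings(MASS::lda(X, grouping = factor(y))),
      predict = function(obj, X) as.character(stats::predict(obj, X)$class),
      importance = function(obj) rowSums(abs(obj$scaling))
    ),
    decision_tree = list(
      fit = function(X, y, seed) {
        df <- data.frame(X, .y = factor(y))
        with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class",
                                     control = rpart::rpart.control(cp = 0.01)))
      },
      predict = function(obj, X) {
        as.character(stats::predict(obj, newdata = data.frame(X), type = "class"))
      },
      importance = function(obj) obj$variable.importance
    ),
    perceptron = list(
      fit = function(X, y, seed) fit_perceptron(X, factor(y), seed),
      predict = function(obj, X) predict_linear_ovr(obj, X),
      importance = function(obj) colSums(abs(obj$W))
    ),
    mlp = list(
      fit = function(X, y, seed) {
        f <- factor(y)
        fit <- with_seed(seed, nnet::nnet(X, nnet::class.ind(f), size = 8,
                                          softmax = TRUE, decay = 1e-3,
                                          maxit = 300, trace = FALSE))
        list(fit = fit, levels = levels(f))
      },
      predict = function(obj, X) {
        p <- stats::predict(obj$fit, X)
        obj$levels[max.col(p)]
      },
      importance = NULL
    ),
    sgd = list(
      fit = function(X, y, seed) fit_sgd_hinge(X, factor(y), seed),
      predict = function(obj, X) predict_linear_ovr(obj, X),
      importance = function(obj) colSums(abs(obj$W))
    ),
    gradient_boosting = xgb_backend(eta = 0.1, max_depth = 3, nrounds = 100),
    xgboost = xgb_backend(eta = 0.3, max_depth = 6, nrounds = 50),
    svm = list(
      fit = function(X, y, seed) {
        with_seed(seed, e1071::svm(X, factor(y), kernel = "radial"))
      },
      predict = function(obj, X) as.character(stats::predict(obj, X)),
      importance = NULL
    ),
    random_forest = list(
      fit = function(X, y, seed) {
        with_seed(seed, randomForest::randomForest(X, factor(y), ntree = 300))
      },
      predict = function(obj, X) as.character(stats::predict(obj, X)),
      importance = function(obj) obj$importance[, "MeanDecreaseGini"]
    ),
    adaboost = list(
      fit = function(X, y, seed) fit_adaboost_samme(X, factor(y), seed),
      predict = function(obj, X) predict_adaboost_samme(obj, X),
      importance = function(obj) obj$importance
    ),
    stop("unknown model_id '", model_id, "'; valid ids: ",
         paste(MODEL_IDS, collapse = ", "), call. = FALSE)
  )
}

glmnet_backend <- function(alpha, lambda) {
  list(
    fit = function(X, y, seed) {
      f <- factor(y)
      fam <- if (nlevels(f) > 2) "multinomial" else "binomial"
      fit <- with_seed(seed, glmnet::glmnet(X, f, family = fam, alpha = alpha,
                                            lambda = c(lambda * 10, lambda)))
      list(fit = fit, lambda = lambda, levels = levels(f))
    },
    predict = function(obj, X) {
      as.character(stats::predict(obj$fit, X, s = obj$lambda, type = "class"))
    },
    importance = function(obj) {
      co <- stats::coef(obj$fit, s = obj$lambda)
      if (is.list(co)) {
        vals <- Reduce(`+`, lapply(co, function(m) abs(as.numeric(m[-1, 1]))))
        stats::setNames(vals, rownames(co[[1]])[-1])
      } else {
        stats::setNames(abs(as.numeric(co[-1, 1])), rownames(co)[-1])
      }
    }
  )
}

xgb_backend <- function(eta, max_depth, nrounds) {
  list(
    fit = function(X, y, seed) {
      fit <- xgboost::xgboost(X, factor(y), nrounds = nrounds,
                              max_depth = max_depth, learning_rate = eta,
                              nthreads = 1,
                              seed = as.integer(seed) %% .Machine$integer.max,
                              verbosity = 0)
      list(fit = fit, feature_names = colnames(X))
    },
    predict = function(obj, X) {
      as.character(stats::predict(obj$fit, X, type = "class"))
    },
    importance = function(obj) {
      imp <- xgboost::xgb.importance(model = obj$fit)
      out <- stats::setNames(rep(0, length(obj$feature_names)),
                             obj$feature_names)
      out[imp$Feature] <- imp$Gain
      out
    }
  )
}

# Pocket perceptron, one-vs-rest for more than two classes.
fit_perceptron <- function(X, f, seed, epochs = 50) {
  lv <- levels(f)
  d <- ncol(X)
  W <- matrix(0, length(lv), d, dimnames = list(lv, colnames(X)))
  b <- stats::setNames(numeric(length(lv)), lv)
  with_seed(seed, {
    for (cl in lv) {
      yy <- ifelse(f == cl, 1, -1)
      w <- numeric(d); b0 <- 0
      best <- list(acc = -1, w = w, b = b0)
      for (e in seq_len(epochs)) {
        for (i in sample(nrow(X))) {
          if (yy[i] * (sum(w * X[i, ]) + b0) <= 0) {
            w <- w + yy[i] * X[i, ]
            b0 <- b0 + yy[i]
          }
        }
        acc <- mean(sign(X %*% w + b0) == yy)
        if (acc > best$acc) best <- list(acc = acc, w = w, b = b0)
      }
      W[cl, ] <- best$w
      b[cl] <- best$b
    }
  })
  list(W = W, b = b, levels = lv)
}

# Linear one-vs-rest classifier trained by stochastic gradient descent on
# the hinge loss with L2 regularisation.
fit_sgd_hinge <- function(X, f, seed, epochs = 30, lambda = 1e-3) {
  lv <- levels(f)
  d <- ncol(X)
  W <- matrix(0, length(lv), d, dimnames = list(lv, colnames(X)))
  b <- stats::setNames(numeric(length(lv)), lv)
  with_seed(seed, {
    for (cl in lv) {
      yy <- ifelse(f == cl, 1, -1)
      w <- numeric(d); b0 <- 0; t <- 0
      for (e in seq_len(epochs)) {
        for (i in sample(nrow(X))) {
          t <- t + 1
          lr <- 1 / (lambda * (t + 100))
          margin <- yy[i] * (sum(w * X[i, ]) + b0)
          w <- w * (1 - lr * lambda)
          if (margin < 1) {
            w <- w + lr * yy[i] * X[i, ]
            b0 <- b0 + lr * yy[i]
          }
        }
      }
      W[cl, ] <- w
      b[cl] <- b0
    }
  })
  list(W = W, b = b, levels = lv)
}

predict_linear_ovr <- function(obj, X) {
  scores <- X %*% t(obj$W) + matrix(obj$b, nrow(X), length(obj$b), byrow = TRUE)
  obj$levels[max.col(scores)]
}

# Multiclass AdaBoost (SAMME) over depth-1 rpart stumps.
fit_adaboost_samme <- function(X, f, seed, n_rounds = 50) {
  lv <- levels(f)
  K <- length(lv)
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  df <- data.frame(X, .y = f)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      st <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                        minsplit = 2,
                                                        xval = 0))
      pred <- stats::predict(st, df, type = "class")
      miss <- pred != f
      err <- sum(w[miss]) / sum(w)
      if (err >= 1 - 1 / K || err <= 0) {
        if (err <= 0) {
          stumps[[length(stumps) + 1L]] <- st
          alphas <- c(alphas, 10)
        }
        break
      }
      alpha <- log((1 - err) / err) + log(K - 1)
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
      stumps[[length(stumps) + 1L]] <- st
      alphas <- c(alphas, alpha)
      vi <- st$variable.importance
      if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + alpha * vi
    }
  })
  list(stumps = stumps, alphas = alphas, levels = lv, importance = imp)
}

predict_adaboost_samme <- function(obj, X) {
  df <- data.frame(X)
  votes <- matrix(0, nrow(X), length(obj$levels),
                  dimnames = list(NULL, obj$levels))
  for (m in seq_along(obj$stumps)) {
    pred <- as.character(stats::predict(obj$stumps[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(X)), match(pred, obj$levels))] <-
      votes[cbind(seq_len(nrow(X)), match(pred, obj$levels))] + obj$alphas[m]
  }
  obj$levels[max.col(votes)]
}

# ---- pipeline: standardise -> RFE -> classifier ----------------------------

#' Build a classification pipeline specification
#'
#' Stages: (i) standardisation to per-feature mean 0 / SD 1 (parameters
#' learned on the training split), (ii) recursive feature elimination down
#' to at most `max_features` features, ranking with the model's own
#' importances when it exposes them and with a multinomial-logistic
#' surrogate otherwise (a message notes the fallback), (iii) the classifier.
#'
#' @param model_id One of [MODEL_IDS].
#' @param max_features Feature budget after RFE (default 6).
#' @param seed Integer seed controlling every stochastic stage.
#' @return A `tug_pipeline` specification; fit it with [fit_pipeline()].
#' @export
build_pipeline <- function(model_id, max_features = 6, seed = 1L) {
  backend <- model_backend(model_id)  # validates the id
  structure(list(model_id = model_id, backend = backend,
                 max_features = max_features, seed = seed),
            class = "tug_pipeline")
}

surrogate_importance <- function(X, y, seed) {
  df <- data.frame(X)
  df$.y <- factor(y)
  fit <- with_seed(seed, nnet::multinom(.y ~ ., data = df,
                                        trace = FALSE, decay = 0.01,
                                        maxit = 200))
  co <- stats::coef(fit)
  if (is.matrix(co)) colSums(abs(co[, -1, drop = FALSE])) else abs(co[-1])
}

#' Fit a pipeline on training data
#'
#' @param pipeline From [build_pipeline()].
#' @param X Numeric matrix (rows = measurements, named columns).
#' @param y Labels.
#' @return A fitted `tug_pipeline_fit` with the scaler, the retained
#'   feature set and the fitted model.
#' @export
fit_pipeline <- function(pipeline, X, y) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  features <- colnames(X)
  ranker <- pipeline$backend$importance
  used_surrogate <- is.null(ranker)
  if (used_surrogate) {
    message(sprintf("RFE: '%s' exposes no importances; ranking with a logistic surrogate",
                    pipeline$model_id))
  }
  step <- 0L
  while (length(features) > pipeline$max_features) {
    step <- step + 1L
    Xc <- Xs[, features, drop = FALSE]
    imp <- if (used_surrogate) {
      surrogate_importance(Xc, y, child_seed(pipeline$seed, step))
    } else {
      obj <- pipeline$backend$fit(Xc, y, child_seed(pipeline$seed, step))
      out <- ranker(obj)
      if (is.null(names(out))) names(out) <- colnames(Xc)[seq_along(out)]
      full <- stats::setNames(rep(0, length(features)), features)
      out <- out[names(out) %in% features]
      full[names(out)] <- out
      full
    }
    features <- setdiff(features, names(which.min(imp[features])))
  }
  model <- pipeline$backend$fit(Xs[, features, drop = FALSE], y,
                                child_seed(pipeline$seed, 9999))
  structure(list(pipeline = pipeline, center = ctr, scale = scl,
                 features = features, model = model,
                 levels = sort(unique(as.character(y)))),
            class = "tug_pipeline_fit")
}

#' Predict labels with a fitted pipeline
#' @param fit From [fit_pipeline()].
#' @param X Feature matrix with the original columns.
#' @return Character labels.
#' @export
predict_pipeline <- function(fit, X) {
  X <- as.matrix(X)
  Xs <- scale(X, center = fit$center, scale = fit$scale)
  fit$pipeline$backend$predict(fit$model, Xs[, fit$features, drop = FALSE])
}

# ---- bank evaluation -------------------------------------------------------

#' Evaluate the classifier bank
#'
#' For each model family: fit the pipeline on the stratified training
#' split, run repeated stratified k-fold cross-validation inside the
#' training split, and report training accuracy, CV mean, test accuracy,
#' G-mean and F1 (Table-2-shaped, one row per model).
#'
#' @param X Feature matrix (named columns, rows = measurements).
#' @param y Labels (2-class or 6-class).
#' @param seed Integer seed.
#' @param models Model ids to evaluate (default all 15).
#' @param test_fraction,cv_k,cv_repeats,max_features Evaluation scheme
#'   (defaults: 80/20 split, 10 x 10 CV, 6 features).
#' @param groups Optional participant ids for a group-aware split.
#' @param path Optional CSV output path.
#' @return Data frame with columns `model_id, acc_train, cv_mean, acc_test,
#'   g_mean, f1` (metrics in `[0, 1]`; a failed model yields NAs and a
#'   warning, the bank continues).
#' @export
evaluate_bank <- function(X, y, seed = 1L, models = MODEL_IDS,
                          test_fraction = 0.2, cv_k = 10, cv_repeats = 10,
                          max_features = 6, groups = NULL, path = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  sp <- stratified_split(y, test_fraction, seed, groups = groups)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]

  rows <- lapply(models, function(mid) {
    res <- tryCatch({
      pl <- build_pipeline(mid, max_features = max_features, seed = seed)
      fit <- suppressMessages(fit_pipeline(pl, Xtr, ytr))
      cv <- suppressMessages(suppressWarnings(repeated_stratified_cv(
        Xtr, ytr,
        fit_predict = function(Xa, ya, Xb, s) {
          p <- build_pipeline(mid, max_features = max_features, seed = s)
          predict_pipeline(fit_pipeline(p, Xa, ya), Xb)
        },
        k = cv_k, repeats = cv_repeats, seed = child_seed(seed, 77))))
      pred_tr <- predict_pipeline(fit, Xtr)
      pred_te <- predict_pipeline(fit, Xte)
      data.frame(model_id = mid,
                 acc_train = accuracy_score(ytr, pred_tr),
                 cv_mean = cv$cv_mean,
                 acc_test = accuracy_score(yte, pred_te),
                 g_mean = geometric_mean_score(yte, pred_te),
                 f1 = f1_report(yte, pred_te),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("model '%s' failed: %s", mid, conditionMessage(e)),
              call. = FALSE)
      data.frame(model_id = mid, acc_train = NA_real_, cv_mean = NA_real_,
                 acc_test = NA_real_, g_mean = NA_real_, f1 = NA_real_,
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
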