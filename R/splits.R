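# Stratified data splitting and repeated stratified k-fold cross-validation.

#' Stratified train/test split
#'
#' Splits measurement rows into train and test with class proportions
#' preserved within rounding. With `groups` supplied, whole participants
#' (all their repetitions) are assigned to the same side, stratified by the
#' participant's class.
#'
#' @param y Class labels (one per row).
#' @param test_fraction Fraction assigned to the test set (default 0.2).
#' @param seed Integer seed (same seed, same split).
#' @param groups Optional participant ids of the same length as `y` for a
#'   group-aware split.
#' @return List with integer row indices `train` and `test`.
#' @export
stratified_split <- function(y, test_fraction = 0.2, seed = 1L, groups = NULL) {
  y <- as.character(y)
  if (any(table(y) < 2)) {
    stop("every class needs at least 2 members to stratify", call. = FALSE)
  }
  if (is.null(groups)) {
    test <- with_seed(seed, {
      unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        n_test <- max(1L, round(test_fraction * length(idx)))
        sample(idx, n_test)
      }), use.names = FALSE)
    })
  } else {
    groups <- as.character(groups)
    glab <- vapply(split(y, groups), function(v) v[1], "")
    gids <- names(glab)
    test_g <- with_seed(seed, {
      unlist(lapply(unique(glab), function(cl) {
        idx <- gids[glab == cl]
        n_test <- max(1L, round(test_fraction * length(idx)))
        sample(idx, n_test)
      }), use.names = FALSE)
    })
    test <- which(groups %in% test_g)
  }
  list(train = sort(setdiff(seq_along(y), test)), test = sort(test))
}

# Stratified k folds: class indices are shuffled and dealt round-robin, so
# every fold's class proportions match the full set within one sample.
make_stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation accuracy
#'
#' Performs exactly `k * repeats` fold evaluations (10 x 10 = 100 by
#' default) of a model-fitting function and returns the mean accuracy.
#'
#' @param X Feature matrix (rows = measurements).
#' @param y Labels.
#' @param fit_predict Function `(X_train, y_train, X_test, seed)` returning
#'   predicted labels for `X_test`.
#' @param k Folds per repeat (default 10); reduced with a warning when the
#'   smallest class has fewer than `k` members.
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed.
#' @return List with `cv_mean`, `fold_accuracies` (length k*repeats), and
#'   the `k` actually used.
#' @export
repeated_stratified_cv <- function(X, y, fit_predict, k = 10, repeats = 10,
                                   seed = 1L) {
  y <- as.character(y)
  min_class <- min(table(y))
  if (min_class < k) {
    k <- max(2L, as.integer(min_class))
    warning(sprintf("smallest class has %d members; k reduced to %d",
                    min_class, k))
  }
  accs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- make_stratified_folds(y, k, child_seed(seed, r))
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      pred <- fit_predict(X[tr, , drop = FALSE], y[tr],
                          X[te, , drop = FALSE],
                          child_seed(seed, r * 1000 + f))
      accs <- c(accs, accuracy_score(y[te], pred))
    }
  }
  list(cv_mean = mean(accs), fold_accuracies = accs, k = k)
}
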