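# Classification metrics. Labels are compared as characters so factor and
# character inputs mix safely.

#' Classification accuracy
#' @param y_true,y_pred Equal-length label vectors.
#' @return Fraction correct in [0, 1].
#' @export
accuracy_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  mean(as.character(y_true) == as.character(y_pred))
}

#' Geometric mean of per-class recalls
#'
#' The multiclass G-mean: the geometric mean of the recall of every class
#' present in `y_true`. A class that is never predicted correctly
#' contributes a zero factor, so the G-mean is 0.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Value in [0, 1].
#' @export
geometric_mean_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  yt <- as.character(y_true); yp <- as.character(y_pred)
  classes <- unique(yt)
  recalls <- vapply(classes, function(cl) mean(yp[yt == cl] == cl), 0)
  exp(mean(log(pmax(recalls, 0))))
}

#' F1 score
#'
#' Binary problems: the standard F1 on the positive class (the "faller"
#' class when present, else the second level). Problems with more than two
#' classes: macro-averaged F1 over the classes present in `y_true`
#' (classes with no predicted instances contribute an F1 of 0).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive Positive class for the binary case (default "faller"
#'   when present).
#' @return Value in [0, 1].
#' @export
f1_report <- function(y_true, y_pred, positive = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  yt <- as.character(y_true); yp <- as.character(y_pred)
  classes <- sort(unique(yt))
  f1_one <- function(cl) {
    tp <- sum(yt == cl & yp == cl)
    fp <- sum(yt != cl & yp == cl)
    fn <- sum(yt == cl & yp != cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }
  if (length(classes) <= 2) {
    pos <- positive %||% if ("faller" %in% classes) "faller" else classes[length(classes)]
    f1_one(pos)
  } else {
    mean(vapply(classes, f1_one, 0))
  }
}

#' F1 from precision and recall
#' @param precision,recall Values in [0, 1].
#' @return Harmonic mean `2 p r / (p + r)` (0 when both are 0).
#' @export
f1_from_pr <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}
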