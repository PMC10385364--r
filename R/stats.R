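# Reliability and group-difference statistics: two-way random-effects
# intraclass correlation for test-retest reliability across the three
# repetitions, pooled-variance t-tests between fallers and nonfallers, and
# the distributional assumption checks that licence them.

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Computes ICC(2,1) (single measure) and ICC(2,k) (average of the k
#' repetitions) from the mean squares of the two-way subject x repetition
#' ANOVA:
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with `MSR` the between-subject, `MSC` the between-repetition and `MSE`
#' the residual mean square. The 95% confidence interval for the single
#' measure uses the F-based approximation of Shrout & Fleiss.
#'
#' @param table n x k numeric matrix: n subjects (rows) by k repetitions
#'   (columns), no missing cells.
#' @param alpha Significance level for the confidence interval.
#' @return An `icc_result` list: `icc` (single-measure), `icc_k` (average
#'   measure), `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `ci95`.
#' @export
icc_2_1 <- function(table, alpha = 0.05) {
  m <- as.matrix(table)
  if (any(!is.finite(m))) stop("ICC table must be complete (no missing cells)", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC needs at least 2 subjects and 2 repetitions", call. = FALSE)
  if (stats::var(as.vector(m)) < .Machine$double.eps) {
    stop("ICC undefined: table has zero variance", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icc_k <- (msr - mse) / (msr + (msc - mse) / n)

  # Shrout-Fleiss F-based interval for the single-measure coefficient.
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = icc, icc_k = icc_k, ms_rows = msr, ms_cols = msc,
                 ms_error = mse, n = n, k = k,
                 ci95 = c(lower = lower, upper = upper)),
            class = "icc_result")
}

#' Between-groups Student t-test (pooled variance)
#'
#' @param a,b Numeric vectors, the two groups (each of length >= 2).
#' @return List with `t`, `p` (two-sided), `df`, and the group means.
#' @export
group_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values", call. = FALSE)
  sp <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp < .Machine$double.eps) stop("zero pooled variance", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk per group and Levene's test (mean-centred) across groups;
#' a feature is flagged as meeting parametric assumptions when every
#' p-value exceeds `alpha`.
#'
#' @param values Numeric vector.
#' @param group_labels Factor/character of the same length.
#' @param alpha Significance level for the flag (default 0.05).
#' @return List with `shapiro_p` (named per group), `levene_p`, and
#'   `parametric_ok`. Groups smaller than 3 are flagged and skipped.
#' @export
assumption_checks <- function(values, group_labels, alpha = 0.05) {
  g <- factor(group_labels)
  sizes <- table(g)
  if (any(sizes < 3)) {
    return(list(shapiro_p = NULL, levene_p = NA_real_, parametric_ok = NA,
                skipped = TRUE))
  }
  shapiro_p <- vapply(levels(g), function(lv) {
    stats::shapiro.test(values[g == lv])$p.value
  }, 0)
  lev <- car::leveneTest(values ~ g, center = mean)
  levene_p <- lev[["Pr(>F)"]][1]
  list(shapiro_p = shapiro_p, levene_p = levene_p,
       parametric_ok = all(c(shapiro_p, levene_p) > alpha),
       skipped = FALSE)
}

#' Per-feature reliability and group-difference report
#'
#' For each of the ten features: mean (SD) per group and overall, the
#' faller-vs-nonfaller pooled t-test (computed on per-participant averages
#' over repetitions), the assumption checks, and both ICC forms across
#' repetitions.
#'
#' @param features Cohort feature table from [extract_cohort_features()].
#' @param path Optional CSV path to write the report to.
#' @return Data frame, one row per feature.
#' @export
reliability_report <- function(features, path = NULL) {
  stopifnot(all(FEATURE_NAMES %in% names(features)))
  rows <- lapply(FEATURE_NAMES, function(fn) {
    # per-participant averages over repetitions (the unit of inference)
    agg <- stats::aggregate(features[[fn]],
                            by = list(id = features$participant_id,
                                      label2 = features$label2),
                            FUN = mean)
    a <- agg$x[agg$label2 == "nonfaller"]
    b <- agg$x[agg$label2 == "faller"]
    tt <- tryCatch(group_ttest(a, b), error = function(e) list(t = NA, p = NA))
    chk <- assumption_checks(agg$x, agg$label2)

    # repetition table for the ICC (only participants with all reps)
    wide <- stats::reshape(features[, c("participant_id", "repetition", fn)],
                           idvar = "participant_id", timevar = "repetition",
                           direction = "wide")
    cc <- wide[stats::complete.cases(wide), -1, drop = FALSE]
    icc <- if (nrow(cc) >= 2 && ncol(cc) >= 2) {
      tryCatch(icc_2_1(cc), error = function(e) NULL)
    }
    data.frame(
      feature = fn,
      mean_nonfaller = mean(a), sd_nonfaller = stats::sd(a),
      mean_faller = mean(b), sd_faller = stats::sd(b),
      mean_total = mean(agg$x), sd_total = stats::sd(agg$x),
      t = tt$t, p = tt$p,
      shapiro_min_p = if (isTRUE(chk$skipped)) NA else min(chk$shapiro_p),
      levene_p = chk$levene_p,
      icc21 = if (is.null(icc)) NA else icc$icc,
      icc2k = if (is.null(icc)) NA else icc$icc_k,
      icc_ci_lower = if (is.null(icc)) NA else icc$ci95[["lower"]],
      icc_ci_upper = if (is.null(icc)) NA else icc$ci95[["upper"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
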