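test_that("ICC(2,1) matches a brute-force two-way ANOVA oracle", {
  for (s in 1:8) {
    set.seed(s)
    m <- matrix(rnorm(18), 6, 3) + rnorm(6)  # subject effects
    r <- icc_2_1(m)
    # oracle: explicit sums of squares
    grand <- mean(m)
    ssr <- 3 * sum((rowMeans(m) - grand)^2)
    ssc <- 6 * sum((colMeans(m) - grand)^2)
    sse <- sum((m - grand)^2) - ssr - ssc
    msr <- ssr / 5; msc <- ssc / 2; mse <- sse / 10
    icc_oracle <- (msr - mse) / (msr + 2 * mse + (3 / 6) * (msc - mse))
    expect_equal(r$icc, icc_oracle, tolerance = 1e-10)
    # the mean squares also agree with stats::aov
    df <- data.frame(v = as.vector(m), subj = factor(rep(1:6, 3)),
                     rep = factor(rep(1:3, each = 6)))
    tab <- summary(stats::aov(v ~ subj + rep, data = df))[[1]]
    expect_equal(r$ms_rows, tab["subj", "Mean Sq"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(r$ms_error, tab["Residuals", "Mean Sq"], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("ICC degenerate and invariance properties hold", {
  # rows differ, repetitions identical: perfect agreement
  m <- matrix(rep(1:5, 3), 5, 3)
  expect_equal(icc_2_1(m)$icc, 1)
  # constant table is undefined
  expect_error(icc_2_1(matrix(2, 4, 3)), "zero variance")
  # adding a constant to every cell changes nothing
  set.seed(3)
  m2 <- matrix(rnorm(24), 8, 3) + rnorm(8)
  expect_equal(icc_2_1(m2)$icc, icc_2_1(m2 + 100)$icc, tolerance = 1e-12)
  # confidence bounds are ordered and bracket the estimate
  r <- icc_2_1(m2)
  expect_lt(r$ci95[["lower"]], r$ci95[["upper"]])
  expect_gte(r$icc, r$ci95[["lower"]])
  expect_lte(r$icc, r$ci95[["upper"]])
})

test_that("null tables give ICC near zero on average", {
  iccs <- vapply(1:400, function(s) {
    set.seed(s + 5000)
    icc_2_1(matrix(rnorm(18), 6, 3))$icc
  }, 0)
  expect_lt(abs(mean(iccs)), 0.05)
})

test_that("pooled t-test matches the textbook formula and quadrature", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- group_ttest(a, b)
  sp <- sqrt(((2) * stats::var(a) + (2) * stats::var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  # p by numerical integration of the t density with 4 df
  dens <- function(x) stats::dt(x, df = 4)
  p_quad <- 2 * stats::integrate(dens, abs(t_hand), Inf)$value
  expect_equal(r$p, p_quad, tolerance = 1e-6)
  # antisymmetry under group swap
  expect_equal(group_ttest(b, a)$t, -r$t, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  r0 <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_error(group_ttest(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("Levene test holds its type-I error under the null", {
  rej <- vapply(1:500, function(s) {
    set.seed(s)
    v <- stats::rnorm(40)
    g <- rep(c("a", "b"), each = 20)
    assumption_checks(v, g)$levene_p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Shapiro-Wilk detects strong skew and passes Gaussian data", {
  power <- mean(vapply(1:60, function(s) {
    set.seed(s)
    stats::shapiro.test(stats::rexp(50))$p.value < 0.05
  }, TRUE))
  expect_gte(power, 0.95)
  chk <- assumption_checks(c(stats::rnorm(30), stats::rnorm(30, 1)),
                           rep(c("a", "b"), each = 30))
  expect_false(chk$skipped)
  expect_length(chk$shapiro_p, 2)
  # undersized groups are skipped, not mangled
  expect_true(assumption_checks(1:4, c("a", "a", "b", "b"))$skipped)
})

test_that("reliability report has one complete row per feature", {
  trials <- make_cohort(8, 2, class_mix = c(0.25, 0.25, 0, 0, 0.25, 0.25),
                        seed = 3)
  ft <- suppressWarnings(extract_cohort_features(trials))
  rep <- reliability_report(ft)
  expect_equal(rep$feature, FEATURE_NAMES)
  expect_true(all(is.finite(rep$icc21)))
  expect_true(all(rep$icc21 > -1 & rep$icc21 <= 1))
  expect_true(all(is.finite(rep$t)))
})
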