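rate <- 100

test_that("resampling is the identity on uniform input and exact on ramps", {
  tt <- seq(0, 5, by = 0.01)
  tr <- structure(list(time = tt,
                       acc = cbind(a = tt, b = sin(tt), c = tt^0),
                       gyr = cbind(0 * tt, 0 * tt, 0 * tt),
                       meta = NULL, truth = NULL), class = "imu_trial")
  u <- resample_uniform(tr, rate)
  expect_equal(u$acc[, "a"], tt, tolerance = 1e-12)
  expect_equal(diff(u$time), rep(0.01, length(tt) - 1), tolerance = 1e-12)

  # irregular sampling of an affine signal reconstructs exactly
  set.seed(1)
  ti <- sort(runif(300, 0, 5))
  tri <- structure(list(time = ti, acc = cbind(ti, 2 * ti + 1, 0 * ti),
                        gyr = cbind(0 * ti, 0 * ti, 0 * ti),
                        meta = NULL, truth = NULL), class = "imu_trial")
  ui <- resample_uniform(tri, rate)
  expect_equal(ui$acc[, 1], ui$time + ti[1], tolerance = 1e-10)

  # duplicate timestamps are rejected
  bad <- tri; bad$time[5] <- bad$time[4]
  expect_error(resample_uniform(bad, rate), "strictly increasing")
})

test_that("zero-lag filter matches the analytic Butterworth cascade response", {
  tt <- seq(0, 20, by = 1 / rate)
  expect_equal(lowpass_zero_lag(rep(2.5, 500), rate), rep(2.5, 500),
               tolerance = 1e-9)
  # steady-state amplitude via projection onto the probe frequency
  measure_gain <- function(f) {
    y <- lowpass_zero_lag(sin(2 * pi * f * tt), rate)
    mid <- 500:1500
    2 * abs(sum(y[mid] * exp(-2i * pi * f * tt[mid]))) / length(mid)
  }
  expect_equal(measure_gain(5), butterworth_cascade_gain(5), tolerance = 0.01)
  expect_equal(measure_gain(30), butterworth_cascade_gain(30), tolerance = 0.01)
  # cross-check against an independent recursive implementation where the
  # bilinear design still matches the analog prototype (well below Nyquist)
  bf <- signal::butter(4, 20 / (rate / 2), type = "low")
  y_ref <- signal::filtfilt(bf, sin(2 * pi * 5 * tt))
  mid <- 500:1500
  g_ref <- 2 * abs(sum(y_ref[mid] * exp(-2i * pi * 5 * tt[mid]))) / length(mid)
  expect_equal(measure_gain(5), g_ref, tolerance = 0.01)
  # zero lag: cross-correlation peak of a band-limited probe at lag 0
  x <- sin(2 * pi * 8 * tt)
  y <- lowpass_zero_lag(x, rate)
  cc <- stats::ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("low-pass never amplifies any probe frequency", {
  tt <- seq(0, 10, by = 1 / rate)
  for (f in c(1, 5, 10, 15, 20, 25, 35, 45)) {
    y <- lowpass_zero_lag(sin(2 * pi * f * tt), rate)
    expect_lte(max(abs(y[200:800])), 1 + 1e-6)
  }
})

test_that("frequency-domain double integration inverts a known sinusoid", {
  expect_equal(double_integrate_fft(numeric(2000), rate, 0.3), numeric(2000))
  tt <- seq(0, 20 - 1 / rate, by = 1 / rate)
  a <- sin(2 * pi * 1 * tt)
  d <- double_integrate_fft(a, rate, 0.3)
  expect_equal(max(abs(d)), 1000 / (2 * pi)^2, tolerance = 0.02)
  # linearity to machine precision
  expect_equal(double_integrate_fft(3.7 * a, rate, 0.3), 3.7 * d,
               tolerance = 1e-9)
  expect_error(double_integrate_fft(a, rate, 60), "Nyquist")
})

test_that("spectral integration agrees with a time-domain integrator", {
  # band-limited test signal with no content below the cutoff; cosine
  # carriers over whole periods are orthogonal to both the constant and
  # the linear term, so the oracle's detrend is exact
  tt <- seq(0, 20 - 1 / rate, by = 1 / rate)
  a <- cos(2 * pi * 1.2 * tt) + 0.5 * cos(2 * pi * 3.1 * tt)
  d_fft <- double_integrate_fft(a, rate, 0.3)
  # brute force: cumulative trapezoidal integration twice, then remove the
  # linear trend the free constants introduce
  v <- cumsum((a + c(a[1], a[-length(a)])) / 2) / rate
  x <- cumsum((v + c(v[1], v[-length(v)])) / 2) / rate
  fit <- stats::lm.fit(cbind(1, tt), x)
  d_time <- (x - cbind(1, tt) %*% fit$coefficients) * 1000
  mid <- 200:1800
  expect_lt(max(abs(d_fft[mid] - d_time[mid])) / max(abs(d_fft[mid])), 0.02)
})
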