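rate <- 100

make_uniform <- function(acc, gyr) {
  structure(list(rate = rate, time = (seq_len(nrow(acc)) - 1) / rate,
                 acc = acc, gyr = gyr, meta = NULL, truth = NULL),
            class = "uniform_trial")
}

test_that("stationary upright sensor keeps roll and pitch at zero", {
  n <- 500
  u <- make_uniform(cbind(0, 9.81, 0)[rep(1, n), ], matrix(0, n, 3))
  o <- estimate_orientation(u)
  after2s <- u$time >= 2
  expect_lt(max(abs(o$euler[after2s, "roll"])) * 180 / pi, 0.5)
  expect_lt(max(abs(o$euler[after2s, "pitch"])) * 180 / pi, 0.5)
  expect_equal(sqrt(rowSums(o$quaternions^2)), rep(1, n), tolerance = 1e-9)
})

test_that("a 10 degree static pitch is recovered from gravity geometry", {
  n <- 500
  ang <- 10 * pi / 180
  # pitch about the ML axis tips gravity into the device AP axis
  acc <- cbind(0, 9.81 * cos(ang), 9.81 * sin(ang))[rep(1, n), ]
  o <- estimate_orientation(make_uniform(acc, matrix(0, n, 3)))
  expect_equal(unname(abs(o$euler[n, "pitch"])) * 180 / pi, 10,
               tolerance = 0.05)
})

test_that("pure constant yaw rate integrates to yaw(t) = w t", {
  n <- 1000
  w <- 0.5
  acc <- cbind(0, 9.81, 0)[rep(1, n), ]
  gyr <- cbind(0, w, 0)[rep(1, n), ]  # device y = vertical
  o <- estimate_orientation(make_uniform(acc, gyr))
  tt <- (seq_len(n) - 1) / rate
  yaw <- tugfall:::unwrap_angle(o$euler[, "yaw"])
  expect_equal(yaw[n], w * tt[n], tolerance = 1e-3)
})

test_that("world-frame linear acceleration removes gravity and preserves norms", {
  tr <- static_trial()
  pre <- preprocess_trial(tr)
  standing <- pre$uniform$time <= 10
  expect_lt(max(abs(pre$acc_world[standing, ])), 1e-6)
  # rotation preserves the vector norm sample by sample
  aw <- pre$acc_world
  aw[, "v"] <- aw[, "v"] + 9.81
  n_dev <- sqrt(rowSums(pre$uniform$acc^2))
  expect_equal(sqrt(rowSums(aw^2)), n_dev, tolerance = 1e-9)
})

test_that("known rotation with known linear acceleration is inverted", {
  n <- 800
  tt <- (seq_len(n) - 1) / rate
  # yaw stays zero over the first second, where the world AP axis is
  # anchored to the mean heading
  yaw <- 0.4 * sin(2 * pi * 0.2 * pmax(tt - 1.5, 0))
  yaw_rate <- c(0, diff(yaw)) * rate
  a_ap <- 0.6 * sin(2 * pi * 1.3 * tt)
  # device acceleration: world AP rotated by yaw, gravity on the vertical
  acc <- cbind(-sin(yaw) * a_ap, 9.81, cos(yaw) * a_ap)
  gyr <- cbind(0, yaw_rate, 0)
  u <- make_uniform(acc, gyr)
  # with the exact orientation the inversion is essentially perfect
  q_exact <- cbind(cos(yaw / 2), 0, 0, sin(yaw / 2))
  o_exact <- structure(list(quaternions = q_exact,
                            euler = cbind(roll = 0, pitch = 0, yaw = yaw),
                            rate = rate,
                            axes = c(ml = 1L, v = 2L, ap = 3L)),
                       class = "orientation_track")
  aw0 <- world_linear_acceleration(u, o_exact)
  expect_lt(max(abs(aw0[, "ap"] - a_ap)), 1e-6)
  expect_lt(max(abs(aw0[, "v"])), 1e-6)
  # the estimated orientation admits a small complementary-filter leak
  o <- estimate_orientation(u)
  aw <- world_linear_acceleration(u, o)
  mid <- 100:(n - 100)
  expect_lt(max(abs(aw[mid, "ap"] - a_ap[mid])), 0.05)
  expect_lt(max(abs(aw[mid, "v"])), 0.05)
})
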