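rate <- 100

test_that("transition power follows m g dh / dt exactly", {
  tt <- seq(0, 10, by = 1 / rate)
  disp <- 1000 * (-0.25) * tugfall:::smootherstep((tt - 4) / 1.5)  # mm
  com_v <- list(time = tt, disp = disp)
  p <- transition_power(com_v, mass = 70, interval = c(4, 5.5))
  expect_equal(p, 70 * 9.81 * 0.25 / 1.5, tolerance = 1e-9)
  expect_equal(p, 114.45, tolerance = 1e-4)
  # zero excursion gives zero power
  expect_equal(transition_power(list(time = tt, disp = disp * 0),
                                mass = 70, interval = c(4, 5.5)), 0)
  # same excursion over half the time doubles the power: a faster step
  # completing inside both intervals
  fast <- 1000 * (-0.25) * tugfall:::smootherstep((tt - 4) / 0.5)
  cv <- list(time = tt, disp = fast)
  expect_equal(transition_power(cv, 70, c(4, 4.75)) /
                 transition_power(cv, 70, c(4, 5.5)),
               2, tolerance = 1e-9)
  expect_error(transition_power(com_v, 70, c(5, 5)), "degenerate")
})

test_that("jerk range matches the analytic derivative of a sinusoid", {
  tt <- seq(0, 10, by = 1 / rate)
  expect_equal(jerk_range(rep(3.3, length(tt)), c(1, 9), rate), 0)
  a <- 2 * sin(2 * pi * 1 * tt)
  jr <- jerk_range(a, c(1, 9), rate)
  expect_equal(jr, 8 * pi, tolerance = 0.02)
  # discretisation error of the central difference against the analytic
  # cosine derivative
  j_num <- (a[3:length(a)] - a[1:(length(a) - 2)]) * rate / 2
  j_ana <- 4 * pi * cos(2 * pi * 1 * tt[2:(length(tt) - 1)])
  expect_lt(max(abs(j_num - j_ana)) / (4 * pi), 0.01)
})

test_that("balance displacement reproduces the quantile of a pure sinusoid", {
  tt <- seq(0, 30, by = 1 / rate)
  D <- 12  # mm sensor-level amplitude
  f <- 0.6
  acc_ap <- -(2 * pi * f)^2 * (D / 1000) * sin(2 * pi * f * tt)
  aw <- cbind(ap = acc_ap, ml = 0 * tt, v = 0 * tt)
  unit_pend <- pendulum_model(0.5, 0.5)  # unit scaling
  bal <- balance_displacement(aw, rate, c(0, 30), pendulum = unit_pend)
  # oracle: empirical 90th percentile of |sin| on a dense grid
  q_sin <- as.numeric(stats::quantile(abs(sin(seq(0, 2 * pi, length.out = 1e5))), 0.9))
  expect_equal(bal[["APDisp"]], D * q_sin, tolerance = 0.03)
  expect_lt(bal[["MLDisp"]], 0.2)
  # doubling the sway acceleration doubles the statistic
  bal2 <- balance_displacement(aw * 2, rate, c(0, 30), pendulum = unit_pend)
  expect_equal(bal2[["APDisp"]] / bal[["APDisp"]], 2, tolerance = 0.01)
})

test_that("time features are plain arithmetic on the phase times", {
  ph <- structure(list(t0 = 0, audio_time = 30, t1 = 30.9, t2 = 35.9,
                       t3 = 37.9, t4 = 39.9, t5 = 41.9, t6 = 43.4,
                       t7 = 44.9, t8 = 49.9), class = "phase_times")
  expect_equal(reaction_time(ph), 0.9)
  expect_equal(total_time(ph), 5 + 5 + 2 + 1.5)
  expect_lt(total_time(ph), ph$t8 - ph$t0)
  ph$t1 <- ph$audio_time
  expect_equal(reaction_time(ph), 0)
})

test_that("gait excursion is invariant to a phase shift of the oscillation", {
  tt <- seq(0, 14, by = 1 / rate)
  one <- function(phase) {
    w <- tugfall:::cos_window(tt, 3, 9, 0.5, 0.5)
    x_v <- 0.012 * sin(2 * pi * 1.8 * tt + phase) * w
    aw <- cbind(ap = 0 * tt, ml = 0 * tt,
                v = tugfall:::central_diff2(x_v, rate))
    gait_excursion(aw, rate, list(c(3, 9)))[["VRange"]]
  }
  expect_equal(one(0), 24, tolerance = 0.5)
  expect_equal(one(0), one(1.1), tolerance = 0.25)
})

test_that("full extraction recovers the designed features of a clean trial", {
  cl <- clean_trial()
  truth <- cl$trial$truth$features
  for (nm in setdiff(names(truth), c("Reaction_Time", "Total_Time"))) {
    expect_lt(relerr(cl$feats[[nm]], truth[[nm]]), 0.05, label = nm)
  }
  expect_lt(abs(cl$feats$Reaction_Time - truth[["Reaction_Time"]]), 0.1)
  expect_lt(abs(cl$feats$Total_Time - truth[["Total_Time"]]), 0.1)
  # determinism of the full chain
  again <- extract_features(cl$trial)
  expect_identical(as.numeric(cl$feats[1, ]), as.numeric(again[1, ]))
})

test_that("body mass scales only the power features", {
  cl <- clean_trial()
  heavier <- cl$trial
  heavier$meta <- participant_meta("P1", mass = 140, height = 1.65, label6 = 3)
  f2 <- extract_features(heavier)
  expect_equal(f2$PTurnSit / cl$feats$PTurnSit, 2, tolerance = 1e-9)
  expect_equal(f2$PStand / cl$feats$PStand, 2, tolerance = 1e-9)
  for (nm in setdiff(FEATURE_NAMES, c("PTurnSit", "PStand"))) {
    expect_equal(f2[[nm]], cl$feats[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("risk-level trends run in the designed direction", {
  # higher designed risk -> longer reaction and total times
  rts <- tts <- numeric(3)
  lvls <- c(1, 3, 6)
  for (i in seq_along(lvls)) {
    tr <- simulate_trial(level_profile(lvls[i], noise_sd = 0),
                         participant_meta("P", 70, 1.65, label6 = lvls[i]),
                         seed = 100 + i)
    f <- extract_features(tr)
    rts[i] <- f$Reaction_Time
    tts[i] <- f$Total_Time
  }
  expect_true(all(diff(rts) > 0))
  expect_true(all(diff(tts) > 0))
})
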