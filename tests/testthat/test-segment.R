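test_that("all nine instants of a clean trial are recovered within 0.1 s", {
  cl <- clean_trial()
  ph <- cl$phases
  truth <- cl$trial$truth$phases
  for (nm in names(truth)) {
    expect_lt(abs(ph[[nm]] - truth[[nm]]), 0.1, label = nm)
  }
  expect_s3_class(ph, "phase_times")
})

test_that("recovered phases always satisfy the ordering invariant", {
  for (s in c(11, 22, 33)) {
    lv <- (s %% 6) + 1
    tr <- simulate_trial(level_profile(lv),
                         participant_meta("P", 70, 1.65, label6 = lv),
                         seed = s)
    pre <- preprocess_trial(tr)
    ph <- segment_phases(pre$uniform, pre$orient, pre$acc_world)
    expect_silent(validate_phase_times(ph, t_end = max(pre$uniform$time)))
  }
  # a scrambled ordering is rejected, naming the offending pair
  bad <- clean_trial()$phases
  bad$t4 <- bad$t3 - 0.5
  expect_error(validate_phase_times(bad), "t3")
})

test_that("gait onset search never fires before the cue and honours truth", {
  cl <- clean_trial()
  t1 <- detect_gait_onset(cl$pre$acc_world, 30, 100)
  expect_gte(t1, 30)
  expect_lt(abs(t1 - cl$trial$truth$phases$t1), 0.1)
})

test_that("noise-only standing produces no spurious onset at k_sd = 4", {
  # trials that never start walking: standing noise all the way through
  for (s in 1:20) {
    n <- 4500
    set.seed(s * 31)
    acc_world <- cbind(ap = rnorm(n, 0, 0.05), ml = rnorm(n, 0, 0.05),
                       v = rnorm(n, 0, 0.05))
    acc_world <- apply(acc_world, 2, lowpass_zero_lag, rate = 100)
    colnames(acc_world) <- c("ap", "ml", "v")
    expect_error(detect_gait_onset(acc_world, 30, 100, k_sd = 4),
                 "no gait detected", label = paste("seed", s))
  }
})

test_that("the peak yaw rate sits at the scripted mid-turn instant", {
  cl <- clean_trial()
  yaw <- tugfall:::unwrap_angle(cl$pre$orient$euler[, "yaw"])
  yr <- abs(c(0, diff(yaw))) * 100
  t_peak <- cl$pre$uniform$time[which.max(yr)]
  expect_equal(t_peak, cl$trial$truth$turn_mid, tolerance = 0.011)
  # and the full turn comes out at ~180 degrees
  expect_equal(abs(yaw[length(yaw)]), pi, tolerance = 0.01)
})

test_that("segmentation degrades gracefully under sensor noise", {
  ok <- 0L
  n_trials <- 12L
  for (s in seq_len(n_trials)) {
    lv <- (s %% 6) + 1
    tr <- simulate_trial(level_profile(lv, noise_sd = 0.1),
                         participant_meta("P", 70, 1.65, label6 = lv),
                         seed = s * 13)
    pre <- preprocess_trial(tr)
    ph <- tryCatch(segment_phases(pre$uniform, pre$orient, pre$acc_world),
                   error = function(e) NULL)
    if (!is.null(ph)) {
      err <- max(abs(vapply(names(tr$truth$phases),
                            function(nm) ph[[nm]] - tr$truth$phases[[nm]], 0)))
      if (err <= 0.2) ok <- ok + 1L
    }
  }
  expect_gte(ok, n_trials - 1L)
})
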