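test_that("identical profile, meta and seed give bitwise-identical trials", {
  prof <- level_profile(2)
  meta <- participant_meta("P1", 70, 1.65, label6 = 2)
  a <- simulate_trial(prof, meta, seed = 7)
  b <- simulate_trial(prof, meta, seed = 7)
  expect_identical(a$acc, b$acc)
  expect_identical(a$gyr, b$gyr)
  expect_identical(a$time, b$time)
  c <- simulate_trial(prof, meta, seed = 8)
  expect_false(identical(a$acc, c$acc))
})

test_that("zero-excitation trial reads pure gravity on the device vertical", {
  tr <- static_trial()
  standing <- tr$time <= 10
  expect_equal(max(abs(tr$acc[standing, "acc_y"] - 9.81)), 0, tolerance = 1e-9)
  expect_equal(max(abs(tr$acc[standing, c("acc_x", "acc_z")])), 0,
               tolerance = 1e-9)
  # gravity norm invariant over standing
  norms <- sqrt(rowSums(tr$acc[standing, ]^2))
  expect_equal(mean(norms), 9.81, tolerance = 1e-9)
})

test_that("scripted quantities pass straight through to the truth", {
  prof <- level_profile(1, noise_sd = 0)
  prof$reaction_latency <- 0.8
  meta <- participant_meta("P1", 70, 1.65, label6 = 1)
  tr <- simulate_trial(do.call(risk_profile, unclass(prof)), meta, seed = 3)
  expect_equal(tr$truth$phases$t1 - tr$truth$phases$audio_time, 0.8)
  expect_equal(tr$truth$features[["Reaction_Time"]], 0.8)
  # designed vertical excursion is twice the oscillation amplitude
  expect_equal(tr$truth$features[["VRange"]], 2 * prof$gait_v_amp,
               tolerance = 0.02)
  expect_equal(tr$truth$features[["Total_Time"]],
               2 * prof$walk_duration + prof$transition_dt_sit +
                 prof$transition_dt_stand)
})

test_that("cohort generation yields participants x repetitions trials", {
  trials <- make_cohort(6, 2, seed = 1)
  expect_length(trials, 12)
  ids <- vapply(trials, function(t) t$meta$id, "")
  reps <- vapply(trials, function(t) t$meta$repetition, 0L)
  expect_equal(length(unique(ids)), 6)
  expect_true(all(table(ids) == 2))
  # one risk level per participant across repetitions
  lv <- tapply(vapply(trials, function(t) t$meta$label6, 0L), ids,
               function(v) length(unique(v)))
  expect_true(all(lv == 1))
  # degenerate single-trial cohort
  one <- make_cohort(1, 1, class_mix = c(1, 0, 0, 0, 0, 0), seed = 2)
  expect_length(one, 1)
})

test_that("class mix is allocated by largest remainder", {
  trials <- make_cohort(60, 1, class_mix = rep(1 / 6, 6), seed = 4)
  lv <- vapply(trials, function(t) t$meta$label6, 0L)
  expect_equal(unname(table(lv)), rep(10L, 6), ignore_attr = TRUE)
  # uneven mix still sums to the cohort size
  trials2 <- make_cohort(7, 1, class_mix = c(.4, .3, .1, .1, .05, .05), seed = 4)
  expect_length(trials2, 7)
})

test_that("timestamp jitter preserves monotonicity and is seeded", {
  tr <- static_trial()
  expect_identical(jitter_timestamps(tr, 0), tr)
  j1 <- jitter_timestamps(tr, 0.002, seed = 9)
  j2 <- jitter_timestamps(tr, 0.002, seed = 9)
  expect_identical(j1$time, j2$time)
  expect_true(all(diff(j1$time) > 0))
  expect_equal(nrow(j1$acc), length(j1$time))
})
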