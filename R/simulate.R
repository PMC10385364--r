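# Smooth building blocks for the scripted trial. All are C2-continuous so
# that acceleration (the second derivative of position) is continuous and
# free of spectral artefacts.

# Quintic smooth step: 0 -> 1 over u in [0, 1], zero first and second
# derivative at both ends.
smootherstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  6 * u^5 - 15 * u^4 + 10 * u^3
}

# Raised-cosine on/off window: 0 before `on`, ramps up over `ramp_on`,
# 1 inside, ramps down to 0 ending exactly at `off`.
cos_window <- function(t, on, off, ramp_on = 0.25, ramp_off = 0.25) {
  w <- numeric(length(t))
  up <- t >= on & t < on + ramp_on
  w[up] <- sin(pi * (t[up] - on) / (2 * ramp_on))^2
  mid <- t >= on + ramp_on & t <= off - ramp_off
  w[mid] <- 1
  down <- t > off - ramp_off & t <= off
  w[down] <- cos(pi * (t[down] - (off - ramp_off)) / (2 * ramp_off))^2
  w
}

# Second derivative of a sampled track by the central difference, with
# one-sided copies at the ends (tracks are quiescent there).
central_diff2 <- function(x, rate) {
  n <- length(x)
  a <- numeric(n)
  a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * rate^2
  a[1] <- a[2]
  a[n] <- a[n - 1]
  a
}

#' Simulate one modified Timed Up and Go trial
#'
#' Generates a six-channel inertial recording of the scripted protocol:
#' quiet standing (default 30 s) with sinusoid-plus-noise sway, an audio cue,
#' gait onset after the profile's reaction latency, a 3 m walking bout with
#' oscillatory gait, a 2 s pause, a 180 degree yaw turn merged with a
#' downward sit transition, a 2 s pause, an upward stand transition, and the
#' return walking bout. Gravity (9.81 m/s^2) is projected onto the device
#' axes throughout; by default the device is worn with x = medial-lateral,
#' y = vertical, z = anterior-posterior.
#'
#' The designed world-frame displacement tracks are built from closed-form
#' smooth primitives, differentiated to acceleration, rotated into the
#' device frame by the scripted yaw, and perturbed by white noise. The
#' returned `truth` element carries the exact scripted phase times and the
#' feature values implied by the designed noiseless tracks, so downstream
#' stages can be validated by parameter recovery.
#'
#' @param profile A [risk_profile()].
#' @param meta A [participant_meta()].
#' @param seed Integer seed; identical inputs give bitwise-identical trials.
#' @param rate Sampling rate in Hz (default 100).
#' @return An `imu_trial`: list with `time` (s), `acc` and `gyr` (N x 3,
#'   columns `*_x`, `*_y`, `*_z` in device axes, SI units), `meta`, and
#'   `truth` (list with `phases` and `features`).
#' @export
simulate_trial <- function(profile, meta, seed = 1L, rate = 100) {
  if (!inherits(profile, "risk_profile")) profile <- do.call(risk_profile, profile)
  if (!inherits(meta, "participant_meta")) stop("`meta` must be a participant_meta", call. = FALSE)
  p <- profile
  dt <- 1 / rate

  # Scripted phase instants.
  t0 <- 0
  audio <- p$standing_duration
  t1 <- audio + p$reaction_latency
  t2 <- t1 + p$walk_duration
  t3 <- t2 + p$pause_duration
  t4 <- t3 + p$transition_dt_sit
  t5 <- t4 + p$pause_duration
  t6 <- t5 + p$transition_dt_stand
  t7 <- t6 + p$stand_walk_gap
  t8 <- t7 + p$walk_duration
  t_end <- t8 + 1.5
  tt <- seq(0, t_end, by = dt)
  n <- length(tt)

  with_seed(seed, {
    ph <- stats::runif(4, 0, 2 * pi)  # sway phases (AP1, AP2, ML1, ML2)

    # --- designed world-frame displacement (m): x = AP, y = ML, z = V (up)
    f1 <- p$sway_freq
    f2 <- p$sway_freq * p$sway_freq2_mult
    # Sway is present through quiet standing and fades gently shortly
    # before the audio cue (anticipatory stiffening before gait
    # initiation), so the post-cue baseline is still.
    sway_w <- numeric(n)
    sway_w[tt <= audio - 1.5] <- 1
    ramp <- tt > audio - 1.5 & tt < audio - 0.5
    sway_w[ramp] <- cos(pi * (tt[ramp] - (audio - 1.5)) / 2)^2
    a_ap1 <- p$sway_amp_ap / 1000
    a_ml1 <- p$sway_amp_ml / 1000
    x_ap <- (a_ap1 * sin(2 * pi * f1 * tt + ph[1]) +
             a_ap1 * p$sway_amp2_frac * sin(2 * pi * f2 * tt + ph[2])) * sway_w
    x_ml <- (a_ml1 * sin(2 * pi * f1 * tt + ph[3]) +
             a_ml1 * p$sway_amp2_frac * sin(2 * pi * f2 * tt + ph[4])) * sway_w
    x_v <- numeric(n)

    # walking bouts: oscillation + 3 m forward translation (out, then back)
    gait_bout <- function(on, off) {
      w <- cos_window(tt, on, off, ramp_on = 0.15, ramp_off = 0.25)
      # The medial-lateral stride sway builds up and dies away over about a
      # second (gentle ramps also keep its spectrum concentrated at the
      # stride frequency).
      rml <- min(1, (off - on) / 3)
      w_ml <- cos_window(tt, on, off, ramp_on = rml, ramp_off = rml)
      tl <- tt - on
      list(
        v  = p$gait_v_amp / 1000 * sin(2 * pi * p$step_freq * tl) * w,
        ml = p$gait_ml_amp / 1000 * sin(2 * pi * p$step_freq / 2 * tl) * w_ml,
        ap = p$gait_ap_amp / 1000 * sin(2 * pi * p$step_freq * tl) * w
      )
    }
    b1 <- gait_bout(t1, t2)
    b2 <- gait_bout(t7, t8)
    transl <- 3 * smootherstep((tt - t1) / p$walk_duration) -
              3 * smootherstep((tt - t7) / p$walk_duration)
    x_ap <- x_ap + b1$ap + b2$ap + transl
    x_ml <- x_ml + b1$ml + b2$ml
    x_v <- x_v + b1$v + b2$v

    # sit and stand vertical transitions (quintic steps)
    x_v <- x_v - p$transition_dh * smootherstep((tt - t3) / p$transition_dt_sit) +
                 p$transition_dh * smootherstep((tt - t5) / p$transition_dt_stand)

    # scripted yaw: 180 degree turn at the start of the turn-and-sit phase
    yaw <- pi * smootherstep((tt - t3) / p$turn_duration)
    yaw_rate <- c(0, diff(yaw)) * rate

    # --- designed world-frame linear acceleration
    acc_ap <- central_diff2(x_ap, rate)
    acc_ml <- central_diff2(x_ml, rate)
    acc_v <- central_diff2(x_v, rate)

    # AP bursts during the transitions (Hann-windowed oscillation), defined
    # at acceleration level; they drive the jerk features.
    ap_burst <- function(on, off, amp) {
      w <- numeric(n)
      inside <- tt >= on & tt <= off
      w[inside] <- sin(pi * (tt[inside] - on) / (off - on))^2
      amp * sin(2 * pi * p$trans_ap_freq * (tt - on)) * w
    }
    acc_ap <- acc_ap + ap_burst(t3, t4, p$trans_ap_amp_sit) +
                       ap_burst(t5, t6, p$trans_ap_amp_stand)

    # --- ground-truth features from the designed noiseless tracks
    pend_scale <- 0.55 / 0.53  # CoM over sensor height fraction (defaults)
    standing <- tt >= t0 & tt <= audio
    q90 <- function(v) as.numeric(stats::quantile(abs(v), 0.9)) * 1000
    in_int <- function(a, b) tt >= a & tt <= b
    rng <- function(v, idx) max(v[idx]) - min(v[idx])
    jerk <- function(a) {
      m <- length(a)
      (a[c(2:m, m)] - a[c(1, 1:(m - 1))]) * rate / 2
    }
    jerk_ap <- jerk(acc_ap)
    truth_features <- c(
      MLDisp = q90(x_ml[standing] * pend_scale),
      APDisp = q90(x_ap[standing] * pend_scale),
      VRange = 1000 * mean(c(rng(x_v, in_int(t1, t2)), rng(x_v, in_int(t7, t8)))),
      MLRange = 1000 * mean(c(rng(x_ml, in_int(t1, t2)), rng(x_ml, in_int(t7, t8)))),
      PTurnSit = meta$mass * GRAVITY * rng(x_v, in_int(t3, t4)) / p$transition_dt_sit,
      PStand = meta$mass * GRAVITY * rng(x_v, in_int(t5, t6)) / p$transition_dt_stand,
      APJerkSit = rng(jerk_ap, in_int(t3, t4)),
      APJerkStand = rng(jerk_ap, in_int(t5, t6)),
      Reaction_Time = p$reaction_latency,
      Total_Time = 2 * p$walk_duration + p$transition_dt_sit + p$transition_dt_stand
    )

    # --- device-frame signals: rotate world AP/ML by the scripted yaw,
    # add gravity along the device vertical, then map (AP, ML, V) onto the
    # device axes x = ML, y = V, z = AP.
    cy <- cos(yaw); sy <- sin(yaw)
    f_ap <- cy * acc_ap + sy * acc_ml
    f_ml <- -sy * acc_ap + cy * acc_ml
    f_v <- acc_v + GRAVITY
    acc <- cbind(acc_x = f_ml, acc_y = f_v, acc_z = f_ap)
    gyr <- cbind(gyr_x = 0, gyr_y = yaw_rate, gyr_z = 0)
    if (p$noise_sd > 0) {
      acc <- acc + matrix(stats::rnorm(3 * n, 0, p$noise_sd), n, 3)
      gyr <- gyr + matrix(stats::rnorm(3 * n, 0, p$noise_sd * 0.05), n, 3)
    }

    structure(list(
      time = tt, acc = acc, gyr = gyr, meta = meta,
      truth = list(
        phases = list(t0 = t0, audio_time = audio, t1 = t1, t2 = t2, t3 = t3,
                      t4 = t4, t5 = t5, t6 = t6, t7 = t7, t8 = t8),
        features = truth_features,
        turn_mid = t3 + p$turn_duration / 2
      ),
      profile = p
    ), class = "imu_trial")
  })
}

#' Perturb trial timestamps
#'
#' Adds Gaussian jitter to the timestamps, re-sorts them and removes
#' duplicates (dropping the corresponding samples), leaving the channel
#' values untouched. Used to exercise the resampling stage.
#'
#' @param trial An `imu_trial`.
#' @param jitter_sd Jitter SD in seconds (0 returns the trial unchanged).
#' @param seed Integer seed.
#' @return An `imu_trial` with strictly increasing timestamps.
#' @export
jitter_timestamps <- function(trial, jitter_sd, seed = 1L) {
  stopifnot_scalar_pos(jitter_sd, "jitter_sd", strict = FALSE)
  if (jitter_sd == 0) return(trial)
  with_seed(seed, {
    ts <- trial$time + stats::rnorm(length(trial$time), 0, jitter_sd)
    ord <- order(ts)
    ts <- ts[ord]
    keep <- c(TRUE, diff(ts) > 0)
    trial$time <- ts[keep]
    trial$acc <- trial$acc[ord, , drop = FALSE][keep, , drop = FALSE]
    trial$gyr <- trial$gyr[ord, , drop = FALSE][keep, , drop = FALSE]
    trial
  })
}

#' Generate a synthetic cohort of modified TUG trials
#'
#' Allocates participants to the six ordinal risk levels by largest-remainder
#' rounding of `class_mix`, draws a per-participant profile around the
#' level's mean profile (a shared multiplicative random effect, so that a
#' participant's repetitions are correlated and test-retest reliability is
#' positive), and simulates `reps` trials per participant with small
#' repetition-to-repetition variation.
#'
#' @param n_participants Number of participants (>= 1).
#' @param reps Repetitions per participant (>= 1).
#' @param class_mix Proportions over the six levels (summing to 1).
#' @param seed Integer seed.
#' @param participant_cv Between-participant coefficient of variation of the
#'   profile parameters within a level (default 0.05, about one third of the
#'   spacing between adjacent level means).
#' @param rep_cv Repetition-to-repetition coefficient of variation
#'   (default 0.03).
#' @param noise_sd Optional accelerometer noise override applied to every
#'   level (e.g. 0 for noise-free cohorts).
#' @param rate Sampling rate in Hz.
#' @return List of `imu_trial` objects (length `n_participants * reps`).
#' @export
make_cohort <- function(n_participants, reps = 3,
                        class_mix = rep(1 / 6, 6), seed = 1L,
                        participant_cv = 0.05, rep_cv = 0.03,
                        noise_sd = NULL, rate = 100) {
  if (n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  if (length(class_mix) != 6 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    stop("`class_mix` must be 6 non-negative proportions summing to 1", call. = FALSE)
  }
  counts <- largest_remainder(class_mix * n_participants)
  if (n_participants >= 6 && any(class_mix > 0 & counts == 0)) {
    warning("some risk levels with positive mix received no participants")
  }
  levels6 <- rep(1:6, counts)

  jittered <- c("sway_amp_ap", "sway_amp_ml", "gait_v_amp", "gait_ml_amp",
                "gait_ap_amp", "walk_duration", "reaction_latency",
                "transition_dh", "transition_dt_sit", "transition_dt_stand",
                "trans_ap_amp_sit", "trans_ap_amp_stand")
  freqs <- c("sway_freq", "step_freq")

  trials <- vector("list", n_participants * reps)
  k <- 0L
  for (i in seq_len(n_participants)) {
    lv <- levels6[i]
    base <- level_profile(lv, noise_sd = noise_sd)
    pseed <- child_seed(seed, i)
    pdraw <- with_seed(pseed, {
      list(fac = pmax(0.6, 1 + stats::rnorm(length(jittered), 0, participant_cv)),
           ffac = pmax(0.8, 1 + stats::rnorm(length(freqs), 0, participant_cv / 2)),
           mass = max(45, stats::rnorm(1, 76, 12)),
           height = min(1.95, max(1.4, stats::rnorm(1, 1.62, 0.08))))
    })
    for (r in seq_len(reps)) {
      rseed <- child_seed(pseed, 1000 + r)
      rfac <- with_seed(rseed, pmax(0.6, 1 + stats::rnorm(length(jittered), 0, rep_cv)))
      prof <- unclass(base)
      for (j in seq_along(jittered)) {
        prof[[jittered[j]]] <- prof[[jittered[j]]] * pdraw$fac[j] * rfac[j]
      }
      for (j in seq_along(freqs)) {
        prof[[freqs[j]]] <- prof[[freqs[j]]] * pdraw$ffac[j]
      }
      prof$turn_duration <- min(prof$turn_duration,
                                0.8 * prof$transition_dt_sit)
      meta <- participant_meta(sprintf("P%03d", i), mass = pdraw$mass,
                               height = pdraw$height, repetition = r,
                               label6 = lv)
      k <- k + 1L
      trials[[k]] <- simulate_trial(do.call(risk_profile, prof), meta,
                                    seed = child_seed(rseed, 7), rate = rate)
    }
  }
  trials
}

# Largest-remainder rounding of non-negative reals to integers preserving
# the (rounded) total.
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  short <- round(sum(x)) - sum(fl)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

#' Cohort with class contrast in frequency content only
#'
#' Generates a two-class cohort whose classes share the same movement
#' amplitudes, excursions, transition durations and latencies (so the ten
#' extracted features carry almost no class signal) but differ in sway and
#' step frequency, which changes the raw acceleration waveforms strongly
#' (acceleration scales with the squared frequency). This isolates the
#' advantage of classifiers that read the raw signals over classifiers
#' limited to the extracted features.
#'
#' @param n_per_class Participants per class.
#' @param seed Integer seed.
#' @param reps Repetitions per participant.
#' @param standing_duration Quiet-standing length (s); shortened from the
#'   protocol's 30 s to keep simulation light, still above the 10 s the
#'   balance feature requires.
#' @param noise_sd Accelerometer noise SD (m/s^2).
#' @return List of `imu_trial` objects; class A participants are labelled
#'   nonfaller (level 2), class B faller (level 5).
#' @export
make_contrast_cohort <- function(n_per_class = 15, seed = 1L, reps = 1,
                                 standing_duration = 12, noise_sd = 0.03) {
  base <- list(sway_amp_ap = 15, sway_amp_ml = 5,
               gait_v_amp = 13, gait_ml_amp = 24, gait_ap_amp = 11,
               walk_duration = 4, reaction_latency = 0.9,
               transition_dh = 0.25, transition_dt_sit = 1.6,
               transition_dt_stand = 1.4, trans_ap_amp_sit = 1.2,
               trans_ap_amp_stand = 1.5, noise_sd = noise_sd,
               standing_duration = standing_duration)
  # transition bursts differ in frequency with amplitude scaled to keep
  # the jerk range (~ amp x freq) equal across classes
  freqs <- list(A = list(sway_freq = 0.35, step_freq = 1.5,
                         trans_ap_freq = 1.0, trans_scale = 1.3 / 1.0),
                B = list(sway_freq = 0.6, step_freq = 2.1,
                         trans_ap_freq = 1.69, trans_scale = 1.3 / 1.69))
  labels6 <- c(A = 2L, B = 5L)
  trials <- list()
  k <- 0L
  for (cl in c("A", "B")) {
    for (i in seq_len(n_per_class)) {
      pseed <- child_seed(seed, (cl == "B") * 1000 + i)
      fac <- with_seed(pseed, pmax(0.7, 1 + stats::rnorm(4, 0, 0.04)))
      prof <- base
      prof$sway_freq <- freqs[[cl]]$sway_freq
      prof$step_freq <- freqs[[cl]]$step_freq
      prof$trans_ap_freq <- freqs[[cl]]$trans_ap_freq
      prof$trans_ap_amp_sit <- base$trans_ap_amp_sit * freqs[[cl]]$trans_scale
      prof$trans_ap_amp_stand <- base$trans_ap_amp_stand * freqs[[cl]]$trans_scale
      prof$walk_duration <- base$walk_duration * fac[1]
      prof$reaction_latency <- base$reaction_latency * fac[2]
      prof$gait_v_amp <- base$gait_v_amp * fac[3]
      prof$transition_dh <- base$transition_dh * fac[4]
      mass <- with_seed(child_seed(pseed, 3), max(50, stats::rnorm(1, 76, 10)))
      for (r in seq_len(reps)) {
        k <- k + 1L
        meta <- participant_meta(sprintf("%s%03d", cl, i), mass = mass,
                                 height = 1.65, repetition = r,
                                 label6 = labels6[[cl]])
        trials[[k]] <- simulate_trial(do.call(risk_profile, prof), meta,
                                      seed = child_seed(pseed, 10 + r))
      }
    }
  }
  trials
}
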