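#' Inverted pendulum scaling model
#'
#' Quiet standing is approximated as rotation about the ankles, so a
#' horizontal displacement measured at sensor height maps to centre-of-mass
#' height by the ratio of the two heights. Both are expressed as fractions
#' of stature; neither is stated by the sensor, so anthropometric defaults
#' are used (CoM at 55% of stature, a waist-worn sensor just below the
#' iliac crest at 53%).
#'
#' @param com_height_fraction CoM height as a fraction of stature.
#' @param sensor_height_fraction Sensor height as a fraction of stature.
#' @return A `pendulum_model` list.
#' @export
pendulum_model <- function(com_height_fraction = 0.55,
                           sensor_height_fraction = 0.53) {
  if (!(com_height_fraction > 0 && com_height_fraction < 1) ||
      !(sensor_height_fraction > 0 && sensor_height_fraction < 1)) {
    stop("pendulum height fractions must lie in (0, 1)", call. = FALSE)
  }
  structure(list(com_height_fraction = com_height_fraction,
                 sensor_height_fraction = sensor_height_fraction),
            class = "pendulum_model")
}

# Windowed frequency-domain integration: returns the displacement (mm) of
# one world-frame acceleration component over [from, to] seconds. A short
# cosine taper removes the edge discontinuity of the truncated acceleration
# before the FFT. Integrating per phase window keeps spectral leakage from
# large events (e.g. the 3 m walking translation) out of unrelated phases.
integrate_window <- function(a, rate, from, to, hp_cutoff, taper = 0.5) {
  n <- length(a)
  i <- max(1L, floor(from * rate) + 1L)
  j <- min(n, ceiling(to * rate) + 1L)
  seg <- a[i:j]
  m <- length(seg)
  # hp_cutoff = 0 removes the DC bin only: short windows cannot resolve
  # sub-bin drift, and cutting into the first resolvable bins distorts
  # oscillations within an octave of the cutoff.
  if (hp_cutoff <= 0) hp_cutoff <- 0.75 * rate / m
  nt <- min(round(taper * rate), floor(m / 4))
  if (nt > 0L) {
    w <- sin(pi * (seq_len(nt) - 0.5) / (2 * nt))^2
    seg[seq_len(nt)] <- seg[seq_len(nt)] * w
    seg[(m - nt + 1L):m] <- seg[(m - nt + 1L):m] * rev(w)
  }
  disp <- double_integrate_fft(seg, rate, hp_cutoff)
  list(time = (i:j - 1L) / rate, disp = disp)
}

#' Balance displacement during quiet standing
#'
#' 90th percentile of the absolute anterior-posterior and medial-lateral
#' centre-of-mass displacement over the standing phase, obtained by
#' frequency-domain double integration of the horizontal acceleration and
#' inverted-pendulum scaling from sensor height to CoM height.
#'
#' @param acc_world World-frame linear acceleration matrix.
#' @param rate Sampling rate (Hz).
#' @param phase Numeric length-2, the standing interval `[t0, audio_time]`.
#' @param pendulum A [pendulum_model()].
#' @param hp_cutoff High-pass cut-off for the balance band (Hz, default 0.3).
#' @param percentile Percentile of |displacement| reported (default 90).
#' @return Named vector `c(APDisp, MLDisp)` in mm.
#' @export
balance_displacement <- function(acc_world, rate, phase,
                                 pendulum = pendulum_model(),
                                 hp_cutoff = 0.3, percentile = 90) {
  if (diff(phase) < 10) stop("standing phase shorter than 10 s", call. = FALSE)
  scale <- pendulum$com_height_fraction / pendulum$sensor_height_fraction
  q <- percentile / 100
  one <- function(col) {
    w <- integrate_window(acc_world[, col], rate, phase[1], phase[2],
                          hp_cutoff, taper = 1.5)
    # exclude 2 s at each end, where the windowed integration carries taper
    # and edge artefacts; the remaining >= 6 s cover many sway cycles
    inside <- w$time >= phase[1] + 2 & w$time <= phase[2] - 2
    as.numeric(stats::quantile(abs(w$disp[inside] * scale), q))
  }
  c(APDisp = one("ap"), MLDisp = one("ml"))
}

#' Vertical and medial-lateral centre-of-mass excursion while walking
#'
#' Range (max minus min) of the high-passed displacement per walking bout,
#' averaged over the outbound and return bouts.
#'
#' @param acc_world World-frame linear acceleration matrix.
#' @param rate Sampling rate (Hz).
#' @param gait_phases List of one or two numeric length-2 intervals,
#'   `[t1, t2]` and `[t7, t8]`.
#' @param hp_cutoff High-pass cut-off for the gait band (Hz); the default 0
#'   removes only the DC bin of the bout window, the short window being
#'   unable to resolve lower-frequency drift in any case.
#' @return Named vector `c(VRange, MLRange)` in mm.
#' @export
gait_excursion <- function(acc_world, rate, gait_phases, hp_cutoff = 0) {
  ok <- vapply(gait_phases, function(ph) diff(ph) >= 1, TRUE)
  if (!any(ok)) stop("no usable walking bout (each must last >= 1 s)", call. = FALSE)
  if (!all(ok)) message("gait excursion computed on a single walking bout")
  gait_phases <- gait_phases[ok]
  one <- function(col) {
    mean(vapply(gait_phases, function(ph) {
      w <- integrate_window(acc_world[, col], rate, ph[1] - 0.5, ph[2] + 0.5,
                            hp_cutoff, taper = 0.3)
      inside <- w$time >= ph[1] & w$time <= ph[2]
      d <- w$disp[inside]
      max(d) - min(d)
    }, 0))
  }
  c(VRange = one("v"), MLRange = one("ml"))
}

#' Average mechanical power of a sit or stand transition
#'
#' `P = m g |dh| / dt`, with `dh` the vertical centre-of-mass excursion
#' (max minus min of the vertical displacement track) inside the transition
#' interval and `dt` its duration.
#'
#' @param com_v Data frame/list with `time` (s) and `disp` (mm): vertical
#'   CoM displacement covering the interval (see [extract_features()] for
#'   the transition band used).
#' @param mass Participant mass (kg).
#' @param interval Numeric length-2 `[ta, tb]`.
#' @return Power in W.
#' @export
transition_power <- function(com_v, mass, interval) {
  stopifnot_scalar_pos(mass, "mass")
  if (!(interval[2] > interval[1])) {
    stop("degenerate transition interval", call. = FALSE)
  }
  inside <- com_v$time >= interval[1] & com_v$time <= interval[2]
  if (!any(inside)) stop("transition interval outside the displacement track", call. = FALSE)
  dh <- (max(com_v$disp[inside]) - min(com_v$disp[inside])) / 1000
  mass * GRAVITY * dh / (interval[2] - interval[1])
}

#' Range of anterior-posterior jerk over an interval
#'
#' Jerk is the central finite difference of the AP acceleration; the
#' feature is its max minus min inside the interval.
#'
#' @param acc_ap World-frame AP acceleration vector (m/s^2).
#' @param interval Numeric length-2 `[ta, tb]` in s.
#' @param rate Sampling rate (Hz).
#' @return Jerk range in m/s^3.
#' @export
jerk_range <- function(acc_ap, interval, rate) {
  m <- length(acc_ap)
  j <- (acc_ap[c(2:m, m)] - acc_ap[c(1, 1:(m - 1))]) * rate / 2
  tt <- (seq_len(m) - 1L) / rate
  inside <- tt >= interval[1] & tt <= interval[2]
  max(j[inside]) - min(j[inside])
}

#' Reaction time from the audio cue to gait onset
#'
#' @param phases A `phase_times` list.
#' @return `t1 - audio_time` in seconds (non-negative by construction of the
#'   onset search).
#' @export
reaction_time <- function(phases) {
  phases$t1 - phases$audio_time
}

#' Total motion time
#'
#' Sum of the two walking splits, the turn-and-sit split and the stand-up
#' split: `(t2-t1) + (t8-t7) + (t4-t3) + (t6-t5)`. Pauses are excluded, so
#' the total is strictly less than `t8 - t0`.
#'
#' @param phases A `phase_times` list.
#' @return Time in seconds.
#' @export
total_time <- function(phases) {
  with(phases, (t2 - t1) + (t8 - t7) + (t4 - t3) + (t6 - t5))
}

#' Extract the ten balance, gait and functional features from a raw trial
#'
#' Runs the full chain: uniform resampling, zero-lag low-pass filtering,
#' orientation estimation, world-frame gravity-free acceleration, phase
#' segmentation, per-band frequency-domain integration to displacement, and
#' the ten feature computations. Deterministic for fixed input and
#' configuration.
#'
#' @param trial An `imu_trial`.
#' @param config Configuration list, see [default_config()].
#' @return A one-row data.frame with the ten features (canonical order and
#'   units: MLDisp/APDisp/VRange/MLRange mm, PTurnSit/PStand W,
#'   APJerkSit/APJerkStand m/s^3, Reaction_Time/Total_Time s), plus the
#'   detected phase times as an attribute `"phases"`.
#' @export
extract_features <- function(trial, config = default_config()) {
  cfg <- config
  pre <- preprocess_trial(trial, cfg)
  # synthetic trials carry their scripted standing duration; recordings of
  # the standard protocol fall back to the configured 30 s cue time
  audio_time <- trial$profile$standing_duration %||% cfg$audio_time
  phases <- tryCatch(
    segment_phases(pre$uniform, pre$orient, pre$acc_world,
                   audio_time = audio_time, k_sd = cfg$k_sd,
                   min_hold = cfg$min_hold),
    error = function(e) {
      stop(sprintf("trial %s: %s", trial$meta$id %||% "?", conditionMessage(e)),
           call. = FALSE)
    })
  rate <- cfg$rate
  aw <- pre$acc_world

  bal <- balance_displacement(aw, rate, c(phases$t0, phases$audio_time),
                              pendulum = pendulum_model(cfg$com_height_fraction,
                                                        cfg$sensor_height_fraction),
                              hp_cutoff = cfg$hp_balance,
                              percentile = cfg$balance_percentile)
  gait <- gait_excursion(aw, rate, list(c(phases$t1, phases$t2),
                                        c(phases$t7, phases$t8)),
                         hp_cutoff = cfg$hp_gait)
  # Vertical track for the transitions: one window spanning both, with a
  # drift-removal-only high-pass (the sit/stand excursion is a
  # low-frequency transient).
  vtrack <- integrate_window(aw[, "v"], rate, phases$t2, phases$t7,
                             hp_cutoff = cfg$hp_transition, taper = 0.3)
  p_sit <- transition_power(vtrack, trial$meta$mass, c(phases$t3, phases$t4))
  p_stand <- transition_power(vtrack, trial$meta$mass, c(phases$t5, phases$t6))
  j_sit <- jerk_range(aw[, "ap"], c(phases$t3, phases$t4), rate)
  j_stand <- jerk_range(aw[, "ap"], c(phases$t5, phases$t6), rate)

  out <- data.frame(MLDisp = bal[["MLDisp"]], APDisp = bal[["APDisp"]],
                    VRange = gait[["VRange"]], MLRange = gait[["MLRange"]],
                    PTurnSit = p_sit, PStand = p_stand,
                    APJerkSit = j_sit, APJerkStand = j_stand,
                    Reaction_Time = reaction_time(phases),
                    Total_Time = total_time(phases))
  attr(out, "phases") <- phases
  out
}

#' Run resampling, filtering, orientation and world-frame projection
#'
#' @param trial An `imu_trial`.
#' @param config Configuration list, see [default_config()].
#' @return List with `uniform` (filtered `uniform_trial`), `orient`, and
#'   `acc_world`.
#' @export
preprocess_trial <- function(trial, config = default_config()) {
  cfg <- config
  u <- resample_uniform(trial, rate = cfg$rate)
  u$acc <- lowpass_zero_lag(u$acc, cfg$rate, order = cfg$filter_order,
                            cutoff = cfg$filter_cutoff)
  u$gyr <- lowpass_zero_lag(u$gyr, cfg$rate, order = cfg$filter_order,
                            cutoff = cfg$filter_cutoff)
  orient <- estimate_orientation(u, correction_gain = cfg$correction_gain,
                                 axes = cfg$device_axes)
  aw <- world_linear_acceleration(u, orient)
  list(uniform = u, orient = orient, acc_world = aw)
}

#' Feature table for a cohort of trials
#'
#' @param trials List of `imu_trial` objects.
#' @param config Configuration list.
#' @return Data frame with participant id, repetition, labels, mass, height
#'   and the ten features, one row per trial. Trials whose segmentation
#'   fails are dropped with a warning naming them.
#' @export
extract_cohort_features <- function(trials, config = default_config()) {
  rows <- lapply(trials, function(tr) {
    feats <- tryCatch(extract_features(tr, config), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(feats)) return(NULL)
    cbind(data.frame(participant_id = tr$meta$id,
                     repetition = tr$meta$repetition,
                     label2 = tr$meta$label2, label6 = tr$meta$label6,
                     mass = tr$meta$mass, height = tr$meta$height,
                     stringsAsFactors = FALSE),
          feats)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
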