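# Phase segmentation of the modified TUG protocol. The nine instants are:
#   t0 trial start, audio cue at t0 + 30 s, t1 gait onset, t2 end of the
#   outbound walk, t3 start of the turn-and-sit, t4 sit completed, t5 stand
#   initiation, t6 upright, t7 start of the return walk, t8 end of the test.
# All detectors operate on the 20 Hz low-passed, world-frame signals.
#
# Two envelopes are used per channel. Movement *detection* (finding
# sustained supra-threshold regions) runs on a noise-robust envelope: the
# moving maximum of a 4 Hz re-filtered copy (protocol movement lives below
# ~2.5 Hz). Edge *refinement* walks outward on the raw moving-maximum
# envelope, which has no filter tails: its only edge effect is a
# deterministic outward shift of half the window, removed when converting
# indices to times. The window must exceed half the slowest gait period so
# the envelope bridges the zero crossings of the oscillatory bouts (0.45 s
# covers step frequencies down to ~1.1 Hz).

AP_ENV_WIN <- 0.45
V_ENV_WIN <- 0.15

smooth_for_detection <- function(x, rate) {
  lowpass_zero_lag(x, rate, order = 2, cutoff = 4)
}

# Raw and smoothed moving-max envelopes of one channel.
channel_envelopes <- function(x, rate, win) {
  n <- round(win * rate)
  list(raw = moving_max(abs(x), n),
       smooth = moving_max(abs(smooth_for_detection(x, rate)), n))
}

baseline_window <- function(tt, audio_time) {
  tt >= audio_time - 6 & tt <= audio_time - 0.5
}

# Quiet floor of an envelope over a span: pauses and tails occupy well over
# a fifth of the span searched, so a low quantile sits at the noise level.
quiet_floor <- function(env, idx) {
  as.numeric(stats::quantile(env[idx], 0.25))
}

#' Detect gait onset after the audio cue
#'
#' The anterior-posterior acceleration envelope is compared against a noise
#' baseline from the quiet standing preceding the cue. The onset is the
#' first instant at or after `audio_time` where the envelope exceeds
#' `mean + k_sd * SD` of the baseline continuously for `min_hold` seconds,
#' refined backwards on the raw envelope to where the signal last sat at
#' its quiet floor. Because a moving-maximum envelope turns a single
#' excursion into a plateau one window long, the continuity requirement is
#' enforced over `min_hold` plus the envelope window, which is equivalent
#' to demanding supra-threshold magnitude in every sub-window for
#' `min_hold` in total.
#'
#' @param acc_world N x 3 world-frame linear acceleration (columns ap, ml,
#'   v) from [world_linear_acceleration()].
#' @param audio_time Audio cue instant (s from trial start).
#' @param rate Sampling rate (Hz).
#' @param k_sd Threshold in baseline SDs above the baseline mean (default 4).
#' @param min_hold Minimum supra-threshold hold time in s (default 0.1).
#' @return Gait onset time t1 in seconds (never earlier than `audio_time`).
#' @export
detect_gait_onset <- function(acc_world, audio_time, rate,
                              k_sd = 4, min_hold = 0.1) {
  n <- nrow(acc_world)
  tt <- (seq_len(n) - 1L) / rate
  if (audio_time < 5) stop("need at least 5 s of standing before the audio cue", call. = FALSE)
  ev <- channel_envelopes(acc_world[, "ap"], rate, AP_ENV_WIN)
  whalf <- AP_ENV_WIN / 2
  base <- ev$smooth[baseline_window(tt, audio_time)]
  thr <- max(mean(base) + k_sd * stats::sd(base), 1.5 * mean(base), 0.05)
  hold <- max(1L, round((min_hold + AP_ENV_WIN) * rate))
  i0 <- which(tt >= audio_time - whalf)[1]
  above <- ev$smooth >= thr
  above[seq_len(i0 - 1L)] <- FALSE
  runs <- true_runs(above, min_len = hold)
  if (nrow(runs) == 0L) stop("no gait detected after the audio cue", call. = FALSE)
  # Walk back on the raw envelope to the quiet floor after the cue (the
  # participant is still between the cue and gait initiation).
  low <- max(1.8 * quiet_floor(ev$raw, i0:n), 0.02)
  i <- runs[1, "start"]
  while (i < n && ev$raw[i] <= low) i <- i + 1L
  while (i > i0 && ev$raw[i - 1L] > low) i <- i - 1L
  max(tt[i] + whalf, audio_time)
}

# Contiguous regions where the detection envelope stays above `thr` for at
# least `min_len` samples, with boundaries extended outward on the raw
# envelope `edge_env` down to a per-region floor (a small fraction of the
# region's own peak, or the quiet floor if larger). Regions separated by
# less than `merge_gap` samples are merged. Returns start/end indices.
envelope_regions <- function(env, edge_env, thr, min_len, from = 1L,
                             to = length(env), merge_gap = 0L,
                             noise_floor = 0, floor_frac = 0.02) {
  flag <- env >= thr
  if (from > 1L) flag[seq_len(from - 1L)] <- FALSE
  if (to < length(env)) flag[(to + 1L):length(env)] <- FALSE
  runs <- true_runs(flag, min_len = min_len)
  if (nrow(runs) == 0L) return(runs)
  for (r in seq_len(nrow(runs))) {
    low <- max(floor_frac * max(edge_env[runs[r, "start"]:runs[r, "end"]]),
               1.8 * noise_floor, 0.015)
    i <- runs[r, "start"]
    j <- runs[r, "end"]
    # the detection envelope can lead the raw support; move inward first
    while (i < j && edge_env[i] <= low) i <- i + 1L
    while (j > i && edge_env[j] <= low) j <- j - 1L
    while (i > from && edge_env[i - 1L] > low) i <- i - 1L
    while (j < to && edge_env[j + 1L] > low) j <- j + 1L
    runs[r, ] <- c(i, j)
  }
  # merge overlapping or near-touching regions after extension
  keep <- rep(TRUE, nrow(runs))
  if (nrow(runs) > 1L) {
    for (r in 2:nrow(runs)) {
      if (runs[r, "start"] <= runs[r - 1L, "end"] + merge_gap) {
        runs[r, "start"] <- runs[r - 1L, "start"]
        runs[r, "end"] <- max(runs[r, "end"], runs[r - 1L, "end"])
        keep[r - 1L] <- FALSE
      }
    }
  }
  runs[keep, , drop = FALSE]
}

#' Segment the nine protocol instants
#'
#' Identifies t0..t8 from characteristic features of the processed signals:
#' gait onset and the two walking bouts from the anterior-posterior
#' acceleration envelope (first and last sustained movement regions after
#' the cue), the turn from the yaw-rate pulse of the orientation track
#' (t3 = start of the yaw ramp, found by walking outward from the peak
#' |yaw rate|), and the sit/stand transitions from the two vertical
#' acceleration transients between the walking bouts.
#'
#' @param trial A `uniform_trial` (20 Hz low-passed).
#' @param orient Matching `orientation_track`.
#' @param acc_world Matching world-frame linear acceleration.
#' @param audio_time Audio cue instant (s, protocol default 30).
#' @param k_sd,min_hold Onset detector parameters, see [detect_gait_onset()].
#' @return A `phase_times` list with elements t0..t8 and `audio_time`, all
#'   in seconds on the uniform time base.
#' @export
segment_phases <- function(trial, orient, acc_world, audio_time = 30,
                           k_sd = 4, min_hold = 0.1) {
  rate <- trial$rate
  n <- nrow(acc_world)
  tt <- (seq_len(n) - 1L) / rate

  t1 <- detect_gait_onset(acc_world, audio_time, rate, k_sd = k_sd,
                          min_hold = min_hold)

  # Walking bouts from the AP envelope: first region after the cue is the
  # outbound walk, last region is the return walk.
  ev <- channel_envelopes(acc_world[, "ap"], rate, AP_ENV_WIN)
  whalf <- AP_ENV_WIN / 2
  base <- ev$smooth[baseline_window(tt, audio_time)]
  thr <- max(mean(base) + k_sd * stats::sd(base), 1.5 * mean(base), 0.05)
  i0 <- which(tt >= audio_time - whalf)[1]
  nf <- quiet_floor(ev$raw, i0:n)
  regions <- envelope_regions(ev$smooth, ev$raw, thr,
                              min_len = round(1.0 * rate),
                              from = i0, to = n,
                              merge_gap = round(0.1 * rate),
                              noise_floor = nf)
  if (nrow(regions) < 2L) {
    stop("segmentation failed: fewer than two movement regions found", call. = FALSE)
  }
  t2 <- tt[regions[1, "end"]] - whalf
  t7 <- tt[regions[nrow(regions), "start"]] + whalf
  t8 <- tt[regions[nrow(regions), "end"]] - whalf

  # Turn: yaw-rate pulse; t3 = start of the yaw ramp. The peak is located
  # on the smoothed rate, the ramp start on the raw rate.
  yaw <- unwrap_angle(orient$euler[, "yaw"])
  yaw_rate <- c(0, diff(yaw)) * rate
  yr_s <- smooth_for_detection(yaw_rate, rate)
  ybase <- yaw_rate[baseline_window(tt, audio_time)]
  ip <- which.max(abs(yr_s))
  peak <- abs(yr_s[ip])
  ythr <- max(0.002 * peak, mean(abs(ybase)) + 4 * stats::sd(abs(ybase)))
  i <- ip
  while (i > 1L && abs(yaw_rate[i - 1L]) > ythr) i <- i - 1L
  t3 <- tt[i]

  # Sit and stand transitions: the two vertical transients between bouts.
  evv <- channel_envelopes(acc_world[, "v"], rate, V_ENV_WIN)
  vwhalf <- V_ENV_WIN / 2
  vbase <- evv$smooth[baseline_window(tt, audio_time)]
  iw <- which(tt > t2 + 0.2 & tt < t7 - 0.1)
  if (length(iw) < rate) stop("segmentation failed: no room between walking bouts", call. = FALSE)
  vmax <- max(evv$smooth[iw])
  vthr <- max(0.3 * vmax, mean(vbase) + k_sd * stats::sd(vbase))
  vnf <- max(quiet_floor(evv$raw, iw), mean(vbase) + 2 * stats::sd(vbase))
  vreg <- envelope_regions(evv$smooth, evv$raw, vthr,
                           min_len = round(0.3 * rate),
                           from = iw[1], to = iw[length(iw)],
                           merge_gap = round(0.5 * rate),
                           noise_floor = vnf)
  if (nrow(vreg) < 2L) {
    stop("segmentation failed: could not find both vertical transitions", call. = FALSE)
  }
  if (nrow(vreg) > 2L) {
    pk <- vapply(seq_len(nrow(vreg)), function(r) max(evv$smooth[vreg[r, 1]:vreg[r, 2]]), 0)
    vreg <- vreg[order(pk, decreasing = TRUE)[1:2], , drop = FALSE]
    vreg <- vreg[order(vreg[, "start"]), , drop = FALSE]
  }
  t4 <- tt[vreg[1, "end"]] - vwhalf
  t5 <- tt[vreg[2, "start"]] + vwhalf
  t6 <- tt[vreg[2, "end"]] - vwhalf

  phases <- structure(list(t0 = 0, audio_time = audio_time, t1 = t1, t2 = t2,
                           t3 = t3, t4 = t4, t5 = t5, t6 = t6, t7 = t7,
                           t8 = t8),
                      class = "phase_times")
  validate_phase_times(phases, t_end = tt[n])
  phases
}

#' Validate the ordering invariant of segmented phase times
#'
#' @param phases A `phase_times` list.
#' @param t_end Trial end time (s).
#' @return `phases`, invisibly; errors naming the first offending pair.
#' @export
validate_phase_times <- function(phases, t_end = Inf) {
  seqs <- list(c("t0", "audio_time"), c("audio_time", "t1"), c("t1", "t2"),
               c("t2", "t3"), c("t3", "t4"), c("t4", "t5"), c("t5", "t6"),
               c("t6", "t7"), c("t7", "t8"))
  strict <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  for (k in seq_along(seqs)) {
    a <- phases[[seqs[[k]][1]]]
    b <- phases[[seqs[[k]][2]]]
    bad <- if (strict[k]) !(a < b) else !(a <= b)
    if (bad) {
      stop(sprintf("phase ordering violated: %s (%.3f) !%s %s (%.3f)",
                   seqs[[k]][1], a, if (strict[k]) "<" else "<=",
                   seqs[[k]][2], b), call. = FALSE)
    }
  }
  if (phases$t8 > t_end) stop("phase t8 beyond trial end", call. = FALSE)
  invisible(phases)
}

unwrap_angle <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}
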