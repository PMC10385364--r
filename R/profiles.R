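#' Feature names in canonical order
#' @export
FEATURE_NAMES <- c("MLDisp", "APDisp", "VRange", "MLRange",
                   "PTurnSit", "PStand", "APJerkSit", "APJerkStand",
                   "Reaction_Time", "Total_Time")

#' Participant metadata
#'
#' @param id Participant identifier (string).
#' @param mass Body mass in kg (> 0).
#' @param height Stature in m (> 0).
#' @param repetition Repetition index (integer >= 1).
#' @param label6 Ordinal fall-risk level 1..6 (1 = very low, 6 = very high).
#' @param faller_threshold Levels strictly above this are labelled "faller"
#'   (default 3).
#' @return A `participant_meta` list with the derived binary label in
#'   `label2` ("nonfaller"/"faller").
#' @export
participant_meta <- function(id, mass, height, repetition = 1L, label6 = 1L,
                             faller_threshold = 3L) {
  stopifnot_scalar_pos(mass, "mass")
  stopifnot_scalar_pos(height, "height")
  if (!(repetition >= 1)) stop("`repetition` must be >= 1", call. = FALSE)
  if (!(label6 %in% 1:6)) stop("`label6` must be an integer in 1..6", call. = FALSE)
  structure(list(
    id = as.character(id), mass = mass, height = height,
    repetition = as.integer(repetition), label6 = as.integer(label6),
    label2 = if (label6 > faller_threshold) "faller" else "nonfaller"
  ), class = "participant_meta")
}

#' Risk profile driving the trial simulator
#'
#' Parameterises the phenomena the feature extractor measures: postural sway
#' amplitude and frequency during quiet standing, vertical/medial-lateral
#' gait oscillation, walking bout duration, reaction latency after the audio
#' cue, the vertical excursion and duration of the sit and stand
#' transitions, the anterior-posterior burst accompanying each transition,
#' and the sensor noise level.
#'
#' @param sway_amp_ap,sway_amp_ml Amplitude (mm) of the primary sway
#'   sinusoid per horizontal axis; a second sinusoid at
#'   `sway_freq2_mult * sway_freq` with relative amplitude `sway_amp2_frac`
#'   is superposed.
#' @param sway_freq Primary sway frequency (Hz).
#' @param gait_v_amp,gait_ml_amp,gait_ap_amp Gait oscillation amplitudes
#'   (mm); vertical and AP oscillate at `step_freq`, ML at `step_freq / 2`
#'   (one cycle per stride).
#' @param step_freq Step frequency (Hz).
#' @param walk_duration Duration of each 3 m walking bout (s).
#' @param reaction_latency Delay from audio cue to gait onset (s).
#' @param transition_dh Vertical centre-of-mass excursion of the sit and
#'   stand transitions (m).
#' @param transition_dt_sit,transition_dt_stand Transition durations (s).
#' @param trans_ap_amp_sit,trans_ap_amp_stand Peak AP acceleration (m/s^2)
#'   of the oscillatory burst during each transition, at `trans_ap_freq` Hz.
#' @param turn_duration Duration of the 180 degree yaw ramp at the start of
#'   the turn-and-sit phase (s).
#' @param noise_sd Accelerometer white-noise SD (m/s^2); gyroscope noise is
#'   `0.05 * noise_sd` rad/s.
#' @param standing_duration Quiet-standing duration before the audio cue
#'   (s, protocol default 30).
#' @param stand_walk_gap Regrouping pause between reaching upright and
#'   starting the return walk (s).
#' @param pause_duration Scripted pauses before the turn-sit and after it
#'   (s, protocol default 2).
#' @param sway_amp2_frac,sway_freq2_mult Second sway sinusoid, relative
#'   amplitude and frequency multiple.
#' @return A validated `risk_profile` list.
#' @export
risk_profile <- function(sway_amp_ap = 15, sway_amp_ml = 5, sway_freq = 0.45,
                         gait_v_amp = 14, gait_ml_amp = 26, gait_ap_amp = 12,
                         step_freq = 1.85, walk_duration = 4,
                         reaction_latency = 0.8,
                         transition_dh = 0.25,
                         transition_dt_sit = 1.5, transition_dt_stand = 1.3,
                         trans_ap_amp_sit = 1.2, trans_ap_amp_stand = 1.5,
                         trans_ap_freq = 1.3, turn_duration = 1.2,
                         noise_sd = 0.03,
                         standing_duration = 30, pause_duration = 2,
                         stand_walk_gap = 1.5,
                         sway_amp2_frac = 0.15, sway_freq2_mult = 2.0) {
  p <- as.list(environment())
  amps <- c("sway_amp_ap", "sway_amp_ml", "gait_v_amp", "gait_ml_amp",
            "gait_ap_amp", "trans_ap_amp_sit", "trans_ap_amp_stand",
            "transition_dh", "noise_sd", "reaction_latency",
            "sway_amp2_frac")
  for (nm in amps) stopifnot_scalar_pos(p[[nm]], nm, strict = FALSE)
  durs <- c("walk_duration", "transition_dt_sit", "transition_dt_stand",
            "turn_duration", "standing_duration", "pause_duration",
            "stand_walk_gap",
            "sway_freq", "step_freq", "trans_ap_freq", "sway_freq2_mult")
  for (nm in durs) stopifnot_scalar_pos(p[[nm]], nm, strict = TRUE)
  if (p$turn_duration > p$transition_dt_sit) {
    stop("`turn_duration` cannot exceed `transition_dt_sit`", call. = FALSE)
  }
  structure(p, class = "risk_profile")
}

# Canonical mean profiles for the six ordinal fall-risk levels. Values
# interpolate linearly from level 1 (very low risk: small sway, brisk gait,
# powerful transitions, short latency) to level 6 (very high risk). The
# direction of every trend follows the faller-vs-nonfaller contrasts the
# features are designed to capture: higher risk means larger sway, smaller
# and slower gait oscillations, longer walks, slower and weaker transitions,
# smoother (lower-jerk) movement, and longer reaction times.
LEVEL_ANCHORS <- list(
  low = list(sway_amp_ap = 11, sway_amp_ml = 3.5, gait_v_amp = 15.5,
             gait_ml_amp = 28, gait_ap_amp = 13, step_freq = 1.95,
             walk_duration = 3.6, reaction_latency = 0.65,
             transition_dh = 0.27, transition_dt_sit = 1.3,
             transition_dt_stand = 1.1, trans_ap_amp_sit = 1.45,
             trans_ap_amp_stand = 1.75, noise_sd = 0.02),
  high = list(sway_amp_ap = 21, sway_amp_ml = 8.5, gait_v_amp = 10.5,
              gait_ml_amp = 21, gait_ap_amp = 10, step_freq = 1.55,
              walk_duration = 5.6, reaction_latency = 1.35,
              transition_dh = 0.23, transition_dt_sit = 2.1,
              transition_dt_stand = 1.9, trans_ap_amp_sit = 0.95,
              trans_ap_amp_stand = 1.15, noise_sd = 0.045)
)

#' Mean risk profile for an ordinal fall-risk level
#'
#' @param level Integer 1..6.
#' @param noise_sd Optional override of the accelerometer noise SD.
#' @return A `risk_profile`.
#' @export
level_profile <- function(level, noise_sd = NULL) {
  if (!(level %in% 1:6)) stop("`level` must be in 1..6", call. = FALSE)
  w <- (level - 1) / 5
  args <- lapply(names(LEVEL_ANCHORS$low), function(nm) {
    (1 - w) * LEVEL_ANCHORS$low[[nm]] + w * LEVEL_ANCHORS$high[[nm]]
  })
  names(args) <- names(LEVEL_ANCHORS$low)
  if (!is.null(noise_sd)) args$noise_sd <- noise_sd
  do.call(risk_profile, args)
}
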