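# Shared fixtures, built once per test run and memoised: simulating and
# preprocessing a trial is the expensive step common to many tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# One noise-free mid-risk trial with its preprocessing products.
clean_trial <- function() {
  fixture("clean_trial", function() {
    tr <- simulate_trial(level_profile(3, noise_sd = 0),
                         participant_meta("P1", mass = 70, height = 1.65,
                                          label6 = 3),
                         seed = 42)
    pre <- preprocess_trial(tr)
    feats <- extract_features(tr)
    list(trial = tr, pre = pre, feats = feats,
         phases = attr(feats, "phases"))
  })
}

# A zero-motion trial (all amplitudes and noise zero): pure gravity.
static_trial <- function() {
  fixture("static_trial", function() {
    prof <- risk_profile(sway_amp_ap = 0, sway_amp_ml = 0, gait_v_amp = 0,
                         gait_ml_amp = 0, gait_ap_amp = 0,
                         trans_ap_amp_sit = 0, trans_ap_amp_stand = 0,
                         transition_dh = 0.0001, noise_sd = 0,
                         standing_duration = 12)
    simulate_trial(prof, participant_meta("S", 70, 1.65), seed = 5)
  })
}

# Relative error helper.
relerr <- function(est, truth) abs(est - truth) / abs(truth)
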