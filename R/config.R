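#' Default pipeline configuration
#'
#' Central registry of the processing constants: 100 Hz sampling, 4th-order
#' 20 Hz zero-lag low-pass, the per-band high-pass cut-offs of the
#' frequency-domain integrator, segmentation thresholds, inverted-pendulum
#' height fractions, the 64-sample window / 20-2 STFT framing of the
#' network input, and the evaluation scheme (80/20 stratified split,
#' 10 x 10 repeated stratified CV, at most 6 features after RFE).
#'
#' @param ... Named overrides of any default.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    rate = 100,
    filter_order = 4,
    filter_cutoff = 20,
    hp_balance = 0.3,
    hp_gait = 0,
    hp_transition = 0.02,
    audio_time = 30,
    k_sd = 4,
    min_hold = 0.1,
    correction_gain = 0.002,
    device_axes = c(ml = 1L, v = 2L, ap = 3L),
    com_height_fraction = 0.55,
    sensor_height_fraction = 0.53,
    balance_percentile = 90,
    window = 64L,
    window_step = 32L,
    stft_frame = 20L,
    stft_step = 2L,
    stft_eps = 1e-6,
    test_fraction = 0.2,
    cv_k = 10L,
    cv_repeats = 10L,
    max_features = 6L,
    epochs = 100L,
    batch_size = 32L,
    faller_threshold = 3L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Read a configuration file (YAML or JSON) merged over the defaults
#'
#' @param path File path; format chosen by extension.
#' @return A config list as from [default_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_config, vals)
}
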