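# Raw-signal windows and their log-magnitude spectrograms: the two inputs
# of the mixed-input network. A window is 64 consecutive samples of the six
# filtered device channels (accelerometer xyz then gyroscope xyz); its
# spectrogram is built from the 384-sample concatenation of the six
# channels, short-time Fourier transformed with frame length 20 and frame
# step 2, giving a 183 x 11 image (one-sided spectrum of each frame).

#' Cut sliding windows from a six-channel signal
#'
#' @param signals N x 6 numeric matrix (accelerometer xyz, gyroscope xyz).
#' @param window Window length in samples (default 64).
#' @param step Stride between window starts (default 32, 50% overlap).
#' @return List with `windows` (W x window x 6 array) and `starts` (first
#'   sample index of each window); `W = floor((N - window)/step) + 1`.
#' @export
make_windows <- function(signals, window = 64L, step = 32L) {
  signals <- as.matrix(signals)
  n <- nrow(signals)
  if (n < window) {
    stop(sprintf("signal has %d samples; need at least %d for one window", n, window),
         call. = FALSE)
  }
  starts <- seq(1L, n - window + 1L, by = step)
  w <- array(0, dim = c(length(starts), window, ncol(signals)))
  for (i in seq_along(starts)) {
    w[i, , ] <- signals[starts[i]:(starts[i] + window - 1L), ]
  }
  list(windows = w, starts = starts)
}

#' Log-magnitude spectrogram of one window
#'
#' The six channels are concatenated in column order into a single
#' 384-sample signal, cut into frames of `frame` samples every `fstep`
#' samples (183 frames at the defaults), and each frame is Fourier
#' transformed; the image is `log(|STFT| + eps)` over the one-sided
#' spectrum (`frame/2 + 1 = 11` bins).
#'
#' @param window `window_len` x 6 matrix (one window).
#' @param frame Frame length in samples (default 20).
#' @param fstep Frame step in samples (default 2).
#' @param eps Floor inside the logarithm (default 1e-6).
#' @param taper `"rectangular"` (default) or `"hann"` frame taper.
#' @return frames x bins numeric matrix, all values finite.
#' @export
window_spectrogram <- function(window, frame = 20L, fstep = 2L, eps = 1e-6,
                               taper = c("rectangular", "hann")) {
  taper <- match.arg(taper)
  x <- as.numeric(as.matrix(window))  # column-major concatenation
  n <- length(x)
  n_frames <- (n - frame) %/% fstep + 1L
  idx <- outer(seq_len(frame), (seq_len(n_frames) - 1L) * fstep, `+`)
  fr <- matrix(x[idx], nrow = frame)
  if (taper == "hann") {
    fr <- fr * (0.5 - 0.5 * cos(2 * pi * (seq_len(frame) - 1) / (frame - 1)))
  }
  sp <- stats::mvfft(fr)[seq_len(frame %/% 2L + 1L), , drop = FALSE]
  t(log(abs(sp) + eps))
}

#' Spectrograms for a batch of windows
#'
#' @param windows W x window_len x 6 array from [make_windows()].
#' @inheritParams window_spectrogram
#' @return W x frames x bins array.
#' @export
spectrogram_batch <- function(windows, frame = 20L, fstep = 2L, eps = 1e-6,
                              taper = "rectangular") {
  nw <- dim(windows)[1]
  first <- window_spectrogram(windows[1, , ], frame, fstep, eps, taper)
  out <- array(0, dim = c(nw, nrow(first), ncol(first)))
  out[1, , ] <- first
  if (nw > 1) {
    for (i in 2:nw) {
      out[i, , ] <- window_spectrogram(windows[i, , ], frame, fstep, eps, taper)
    }
  }
  out
}

#' Windows and spectrograms for a list of trials
#'
#' Preprocesses each trial (resampling + zero-lag filtering), cuts windows
#' from the filtered device-frame signals and attaches the trial's class
#' label to each of its windows. Windows never cross a trial boundary.
#'
#' Windows whose channels are all flat (below `min_activity` standard
#' deviation within the window, e.g. rest pauses) carry no movement
#' information and are dropped; a trial whose windows are all flat keeps
#' them all rather than vanish.
#'
#' @param trials List of `imu_trial` objects.
#' @param n_classes 2 or 6: which label each window inherits.
#' @param config Pipeline configuration, see [default_config()].
#' @param min_activity Minimum mean within-window channel SD (m/s^2) for a
#'   window to be kept (default 0.04; 0 keeps everything).
#' @return List with `windows` (W x 64 x 6), `spectrograms` (W x 183 x 11),
#'   `labels` (character), and `trial` (index of the source trial per
#'   window).
#' @export
cohort_windows <- function(trials, n_classes = 2, config = default_config(),
                           min_activity = 0.04) {
  stopifnot(n_classes %in% c(2, 6))
  wlist <- list(); labs <- character(0); src <- integer(0)
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    u <- resample_uniform(tr, rate = config$rate)
    sig <- cbind(lowpass_zero_lag(u$acc, config$rate, config$filter_order,
                                  config$filter_cutoff),
                 lowpass_zero_lag(u$gyr, config$rate, config$filter_order,
                                  config$filter_cutoff))
    mw <- make_windows(sig, config$window, config$window_step)
    if (min_activity > 0) {
      act <- vapply(seq_len(dim(mw$windows)[1]), function(i) {
        mean(apply(mw$windows[i, , 1:3], 2, stats::sd))
      }, 0)
      if (any(act >= min_activity)) {
        mw$windows <- mw$windows[act >= min_activity, , , drop = FALSE]
      }
    }
    lab <- if (n_classes == 2) tr$meta$label2 else as.character(tr$meta$label6)
    wlist[[ti]] <- mw$windows
    labs <- c(labs, rep(lab, dim(mw$windows)[1]))
    src <- c(src, rep(ti, dim(mw$windows)[1]))
  }
  windows <- do.call(abind3, wlist)
  list(windows = windows,
       spectrograms = spectrogram_batch(windows, config$stft_frame,
                                        config$stft_step, config$stft_eps),
       labels = labs, trial = src)
}

# bind 3D arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
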