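#' @keywords internal
"_PACKAGE"

# Standard gravity used throughout (m/s^2).
GRAVITY <- 9.81

#' Evaluate an expression with a local, restorable RNG state
#'
#' All stochastic operations in the package funnel their seeds through this
#' helper so that a call is reproducible and does not disturb the caller's
#' random number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a %s finite scalar", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

# Moving root-mean-square envelope with a centred rectangular window.
moving_rms <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  half <- (n - 1L) %/% 2L
  xx <- c(rep(x[1]^2, half), x^2, rep(x[length(x)]^2, half))
  cs <- cumsum(xx)
  s <- cs[(n):(n + length(x) - 1L)] - c(0, cs[seq_len(length(x) - 1L)])
  sqrt(s / n)
}

# Moving maximum with a centred window of n samples (morphological
# dilation): a signal edge is displaced outward by exactly (n-1)/2 samples,
# which detectors compensate deterministically.
moving_max <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  half <- (n - 1L) %/% 2L
  len <- length(x)
  xx <- c(rep(-Inf, half), x, rep(-Inf, half))
  vapply(seq_len(len), function(i) max(xx[i:(i + n - 1L)]), 0)
}

# Contiguous runs where a logical vector is TRUE, as a two-column matrix of
# start/end indices. Runs shorter than `min_len` samples are dropped.
true_runs <- function(flag, min_len = 1L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])
}
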