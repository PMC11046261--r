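#' @keywords internal
"_PACKAGE"

## Millisecond <-> sample conversions under the package-wide half-open
## window convention: a window (start_ms, end_ms) at sampling rate fs maps to
## sample offsets round(start*fs/1000) ... round(end*fs/1000) - 1 relative to
## the event sample, so adjacent windows never share a sample.

ms_to_samp <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' Number of samples in a half-open millisecond window
#' @param window_ms length-2 numeric, (start_ms, end_ms)
#' @param fs sampling rate in Hz
#' @return integer sample count
#' @keywords internal
window_length <- function(window_ms, fs) {
  ms_to_samp(window_ms[2], fs) - ms_to_samp(window_ms[1], fs)
}

## Relative (to an event sample, 1-based) sample indices of a window.
window_offsets <- function(window_ms, fs) {
  seq.int(ms_to_samp(window_ms[1], fs), ms_to_samp(window_ms[2], fs) - 1L)
}

stop_if_not_window <- function(window_ms) {
  if (length(window_ms) != 2L || !is.numeric(window_ms) ||
      window_ms[1] >= window_ms[2]) {
    stop("window must be numeric (start_ms, end_ms) with start < end",
         call. = FALSE)
  }
}

## Raised-cosine on/off ramp envelope for a segment of n samples.
## ramp_n samples rise at the start and fall at the end; flat in between.
ramp_envelope <- function(n, ramp_n) {
  env <- rep(1, n)
  if (ramp_n > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(ramp_n) - 0.5) / ramp_n))
    env[seq_len(ramp_n)] <- r
    env[seq.int(n - ramp_n + 1L, n)] <- rev(r)
  }
  env
}

## Zero-phase IIR filtering of every column of a matrix (forward-backward,
## odd-reflection padding as in standard filtfilt implementations). Written
## over stats::filter so that all columns are filtered in one pass.
zero_phase_filter <- function(x, b, a, padlen = NULL) {
  one_pass <- function(m) {
    nb <- length(b) - 1L
    z <- stats::filter(rbind(matrix(0, nb, ncol(m)), m),
                       b, method = "convolution", sides = 1)
    z <- z[-seq_len(nb), , drop = FALSE]      # drops the ts class
    y <- stats::filter(z, -a[-1], method = "recursive")
    y <- unclass(y)
    attr(y, "tsp") <- NULL
    dim(y) <- dim(m)
    y
  }
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 10L)
  top <- 2 * x[rep(1L, padlen), , drop = FALSE] - x[seq.int(padlen + 1L, 2L), , drop = FALSE]
  bot <- 2 * x[rep(n, padlen), , drop = FALSE] - x[seq.int(n - 1L, n - padlen), , drop = FALSE]
  y <- one_pass(rbind(top, x, bot))
  y <- one_pass(y[rev(seq_len(nrow(y))), , drop = FALSE])
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- y[seq.int(padlen + 1L, padlen + n), , drop = FALSE]
  if (vec) drop(y) else y
}

## Real FFT band shaping: multiply the spectrum of each column by gain(f)
## and return the reshaped real signal. gain is evaluated on the one-sided
## frequency grid and mirrored onto negative frequencies.
fft_shape <- function(x, fs, gain_fun) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  f <- seq.int(0L, n - 1L) * (fs / n)
  f <- pmin(f, fs - f)              # two-sided grid folded to [0, fs/2]
  g <- gain_fun(f)
  y <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / n
  if (vec) drop(y) else y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
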