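## Spectral amplitude shape of the 1/f^alpha background on the folded
## frequency grid; flat below f_floor to keep the DC region finite, zero at
## exactly 0 Hz so channels are mean-free.
background_shape <- function(f, exponent, f_floor = 1) {
  s <- pmax(f, f_floor)^(-exponent / 2)
  s[f == 0] <- 0
  s
}

#' Simulate the 1/f EEG background
#'
#' Each channel is independent Gaussian noise spectrally shaped so that its
#' power spectral density follows `1 / f^alpha` (flat below 1 Hz), scaled
#' to a physiological RMS. Shaping is done by inverse FFT of white noise
#' with `f^(-alpha/2)` amplitude, so the target spectrum is exact in
#' expectation at every DFT bin.
#'
#' @param config a [sim_config()]
#' @param n_samples recording length in samples (defaults to the length
#'   implied by the condition table and trial spacing)
#' @param seed integer seed; the same (config, seed) yields a bit-identical
#'   recording
#' @return an [new_recording()] without events
#' @export
simulate_background <- function(config, n_samples = NULL, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  if (is.null(n_samples)) {
    n_trials <- sum(config$condition_table$n_trials)
    spacing <- ms_to_samp((config$stimulus_duration +
                             config$interstimulus_interval) * 1000, fs)
    n_samples <- as.integer(2 * round(config$lead_in_s * fs) +
                              n_trials * spacing)
  }
  n_ch <- length(config$channel_labels)
  f <- seq.int(0L, n_samples - 1L) * (fs / n_samples)
  f <- pmin(f, fs - f)
  s <- background_shape(f, config$background_exponent)
  s <- s * config$background_rms / sqrt(mean(s^2))
  data <- withr::with_seed(seed, {
    out <- matrix(0, n_ch, n_samples)
    for (ch in seq_len(n_ch)) {
      w <- stats::rnorm(n_samples)
      out[ch, ] <- Re(stats::fft(stats::fft(w) * s, inverse = TRUE)) / n_samples
    }
    out
  })
  new_recording(data, fs, config$channel_labels,
                impedances = config$impedances)
}
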