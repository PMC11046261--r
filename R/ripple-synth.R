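#' Synthesize a ripple stimulus waveform
#'
#' Sums the tone bank of `spec` with each carrier's amplitude following the
#' moving-ripple envelope on a linear scale. Carrier starting phases are
#' drawn uniformly from `[0, 2 * pi)` with the supplied seed (randomized
#' phases avoid an impulsive waveform at `t = 0`). Raised-cosine on/off
#' ramps of `spec$ramp` seconds are applied and the waveform is
#' peak-normalized to `headroom` full scale.
#'
#' @param spec a [ripple_spec()]
#' @param seed integer seed for the carrier phases
#' @param headroom peak amplitude of the normalized waveform (0-1]
#' @return numeric waveform of `round(duration * sample_rate)` samples with
#'   attributes `sample_rate`, `spec`, `seed`
#' @export
#' @examples
#' w <- synthesize_ripple(ripple_spec(density = 0.8, velocity = 10), seed = 1)
#' length(w)
synthesize_ripple <- function(spec, seed = 1L, headroom = 0.9) {
  stopifnot(inherits(spec, "ripple_spec"))
  freqs <- tone_frequencies(spec)
  if (max(freqs) >= spec$sample_rate / 2) {
    stop(sprintf(
      "aliasing: top tone %.1f Hz is not below Nyquist (%g Hz)",
      max(freqs), spec$sample_rate / 2), call. = FALSE)
  }
  n <- as.integer(round(spec$duration * spec$sample_rate))
  t <- (seq_len(n) - 1L) / spec$sample_rate
  phases <- withr::with_seed(seed, stats::runif(length(freqs), 0, 2 * pi))
  x_oct <- log2(freqs / spec$low_edge)
  wave <- numeric(n)
  for (i in seq_along(freqs)) {
    wave <- wave + envelope_moving(x_oct[i], t, spec) *
      sin(2 * pi * freqs[i] * t + phases[i])
  }
  wave <- wave * ramp_envelope(n, as.integer(round(spec$ramp * spec$sample_rate)))
  peak <- max(abs(wave))
  if (peak > 0) wave <- wave * (headroom / peak)
  structure(wave, sample_rate = spec$sample_rate, spec = spec, seed = seed)
}
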