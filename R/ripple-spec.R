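#' Ripple stimulus specification
#'
#' Full parameterization of a stationary or moving ripple ("auditory
#' grating"): a bank of log-spaced tone carriers whose amplitudes follow a
#' sinusoidal spectral envelope that may drift along the log-frequency axis.
#'
#' The spectral envelope at log-frequency position `x = log2(f / low_edge)`
#' octaves and time `t` seconds is
#' `S(x, t) = 1 + depth * sin(2 * pi * (velocity * t + density * x) + phase)`.
#' With this sign convention and positive `density`/`velocity`,
#' constant-phase contours satisfy `x = -(velocity / density) * t + c`, i.e.
#' the envelope drifts downward toward lower frequencies.
#'
#' @param density spectral modulation rate in cycles/octave (>= 0)
#' @param velocity temporal modulation rate in cycles/s (>= 0; the drift is
#'   downward by convention, see Details)
#' @param depth modulation depth in `[0, 1]` (1 = full modulation)
#' @param phase starting phase in radians, referenced to the low-frequency
#'   edge of the spectrum
#' @param low_edge lowest carrier frequency in Hz
#' @param n_octaves number of octaves spanned by the tone bank
#' @param tones_per_octave carriers per octave (log-uniform spacing)
#' @param duration stimulus duration in seconds
#' @param sample_rate audio sampling rate in Hz
#' @param ramp on/off ramp duration in seconds (raised cosine)
#' @return object of class `ripple_spec`
#' @export
#' @examples
#' spec <- ripple_spec(density = 0.8, velocity = 10)
#' length(tone_frequencies(spec))
ripple_spec <- function(density = 0, velocity = 0, depth = 0.9, phase = 0,
                        low_edge = 250, n_octaves = 5, tones_per_octave = 16,
                        duration = 0.8, sample_rate = 44100, ramp = 0.010) {
  if (!is.numeric(depth) || depth < 0 || depth > 1) {
    stop("depth must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(low_edge) || low_edge <= 0) {
    stop("low_edge must be positive", call. = FALSE)
  }
  if (density < 0 || velocity < 0) {
    stop("density and velocity must be >= 0 (downward drift by convention)",
         call. = FALSE)
  }
  if (tones_per_octave < 1 || n_octaves <= 0) {
    stop("tone bank must contain at least one tone", call. = FALSE)
  }
  if (duration <= 2 * ramp) {
    stop("duration must exceed twice the ramp length", call. = FALSE)
  }
  structure(list(density = density, velocity = velocity, depth = depth,
                 phase = phase, low_edge = low_edge, n_octaves = n_octaves,
                 tones_per_octave = tones_per_octave, duration = duration,
                 sample_rate = sample_rate, ramp = ramp),
            class = "ripple_spec")
}

#' @export
print.ripple_spec <- function(x, ...) {
  cat(sprintf(
    "Ripple stimulus: density %g cyc/oct, velocity %g cyc/s, depth %g\n",
    x$density, x$velocity, x$depth))
  cat(sprintf("  %d tones, %g-%g Hz (%g octaves), %g s at %g Hz\n",
              x$tones_per_octave * x$n_octaves, x$low_edge,
              x$low_edge * 2^x$n_octaves, x$n_octaves, x$duration,
              x$sample_rate))
  invisible(x)
}

#' Carrier tone frequencies of a ripple spectrum
#'
#' The tone bank places `tones_per_octave * n_octaves` carriers at
#' log-uniform spacing starting at the low-frequency edge:
#' `f_i = low_edge * 2^(i / tones_per_octave)`, `i = 0, ..., N - 1`.
#'
#' @param spec a [ripple_spec()]
#' @return numeric vector of strictly increasing carrier frequencies (Hz)
#' @export
#' @examples
#' f <- tone_frequencies(ripple_spec())
#' f[17] / f[1]  # one octave up doubles the frequency
tone_frequencies <- function(spec) {
  stopifnot(inherits(spec, "ripple_spec"))
  n <- spec$tones_per_octave * spec$n_octaves
  spec$low_edge * 2^((seq_len(n) - 1L) / spec$tones_per_octave)
}

#' Stationary ripple spectral envelope
#'
#' Amplitude of the spectral envelope at log-frequency position `x` octaves
#' above the low edge: `1 + depth * sin(2 * pi * density * x + phase)`.
#'
#' @param x position on the log-frequency axis in octaves (>= 0)
#' @param spec a [ripple_spec()]
#' @return envelope amplitude, bounded in `[1 - depth, 1 + depth]`
#' @export
envelope_stationary <- function(x, spec) {
  stopifnot(inherits(spec, "ripple_spec"))
  1 + spec$depth * sin(2 * pi * spec$density * x + spec$phase)
}

#' Moving ripple spectrotemporal envelope
#'
#' `1 + depth * sin(2 * pi * (velocity * t + density * x) + phase)`. At
#' `t = 0` (or `velocity = 0`) this reduces to [envelope_stationary()]
#' pointwise. With positive density and velocity the constant-phase
#' contours move downward toward lower frequencies.
#'
#' @param x position on the log-frequency axis in octaves
#' @param t time in seconds
#' @inheritParams envelope_stationary
#' @return envelope amplitude, bounded in `[1 - depth, 1 + depth]`
#' @export
envelope_moving <- function(x, t, spec) {
  stopifnot(inherits(spec, "ripple_spec"))
  1 + spec$depth * sin(2 * pi * (spec$velocity * t + spec$density * x) +
                         spec$phase)
}

#' Auditory ripple stimulus grid
#'
#' The stimulus grid for the auditory task: all combinations of ripple
#' density 0, 0.8, 1.6 cycles/octave and velocity 0, 5, 10, 20 cycles/s
#' (12 conditions), each repeated `n_repeats` times.
#'
#' @param n_repeats repeats per condition
#' @return data.frame with columns condition, density, velocity, n_repeats
#' @export
#' @examples
#' g <- auditory_stimulus_grid()
#' nrow(g); sum(g$n_repeats)
auditory_stimulus_grid <- function(n_repeats = 40) {
  g <- expand.grid(density = c(0, 0.8, 1.6), velocity = c(0, 5, 10, 20),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(condition = seq_len(nrow(g)), g, n_repeats = n_repeats)
}

#' Visual grating stimulus grid
#'
#' The stimulus grid for the visual task: full-contrast gratings at two
#' spatial frequencies (2, 4 cycles/degree) and four orientations (0, 45,
#' 90, 135 degrees), 8 conditions, each repeated `n_repeats` times.
#'
#' @param n_repeats repeats per condition
#' @return data.frame with columns condition, spatial_frequency,
#'   orientation, n_repeats
#' @export
visual_stimulus_grid <- function(n_repeats = 25) {
  g <- expand.grid(spatial_frequency = c(2, 4),
                   orientation = c(0, 45, 90, 135),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(condition = seq_len(nrow(g)), g, n_repeats = n_repeats)
}
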