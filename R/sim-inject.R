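#' Inject a band-limited power change into trials
#'
#' Changes band power during the stated window of every matching trial by
#' `delta_db` decibels. The band component of each target channel is
#' extracted by frequency-domain filtering (flat passband extended
#' `guard_hz` beyond the band edges, raised-cosine transition of
#' `transition_hz`) and rescaled by `10^(delta_db / 20)` under a ramped
#' window envelope. Because the same realization is rescaled rather than
#' independent noise added, the true band power in the fully ramped-on part
#' of the window changes by exactly `delta_db`, for positive and negative
#' changes alike; the guard band ensures the change is also unbiased when
#' band power is read off a spectral estimate whose half-bandwidth does not
#' exceed `guard_hz`. Other electrodes and frequencies outside
#' `band +/- (guard_hz + transition_hz)` are untouched.
#'
#' @param recording an [new_recording()]
#' @param events event table (defaults to `recording$events`)
#' @param band length-2 numeric band in Hz (must clear 0 and Nyquist by
#'   `guard_hz + transition_hz`)
#' @param electrodes target channel labels
#' @param delta_db band-power change in dB (0 returns the input unchanged)
#' @param window_ms effect window relative to onset (half-open)
#' @param ramp_ms raised-cosine ramp of the effect envelope inside the
#'   window
#' @param conditions condition codes to affect (`NULL` = all)
#' @param guard_hz flat-passband extension beyond the band edges
#' @param transition_hz raised-cosine transition width beyond the guard
#' @return the modified `eeg_recording`
#' @export
inject_band_response <- function(recording, events = NULL, band, electrodes,
                                 delta_db, window_ms = c(0, 800),
                                 ramp_ms = 50, conditions = NULL,
                                 guard_hz = 2, transition_hz = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (delta_db == 0) return(recording)
  fs <- recording$sampling_rate
  events <- validate_events(events %||% recording$events,
                            ncol(recording$data))
  lo <- band[1] - guard_hz - transition_hz
  hi <- band[2] + guard_hz + transition_hz
  if (lo <= 0 || hi >= fs / 2) {
    stop("band (with guard and transition) must lie strictly inside (0, Nyquist)",
         call. = FALSE)
  }
  ci <- match(electrodes, recording$channel_labels)
  if (anyNA(ci)) stop("unknown electrode label", call. = FALSE)
  gain <- function(f) {
    w <- numeric(length(f))
    flat <- f >= band[1] - guard_hz & f <= band[2] + guard_hz
    w[flat] <- 1
    rise <- f > lo & f < band[1] - guard_hz
    w[rise] <- 0.5 * (1 - cos(pi * (f[rise] - lo) / transition_hz))
    fall <- f > band[2] + guard_hz & f < hi
    w[fall] <- 0.5 * (1 + cos(pi * (f[fall] - band[2] - guard_hz) /
                                transition_hz))
    w
  }
  g <- 10^(delta_db / 20)
  offs <- window_offsets(window_ms, fs)
  env <- ramp_envelope(length(offs), ms_to_samp(ramp_ms, fs))
  use <- if (is.null(conditions)) rep(TRUE, nrow(events)) else
    events$condition %in% conditions
  onsets <- events$onset[use]
  for (k in ci) {
    b <- fft_shape(recording$data[k, ], fs, gain)
    for (on in onsets) {
      idx <- on + offs
      ok <- idx >= 1L & idx <= ncol(recording$data)
      recording$data[k, idx[ok]] <- recording$data[k, idx[ok]] +
        (g - 1) * env[ok] * b[idx[ok]]
    }
  }
  recording
}

## Hann pulse of the given width in samples, unit peak.
hann_pulse <- function(width) {
  0.5 * (1 - cos(2 * pi * (seq_len(width) - 0.5) / width))
}

#' Inject blink, spike and flat-channel artifacts
#'
#' Inserts artifacts at seeded positions and returns both the contaminated
#' recording and a ground-truth table of every affected trial. Blinks are
#' 250 ms pulses on the frontal electrodes (full amplitude at Fp1/Fp2,
#' reduced on AF and lateral frontal sites); spikes are 60 ms pulses on a
#' random electrode subset; flat segments silence the flat channel across
#' one trial's artifact-screening window (-500 to 1500 ms). Artifact
#' support is confined to -500..1000 ms around the own trial's onset so an
#' artifact never contaminates the neighbouring trial's screening window.
#'
#' @param recording an [new_recording()] with events
#' @param spec an [artifact_spec()]
#' @param seed integer seed
#' @return list with elements `recording` and `truth` (data.frame with
#'   columns trial, type, electrodes — a list column)
#' @export
inject_artifacts <- function(recording, spec, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(spec, "artifact_spec"))
  fs <- recording$sampling_rate
  events <- recording$events
  n_trials <- nrow(events)
  labels <- recording$channel_labels
  sets <- electrode_sets()
  frontal <- intersect(sets$frontal, labels)
  w_frontal <- c(Fp1 = 1, Fp2 = 1, AF7 = 0.7, AF3 = 0.7, AFz = 0.7,
                 AF4 = 0.7, AF8 = 0.7, F7 = 0.4, F8 = 0.4)[frontal]
  if (n_trials == 0L ||
      (spec$blink_rate == 0 && spec$spike_rate == 0 && spec$flat_rate == 0)) {
    return(list(recording = recording,
                truth = data.frame(trial = integer(0), type = character(0),
                                   electrodes = I(list()))))
  }
  res <- withr::with_seed(seed, {
    d <- recording$data
    truth <- list()
    flat_ch <- spec$flat_channel %||% sample(labels, 1L)
    blink_w <- ms_to_samp(250, fs)
    spike_w <- ms_to_samp(60, fs)
    for (tr in seq_len(n_trials)) {
      on <- events$onset[tr]
      if (length(frontal) && stats::runif(1) < spec$blink_rate) {
        centre <- stats::runif(1, -300, 800)
        amp <- spec$blink_amplitude * stats::runif(1, 0.8, 1.2)
        start <- on + ms_to_samp(centre, fs) - blink_w %/% 2L
        idx <- seq.int(start, start + blink_w - 1L)
        ok <- idx >= 1L & idx <= ncol(d)
        pulse <- hann_pulse(blink_w)[ok]
        for (j in seq_along(frontal)) {
          d[frontal[j], idx[ok]] <- d[frontal[j], idx[ok]] +
            amp * w_frontal[j] * pulse
        }
        truth[[length(truth) + 1L]] <- list(trial = tr, type = "blink",
                                            electrodes = frontal)
      }
      if (stats::runif(1) < spec$spike_rate) {
        centre <- stats::runif(1, -450, 950)
        chans <- sample(labels, min(spec$spike_n_channels, length(labels)))
        start <- on + ms_to_samp(centre, fs) - spike_w %/% 2L
        idx <- seq.int(start, start + spike_w - 1L)
        ok <- idx >= 1L & idx <= ncol(d)
        pulse <- hann_pulse(spike_w)[ok]
        sign_ <- sample(c(-1, 1), length(chans), replace = TRUE)
        for (j in seq_along(chans)) {
          d[chans[j], idx[ok]] <- d[chans[j], idx[ok]] +
            sign_[j] * spec$spike_amplitude * pulse
        }
        truth[[length(truth) + 1L]] <- list(trial = tr, type = "spike",
                                            electrodes = chans)
      }
      if (stats::runif(1) < spec$flat_rate) {
        idx <- on + window_offsets(c(-500, 1500), fs)
        ok <- idx >= 1L & idx <= ncol(d)
        d[flat_ch, idx[ok]] <- d[flat_ch, idx[ok]] * 0.001
        truth[[length(truth) + 1L]] <- list(trial = tr, type = "flat",
                                            electrodes = flat_ch)
      }
    }
    list(d = d, truth = truth)
  })
  recording$data <- res$d
  truth <- res$truth
  truth_df <- if (length(truth)) {
    data.frame(trial = vapply(truth, `[[`, 0L, "trial"),
               type = vapply(truth, `[[`, "", "type"),
               electrodes = I(lapply(truth, `[[`, "electrodes")))
  } else {
    data.frame(trial = integer(0), type = character(0),
               electrodes = I(list()))
  }
  list(recording = recording, truth = truth_df)
}
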