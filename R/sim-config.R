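#' Band-power effect specification for the simulator
#'
#' Describes one injected band-power change: during `window_ms` of every
#' matching trial, the power of the background in `band` on the listed
#' electrodes is changed by `delta_db` decibels (negative values attenuate).
#'
#' @param band length-2 numeric, band edges in Hz
#' @param electrodes character vector of target electrode labels
#' @param delta_db target band-power change in dB relative to baseline
#' @param window_ms effect window relative to stimulus onset (half-open)
#' @param ramp_ms raised-cosine on/off ramp of the effect envelope
#' @param conditions integer condition codes the effect applies to
#'   (`NULL` = all)
#' @return object of class `band_effect`
#' @export
band_effect <- function(band, electrodes, delta_db, window_ms = c(0, 800),
                        ramp_ms = 50, conditions = NULL) {
  stopifnot(length(band) == 2L, band[1] < band[2], band[1] > 0)
  structure(list(band = band, electrodes = electrodes, delta_db = delta_db,
                 window_ms = window_ms, ramp_ms = ramp_ms,
                 conditions = conditions),
            class = "band_effect")
}

#' Artifact rates and amplitudes for the simulator
#'
#' Blinks are slow high-amplitude pulses on the frontal electrodes; spikes
#' are brief high-amplitude transients hitting a random subset of
#' electrodes (muscle/movement-like); flat segments silence one designated
#' channel for the whole artifact-screening window of a trial. All rates
#' are per-trial probabilities.
#'
#' @param blink_rate per-trial blink probability
#' @param blink_amplitude blink peak amplitude in microvolts (per-event
#'   amplitudes vary uniformly within +/-20%)
#' @param spike_rate per-trial spike probability
#' @param spike_amplitude spike peak amplitude in microvolts
#' @param spike_n_channels number of electrodes hit by each spike
#' @param flat_rate per-trial probability of a flat segment on the flat
#'   channel
#' @param flat_channel label of the channel carrying flat segments
#'   (`NULL` = drawn at random per session)
#' @return object of class `artifact_spec`
#' @export
artifact_spec <- function(blink_rate = 0.05, blink_amplitude = 350,
                          spike_rate = 0.03, spike_amplitude = 500,
                          spike_n_channels = 12, flat_rate = 0.02,
                          flat_channel = NULL) {
  stopifnot(blink_rate >= 0, spike_rate >= 0, flat_rate >= 0)
  structure(list(blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 spike_rate = spike_rate, spike_amplitude = spike_amplitude,
                 spike_n_channels = spike_n_channels, flat_rate = flat_rate,
                 flat_channel = flat_channel),
            class = "artifact_spec")
}

#' Eye-movement behaviour for the simulator
#'
#' @param break_rate per-trial probability of a fixation break (a step
#'   excursion beyond the fixation window during the checked interval)
#' @param excursion_deg excursion size in degrees (> 2.5 to violate the
#'   5-degree square window)
#' @param duration_ms excursion duration (>= 50 ms)
#' @param noise_sd_deg standard deviation of slow fixational jitter
#' @return object of class `eye_spec`
#' @export
eye_spec <- function(break_rate = 0.05, excursion_deg = 4,
                     duration_ms = 120, noise_sd_deg = 0.1) {
  stopifnot(break_rate >= 0, excursion_deg > 0, duration_ms >= 50)
  structure(list(break_rate = break_rate, excursion_deg = excursion_deg,
                 duration_ms = duration_ms, noise_sd_deg = noise_sd_deg),
            class = "eye_spec")
}

#' Simulator session configuration
#'
#' Defines a synthetic EEG session: montage, sampling, trial structure
#' (continuous stimulus train of `stimulus_duration` followed by
#' `interstimulus_interval`), 1/f background, injected band effects,
#' artifact statistics, eye behaviour and electrode impedances.
#'
#' @param channel_labels montage labels (defaults to the 64-channel 10-10
#'   set)
#' @param sampling_rate sampling rate in Hz
#' @param condition_table data.frame with columns `condition` and
#'   `n_trials`
#' @param stimulus_duration stimulus length in seconds
#' @param interstimulus_interval gap between stimuli in seconds
#' @param background_exponent exponent alpha of the 1/f^alpha background
#' @param background_rms per-channel background RMS in microvolts
#' @param band_effects list of [band_effect()] objects
#' @param artifacts an [artifact_spec()], or `NULL` for a clean session
#' @param eye an [eye_spec()], or `NULL` (e.g. an eyes-closed session
#'   without eye tracking)
#' @param impedances electrode impedances in kOhm (scalar recycled or one
#'   per channel)
#' @param lead_in_s silence-free background time before the first stimulus
#'   and after the last one, in seconds
#' @return object of class `sim_config`
#' @export
#' @examples
#' cfg <- sim_config(condition_table = data.frame(condition = 1:2,
#'                                                n_trials = 10))
sim_config <- function(channel_labels = acticap64_labels(),
                       sampling_rate = 1000,
                       condition_table = data.frame(condition = 1L,
                                                    n_trials = 40L),
                       stimulus_duration = 0.8,
                       interstimulus_interval = 0.8,
                       background_exponent = 1.0,
                       background_rms = 10,
                       band_effects = list(),
                       artifacts = NULL,
                       eye = NULL,
                       impedances = 7,
                       lead_in_s = 2) {
  stopifnot(is.data.frame(condition_table),
            all(c("condition", "n_trials") %in% names(condition_table)),
            all(condition_table$n_trials > 0),
            sampling_rate > 0, background_rms > 0,
            background_exponent >= 0)
  nyq <- sampling_rate / 2
  for (ef in band_effects) {
    stopifnot(inherits(ef, "band_effect"))
    if (ef$band[2] >= nyq) stop("effect band exceeds Nyquist", call. = FALSE)
    if (!all(ef$electrodes %in% channel_labels)) {
      stop("effect electrodes not in montage", call. = FALSE)
    }
  }
  if (length(impedances) == 1L) {
    impedances <- rep(impedances, length(channel_labels))
  }
  stopifnot(length(impedances) == length(channel_labels))
  structure(list(channel_labels = channel_labels,
                 sampling_rate = sampling_rate,
                 condition_table = condition_table,
                 stimulus_duration = stimulus_duration,
                 interstimulus_interval = interstimulus_interval,
                 background_exponent = background_exponent,
                 background_rms = background_rms,
                 band_effects = band_effects, artifacts = artifacts,
                 eye = eye, impedances = impedances, lead_in_s = lead_in_s),
            class = "sim_config")
}

#' Canonical frequency bands
#'
#' Band edges (Hz) used throughout: alpha 8-12, beta 14-26, narrowband
#' gamma 20-66, broadband high-gamma 70-150.
#'
#' @return named list of length-2 numeric vectors
#' @export
canonical_bands <- function() {
  list(alpha = c(8, 12), beta = c(14, 26), narrowband_gamma = c(20, 66),
       high_gamma = c(70, 150))
}

#' Default visual-task session configuration
#'
#' Emulates a visual grating session: 8 conditions x 25 trials (800 ms
#' stimulus, 700 ms gap), occipital narrowband-gamma increase (+1 dB,
#' 20-66 Hz) with alpha suppression (-1 dB, 8-12 Hz), default artifacts and
#' eye behaviour.
#'
#' @param n_repeats trials per condition
#' @param gamma_db,alpha_db injected band changes in dB
#' @param artifacts,eye see [sim_config()]
#' @param channels montage labels; effect electrode sets are intersected
#'   with this, so a reduced montage keeps the same study conditions
#' @return a `sim_config`
#' @export
visual_sim_config <- function(n_repeats = 25, gamma_db = 1, alpha_db = -1,
                              artifacts = artifact_spec(),
                              eye = eye_spec(),
                              channels = acticap64_labels()) {
  grid <- visual_stimulus_grid(n_repeats)
  sets <- electrode_sets()
  alpha_set <- union(sets$visual_unipolar, sets$occipital_group)
  sim_config(
    channel_labels = channels,
    condition_table = data.frame(condition = grid$condition,
                                 n_trials = grid$n_repeats),
    interstimulus_interval = 0.7,
    band_effects = list(
      band_effect(canonical_bands()$narrowband_gamma,
                  intersect(sets$visual_unipolar, channels), gamma_db),
      band_effect(canonical_bands()$alpha, intersect(alpha_set, channels),
                  alpha_db)),
    artifacts = artifacts, eye = eye)
}

#' Default auditory-task session configuration
#'
#' Emulates an auditory ripple session: 12 conditions x 40 trials (800 ms
#' stimulus, 800 ms gap), temporal broadband high-gamma increase (+0.1 dB,
#' 70-150 Hz) with widespread beta suppression (-0.3 dB, 14-26 Hz). The
#' eyes-closed default carries no eye trace.
#'
#' @param n_repeats trials per condition
#' @param high_gamma_db,beta_db injected band changes in dB
#' @param artifacts,eye see [sim_config()]
#' @param channels montage labels; effect electrode sets are intersected
#'   with this, so a reduced montage keeps the same study conditions
#' @return a `sim_config`
#' @export
auditory_sim_config <- function(n_repeats = 40, high_gamma_db = 0.1,
                                beta_db = -0.3,
                                artifacts = artifact_spec(), eye = NULL,
                                channels = acticap64_labels()) {
  grid <- auditory_stimulus_grid(n_repeats)
  sets <- electrode_sets()
  sim_config(
    channel_labels = channels,
    condition_table = data.frame(condition = grid$condition,
                                 n_trials = grid$n_repeats),
    interstimulus_interval = 0.8,
    band_effects = list(
      band_effect(canonical_bands()$high_gamma,
                  intersect(sets$auditory_unipolar, channels),
                  high_gamma_db),
      band_effect(canonical_bands()$beta, channels, beta_db)),
    artifacts = artifacts, eye = eye)
}
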