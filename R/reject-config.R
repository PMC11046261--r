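#' Artifact-rejection cascade configuration
#'
#' Thresholds and electrode sets for the automated rejection cascade. All
#' comparisons are strict: an electrode at exactly 25 kOhm, a bad-trial
#' fraction of exactly 30%, a trial flagged on exactly 10% of electrodes,
#' a surviving group fraction of exactly 50% and a fitted slope of exactly
#' 0 are all kept.
#'
#' @param impedance_max electrodes with impedance strictly above this
#'   (kOhm) are discarded
#' @param highpass_cutoff high-pass cutoff (Hz) applied before the trial
#'   RMS screen, removing slow drifts
#' @param rms_window_ms screening window relative to stimulus onset
#' @param rms_bounds (lower, upper) RMS bounds in microvolts; trials
#'   outside the open interval are flagged
#' @param psd_sd_mult deviation multiplier of the per-frequency PSD
#'   outlier rule
#' @param psd_freq_range frequency range (Hz) screened by the PSD rule
#' @param psd_log apply the PSD outlier rule on log10 power (see the
#'   methods vignette; set `FALSE` for linear power)
#' @param psd_nw,psd_k taper parameters of the multitaper PSD behind the
#'   outlier rule (time-bandwidth 3 with 5 tapers, the standard multitaper
#'   family; see the methods vignette for why a single taper is not used
#'   here)
#' @param electrode_bad_frac electrodes with more than this fraction of
#'   trials flagged are discarded
#' @param trial_bad_frac trials flagged on more than this fraction of the
#'   remaining electrodes join the common bad set
#' @param priority_electrodes list of electrode label sets whose surviving
#'   members force any of their flagged trials into the common bad set
#' @param slope_range frequency range (Hz) of the baseline-PSD power-law
#'   slope fit
#' @param slope_min electrodes with fitted slope strictly below this are
#'   discarded
#' @param group_electrodes named list of group sets (`visual`,
#'   `auditory`) for the subject-level verdict
#' @param subject_min_frac subjects with a surviving group fraction
#'   strictly below this are rejected for that task
#' @return object of class `rejection_config`
#' @export
rejection_config <- function(impedance_max = 25,
                             highpass_cutoff = 1.6,
                             rms_window_ms = c(-500, 1500),
                             rms_bounds = c(1.5, 35),
                             psd_sd_mult = 6,
                             psd_freq_range = c(0, 200),
                             psd_log = TRUE,
                             psd_nw = 3, psd_k = 5,
                             electrode_bad_frac = 0.30,
                             trial_bad_frac = 0.10,
                             priority_electrodes = list(
                               visual = electrode_sets()$visual_priority,
                               auditory = electrode_sets()$auditory_priority),
                             slope_range = c(56, 86),
                             slope_min = 0,
                             group_electrodes = list(
                               visual = electrode_sets()$occipital_group,
                               auditory = electrode_sets()$temporal_group),
                             subject_min_frac = 0.5) {
  stopifnot(rms_bounds[1] < rms_bounds[2],
            electrode_bad_frac > 0, electrode_bad_frac < 1,
            trial_bad_frac > 0, trial_bad_frac < 1,
            subject_min_frac > 0, subject_min_frac < 1,
            psd_sd_mult > 0, slope_range[1] < slope_range[2])
  structure(list(impedance_max = impedance_max,
                 highpass_cutoff = highpass_cutoff,
                 rms_window_ms = rms_window_ms, rms_bounds = rms_bounds,
                 psd_sd_mult = psd_sd_mult,
                 psd_freq_range = psd_freq_range, psd_log = psd_log,
                 psd_nw = psd_nw, psd_k = psd_k,
                 electrode_bad_frac = electrode_bad_frac,
                 trial_bad_frac = trial_bad_frac,
                 priority_electrodes = priority_electrodes,
                 slope_range = slope_range, slope_min = slope_min,
                 group_electrodes = group_electrodes,
                 subject_min_frac = subject_min_frac),
            class = "rejection_config")
}
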