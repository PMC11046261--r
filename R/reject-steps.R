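#' Discard electrodes by impedance
#'
#' Electrodes whose impedance is strictly above `impedance_max` kOhm are
#' discarded. Electrodes without an impedance value are kept with a
#' warning.
#'
#' @param recording an [new_recording()] with impedance metadata
#' @param config a [rejection_config()]
#' @return character vector of discarded electrode labels
#' @export
impedance_reject <- function(recording, config = rejection_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  imp <- recording$impedances
  if (is.null(imp)) {
    warning("no impedance metadata; keeping all electrodes", call. = FALSE)
    return(character(0))
  }
  if (anyNA(imp)) {
    warning("missing impedance for ",
            paste(recording$channel_labels[is.na(imp)], collapse = ", "),
            "; those electrodes are kept", call. = FALSE)
  }
  recording$channel_labels[!is.na(imp) & imp > config$impedance_max]
}

## High-pass Butterworth (order 4, zero phase) used by the RMS screen.
highpass_epochs <- function(x, fs, cutoff) {
  if (cutoff >= fs / 2) stop("high-pass cutoff at or above Nyquist",
                             call. = FALSE)
  bt <- signal::butter(4, cutoff / (fs / 2), type = "high")
  y <- zero_phase_filter(x, bt$b, bt$a)
  if (anyNA(y)) stop("high-pass filter unstable at this sampling rate",
                     call. = FALSE)
  y
}

## Trial x electrode RMS of the high-passed screening window. Filtered one
## electrode at a time to keep the temporaries small on large sessions.
trial_rms <- function(epochs, config) {
  idx <- subwindow_index(epochs, config$rms_window_ms)
  n_tr <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]
  rms <- matrix(NA_real_, n_tr, n_ch,
                dimnames = list(NULL, epochs$channel_labels))
  for (ch in seq_len(n_ch)) {
    x <- t(epochs$data[, ch, idx, drop = TRUE])
    if (n_tr == 1L) x <- matrix(x, ncol = 1L)
    y <- highpass_epochs(x, epochs$sampling_rate, config$highpass_cutoff)
    rms[, ch] <- sqrt(colMeans(y^2))
  }
  rms
}

#' Flag trials by RMS amplitude bounds
#'
#' Per electrode, computes the RMS of each trial's screening window
#' (-500 to 1500 ms by default) after a 1.6 Hz zero-phase high-pass, and
#' flags trials whose RMS lies outside the open interval given by
#' `rms_bounds` (default 1.5-35 uV): large values indicate movement or
#' muscle artifacts, small values a flat or disconnected channel.
#'
#' @param epochs an [epoch()] result covering the screening window
#' @param config a [rejection_config()]
#' @return named list (one element per electrode) of flagged trial ids,
#'   each with a `reason` attribute (`"rms_high"` / `"rms_low"`); the RMS
#'   matrix is attached as attribute `rms`
#' @export
rms_reject <- function(epochs, config = rejection_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  rms <- trial_rms(epochs, config)
  out <- lapply(seq_len(ncol(rms)), function(ch) {
    hi <- rms[, ch] > config$rms_bounds[2]
    lo <- rms[, ch] < config$rms_bounds[1]
    ids <- epochs$trial_ids[hi | lo]
    structure(ids, reason = ifelse(hi[hi | lo], "rms_high", "rms_low"))
  })
  names(out) <- epochs$channel_labels
  attr(out, "rms") <- rms
  out
}

#' Flag trials as per-frequency PSD outliers
#'
#' Per electrode, computes a multitaper PSD of each trial's screening
#' window (time-bandwidth 3, 5 tapers by default), and flags any trial
#' whose power deviates from the across-trial mean by more than
#' `psd_sd_mult` standard deviations at any frequency bin inside
#' `psd_freq_range`. All trials (including the candidate) enter the mean
#' and SD, which bounds the attainable standardized deviation at
#' `(n - 1) / sqrt(n)`. The rule is applied to log10 power by default
#' (`psd_log`); taper averaging and the log transform together keep the
#' false-flag rate of clean Gaussian trials negligible at the 6-SD
#' threshold.
#'
#' @inheritParams rms_reject
#' @return named list of flagged trial ids per electrode
#' @export
psd_outlier_reject <- function(epochs, config = rejection_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- dim(epochs$data)[1]
  if (n_tr < 3L) {
    warning("fewer than 3 trials; PSD outlier screen skipped", call. = FALSE)
    out <- rep(list(integer(0)), dim(epochs$data)[2])
    names(out) <- epochs$channel_labels
    return(out)
  }
  ## one electrode at a time: the per-trial PSD batch of a whole session
  ## would otherwise dominate memory
  out <- lapply(epochs$channel_labels, function(ch) {
    est <- multitaper_psd(subset_epochs(epochs, channels = ch),
                          config$rms_window_ms, nw = config$psd_nw,
                          k = config$psd_k)
    bins <- which(est$freqs >= config$psd_freq_range[1] &
                    est$freqs <= config$psd_freq_range[2])
    p <- est$power[, 1, bins, drop = TRUE]
    if (n_tr == 1L) p <- matrix(p, nrow = 1L)
    if (config$psd_log) p <- log10(pmax(p, .Machine$double.xmin))
    m <- colMeans(p)
    s <- sqrt(colSums(sweep(p, 2, m)^2) / (n_tr - 1L))
    dev <- abs(sweep(p, 2, m))
    flag <- rowSums(dev > config$psd_sd_mult * rep(s, each = n_tr)) > 0L
    epochs$trial_ids[flag]
  })
  names(out) <- epochs$channel_labels
  out
}

#' Fit the aperiodic power-law slope of a PSD
#'
#' Fits `P(f) = A * f^(-slope)` by least squares on `(log f, log P)` over
#' the bins inside `freq_range` and returns the slope. The cascade
#' discards electrodes whose baseline slope over 56-86 Hz is strictly
#' negative (rising spectra there indicate broadband noise).
#'
#' @param freqs frequency grid in Hz
#' @param power PSD values (same length as `freqs`), strictly positive in
#'   range
#' @param freq_range fit range in Hz (endpoints inclusive)
#' @return fitted slope (positive for decaying spectra)
#' @export
#' @examples
#' f <- seq(2, 200, by = 2)
#' fit_spectral_slope(f, f^-2)  # exactly 2
fit_spectral_slope <- function(freqs, power, freq_range = c(56, 86)) {
  keep <- freqs >= freq_range[1] & freqs <= freq_range[2]
  if (sum(keep) < 3L) stop("need >= 3 frequency bins in the fit range",
                           call. = FALSE)
  p <- power[keep]
  if (any(p <= 0)) stop("non-positive power in the fit range", call. = FALSE)
  -unname(stats::coef(stats::lm(log(p) ~ log(freqs[keep])))[2])
}

#' Consolidate per-electrode flags into electrode and trial rejections
#'
#' Applies the printed consolidation rules to the per-electrode bad-trial
#' lists: (1) electrodes with more than `electrode_bad_frac` of all
#' repeats flagged are discarded; (2) a trial flagged on more than
#' `trial_bad_frac` of the remaining electrodes joins the common bad set;
#' (3) any trial flagged on any surviving priority electrode also joins
#' the common bad set.
#'
#' @param badlists named list of flagged trial ids per electrode (the
#'   union of the RMS and PSD screens)
#' @param trial_ids ids of all screened trials
#' @param config a [rejection_config()]
#' @return list with `discarded_electrodes` (by bad fraction),
#'   `common_bad_trials`, and the per-electrode `bad_fraction`
#' @export
consolidate <- function(badlists, trial_ids, config = rejection_config()) {
  if (!length(badlists)) stop("no electrodes to consolidate", call. = FALSE)
  n_rep <- length(trial_ids)
  frac <- vapply(badlists, function(b) length(unique(b)) / n_rep, 0)
  discarded <- names(badlists)[frac > config$electrode_bad_frac]
  remaining <- setdiff(names(badlists), discarded)
  if (!length(remaining)) stop("all electrodes discarded by bad fraction",
                               call. = FALSE)
  counts <- table(factor(unlist(badlists[remaining], use.names = FALSE),
                         levels = trial_ids))
  common <- as.integer(names(counts))[as.integer(counts) / length(remaining) >
                                        config$trial_bad_frac]
  priority <- intersect(unique(unlist(config$priority_electrodes)), remaining)
  common <- sort(unique(c(common,
                          unlist(badlists[priority], use.names = FALSE))))
  list(discarded_electrodes = discarded,
       common_bad_trials = as.integer(common), bad_fraction = frac)
}

#' Subject-level verdict per task
#'
#' A subject is rejected for a task when strictly fewer than
#' `subject_min_frac` of that task's group electrodes survive the cascade.
#'
#' @param surviving character vector of surviving electrode labels
#' @param config a [rejection_config()]
#' @return named logical vector (`TRUE` = keep), one element per task
#' @export
reject_subject <- function(surviving, config = rejection_config()) {
  vapply(config$group_electrodes, function(grp) {
    length(intersect(surviving, grp)) / length(grp) >= config$subject_min_frac
  }, TRUE)
}
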