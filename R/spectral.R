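## Core taper-and-FFT step: x is an n_samp x m matrix of segments (columns),
## returns (one-sided) PSD matrix n_freq x m in uV^2/Hz, averaged over the
## k tapers. One-sided scaling doubles every bin except DC (and Nyquist for
## even n), so that sum(psd) * df equals the taper-weighted variance.
## Columns are processed in blocks to bound the size of the complex FFT
## temporaries on large trial x channel batches.
taper_psd_core <- function(x, fs, nw, k, block = 4096L) {
  n <- nrow(x)
  m <- ncol(x)
  tapers <- dpss_tapers(n, nw, k)
  n_freq <- n %/% 2L + 1L
  scale <- rep(2, n_freq)
  scale[1] <- 1
  if (n %% 2L == 0L) scale[n_freq] <- 1
  out <- matrix(0, n_freq, m)
  for (start in seq.int(1L, m, by = block)) {
    cols <- seq.int(start, min(start + block - 1L, m))
    acc <- matrix(0, n_freq, length(cols))
    for (j in seq_len(k)) {
      X <- stats::mvfft(x[, cols, drop = FALSE] * tapers[, j])
      acc <- acc + (Mod(X[seq_len(n_freq), , drop = FALSE])^2) / fs
    }
    out[, cols] <- (acc / k) * scale
  }
  out
}

## Offsets of a sub-window inside an epoch_set's stored sample axis.
subwindow_index <- function(epochs, window_ms) {
  stop_if_not_window(window_ms)
  fs <- epochs$sampling_rate
  e0 <- ms_to_samp(epochs$window[1], fs)
  w0 <- ms_to_samp(window_ms[1], fs)
  w1 <- ms_to_samp(window_ms[2], fs)
  if (w0 < e0 || w1 > ms_to_samp(epochs$window[2], fs)) {
    stop("analysis window lies outside the epoch window", call. = FALSE)
  }
  seq.int(w0 - e0 + 1L, w1 - e0)
}

#' Multitaper power spectral density per trial and electrode
#'
#' Computes the PSD of the given analysis window of every trial and
#' channel using discrete prolate spheroidal tapers. No zero-padding is
#' applied, so the frequency spacing equals the reciprocal of the window
#' length (500 ms windows give exactly 2 Hz resolution). The default
#' single taper is the DPSS taper with time-bandwidth product 1.
#'
#' @param epochs an [epoch()] result
#' @param window_ms analysis window (half-open) relative to stimulus
#'   onset; must lie inside the epoch window
#' @param nw taper time-bandwidth product
#' @param k number of tapers
#' @return object of class `spectral_estimate`: `freqs` (Hz), `power`
#'   (trials x channels x frequencies, uV^2/Hz), plus window and taper
#'   metadata
#' @export
#' @examples
#' rec <- new_recording(matrix(rnorm(4000), 1), 1000, "Oz",
#'                      events = data.frame(onset = 2000, condition = 1L))
#' ep <- epoch(rec, c(-848, 1650))
#' est <- multitaper_psd(ep, c(-500, 0))
#' diff(est$freqs)[1]
multitaper_psd <- function(epochs, window_ms, nw = 1, k = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- subwindow_index(epochs, window_ms)
  if (length(idx) < 2L) stop("analysis window must span >= 2 samples",
                             call. = FALSE)
  fs <- epochs$sampling_rate
  d <- epochs$data[, , idx, drop = FALSE]
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_samp <- dim(d)[3]
  x <- matrix(aperm(d, c(3, 1, 2)), nrow = n_samp)
  p <- taper_psd_core(x, fs, nw, k)
  n_freq <- nrow(p)
  power <- aperm(array(t(p), dim = c(n_tr, n_ch, n_freq)), c(1, 2, 3))
  dimnames(power) <- list(NULL, epochs$channel_labels, NULL)
  structure(list(freqs = seq.int(0L, n_freq - 1L) * (fs / n_samp),
                 power = power, window = window_ms,
                 taper_params = c(nw = nw, k = k), sampling_rate = fs,
                 channel_labels = epochs$channel_labels,
                 trial_condition = epochs$trial_condition,
                 trial_ids = epochs$trial_ids),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "Spectral estimate: %d trials x %d channels x %d freqs (0-%g Hz, %g Hz spacing)\n",
    dim(x$power)[1], dim(x$power)[2], dim(x$power)[3], max(x$freqs),
    x$freqs[2] - x$freqs[1]))
  cat(sprintf("  window %g..%g ms, DPSS nw=%g k=%d\n", x$window[1],
              x$window[2], x$taper_params["nw"], x$taper_params["k"]))
  invisible(x)
}

#' Sliding-window multitaper spectrogram
#'
#' Time-frequency estimate from a moving analysis window. Time stamps are
#' window centres; the frequency spacing is the reciprocal of the window
#' length (250 ms windows give exactly 4 Hz).
#'
#' @param epochs an [epoch()] result
#' @param window_ms moving-window length in ms
#' @param step_ms step between consecutive windows in ms (must not exceed
#'   the window length)
#' @inheritParams multitaper_psd
#' @return object of class `tfr_estimate`: `times` (ms, window centres),
#'   `freqs` (Hz), `power` (trials x channels x times x freqs)
#' @export
spectrogram <- function(epochs, window_ms = 250, step_ms = 25, nw = 1,
                        k = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (step_ms > window_ms) stop("step must not exceed the window length",
                                call. = FALSE)
  ep_win <- epochs$window
  if (diff(ep_win) < window_ms) {
    stop("epoch shorter than one analysis window", call. = FALSE)
  }
  starts <- seq(ep_win[1], ep_win[2] - window_ms, by = step_ms)
  fs <- epochs$sampling_rate
  n_tr <- dim(epochs$data)[1]; n_ch <- dim(epochs$data)[2]
  cols <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    est <- multitaper_psd(epochs, c(starts[i], starts[i] + window_ms),
                          nw = nw, k = k)
    cols[[i]] <- est$power
    if (i == 1L) freqs <- est$freqs
  }
  power <- array(NA_real_,
                 dim = c(n_tr, n_ch, length(starts), length(freqs)),
                 dimnames = list(NULL, epochs$channel_labels, NULL, NULL))
  for (i in seq_along(cols)) power[, , i, ] <- cols[[i]]
  structure(list(times = starts + window_ms / 2, freqs = freqs,
                 power = power, window_ms = window_ms, step_ms = step_ms,
                 taper_params = c(nw = nw, k = k), sampling_rate = fs,
                 channel_labels = epochs$channel_labels,
                 trial_condition = epochs$trial_condition,
                 trial_ids = epochs$trial_ids),
            class = "tfr_estimate")
}

#' Baseline-normalized band-power change in decibels
#'
#' The band-power change statistic: power is averaged across trials (and
#' the selected electrodes), summed over the band's frequency bins
#' (endpoints inclusive), and the stimulus/baseline ratio is expressed in
#' dB as `10 * log10(sum ST(f) / sum BL(f))`.
#'
#' @param stim spectral estimate of the stimulus window
#' @param base spectral estimate of the baseline window (identical
#'   frequency grid)
#' @param band length-2 numeric band in Hz
#' @param electrodes electrode labels to pool (default: all channels of
#'   the estimates)
#' @param conditions condition codes to pool (default: all trials)
#' @return object of class `band_power_change`: `delta_db` (electrode-
#'   pooled change), `per_electrode` (named vector of per-electrode
#'   changes), `band`, `n_trials`
#' @export
#' @examples
#' # ST = 2 * BL at every bin gives 10 * log10(2) dB
delta_power <- function(stim, base, band, electrodes = NULL,
                        conditions = NULL) {
  stopifnot(inherits(stim, "spectral_estimate"),
            inherits(base, "spectral_estimate"))
  if (length(stim$freqs) != length(base$freqs) ||
      any(stim$freqs != base$freqs)) {
    stop("stimulus and baseline estimates must share one frequency grid",
         call. = FALSE)
  }
  bins <- which(stim$freqs >= band[1] & stim$freqs <= band[2])
  if (!length(bins)) stop("band contains no frequency bins", call. = FALSE)
  electrodes <- electrodes %||% stim$channel_labels
  ci <- match(electrodes, stim$channel_labels)
  if (anyNA(ci)) stop("unknown electrode label", call. = FALSE)
  pick <- function(est) {
    ti <- if (is.null(conditions)) seq_len(dim(est$power)[1]) else
      which(est$trial_condition %in% conditions)
    if (!length(ti)) stop("no trials for the requested conditions",
                          call. = FALSE)
    est$power[ti, ci, bins, drop = FALSE]
  }
  st <- pick(stim)
  bl <- pick(base)
  ## trial-averaged band sums per electrode
  st_e <- apply(st, 2, function(m) sum(colMeans(m)))
  bl_e <- apply(bl, 2, function(m) sum(colMeans(m)))
  if (any(bl_e <= 0)) stop("baseline band power must be positive",
                           call. = FALSE)
  per_electrode <- 10 * log10(st_e / bl_e)
  names(per_electrode) <- electrodes
  structure(list(band = band, delta_db = 10 * log10(mean(st_e) / mean(bl_e)),
                 per_electrode = per_electrode, electrodes = electrodes,
                 n_trials = c(stim = dim(st)[1], base = dim(bl)[1])),
            class = "band_power_change")
}

#' @export
print.band_power_change <- function(x, ...) {
  cat(sprintf("Band power change %g-%g Hz: %+.3f dB (pooled over %d electrodes, %d trials)\n",
              x$band[1], x$band[2], x$delta_db, length(x$per_electrode),
              x$n_trials["stim"]))
  invisible(x)
}

#' Baseline-normalized change spectrogram
#'
#' Converts a time-frequency estimate into dB change relative to the mean
#' baseline power at each frequency: every (time, frequency) cell becomes
#' `10 * log10(power / mean baseline power)` after trial averaging.
#' Baseline columns are the windows fully contained in `baseline_ms`.
#'
#' @param tfr a [spectrogram()] result
#' @param baseline_ms baseline interval (half-open) relative to onset
#' @return object of class `tfr_change`: `change` is a channels x times x
#'   freqs array in dB
#' @export
change_spectrogram <- function(tfr, baseline_ms = c(-500, 0)) {
  stopifnot(inherits(tfr, "tfr_estimate"))
  stop_if_not_window(baseline_ms)
  half <- tfr$window_ms / 2
  base_cols <- which(tfr$times - half >= baseline_ms[1] &
                       tfr$times + half <= baseline_ms[2])
  if (!length(base_cols)) stop("no spectrogram columns lie inside the baseline",
                               call. = FALSE)
  avg <- apply(tfr$power, c(2, 3, 4), mean)      # channels x times x freqs
  bl <- apply(avg[, base_cols, , drop = FALSE], c(1, 3), mean)
  if (any(bl <= 0)) stop("zero baseline power", call. = FALSE)
  change <- 10 * log10(sweep(avg, c(1, 3), bl, "/"))
  structure(list(times = tfr$times, freqs = tfr$freqs, change = change,
                 baseline_ms = baseline_ms, base_cols = base_cols,
                 channel_labels = tfr$channel_labels),
            class = "tfr_change")
}

#' Electrode with the most robust band response
#'
#' Returns the candidate electrode with the maximum band-power change.
#' Exact ties are broken by the first label in canonical montage order
#' (the order the changes are stored in) and reported with a message.
#'
#' @param change a [delta_power()] result
#' @param candidates candidate labels (default: all electrodes of
#'   `change`)
#' @return single electrode label
#' @export
best_electrode <- function(change, candidates = NULL) {
  stopifnot(inherits(change, "band_power_change"))
  candidates <- candidates %||% names(change$per_electrode)
  vals <- change$per_electrode[candidates]
  if (anyNA(match(candidates, names(change$per_electrode)))) {
    stop("candidate not among the estimated electrodes", call. = FALSE)
  }
  if (all(!is.finite(vals))) stop("all candidate values are non-finite",
                                  call. = FALSE)
  top <- which(vals == max(vals[is.finite(vals)]))
  if (length(top) > 1L) {
    message("tie for best electrode broken by canonical label order")
  }
  candidates[top[1]]
}
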