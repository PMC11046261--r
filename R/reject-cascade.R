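#' Run the full automated artifact-rejection cascade
#'
#' Executes the rejection stages in order — impedance, fixation-break
#' filter (when an eye trace is supplied), trial RMS bounds, per-frequency
#' PSD outliers, electrode/trial consolidation with priority electrodes,
#' baseline-PSD slope, manual exclusions, subject verdict — and returns a
#' report recording which stage flagged each item.
#'
#' @param recording an [new_recording()] with events and impedances
#' @param config a [rejection_config()]
#' @param eye optional [eye_trace()]; when given, fixation-break trials
#'   are removed before the EEG screens
#' @param manual_bad_electrodes user-supplied electrode exclusions applied
#'   after the automated stages (never automated)
#' @param epoch_window_ms epoching window; must cover the RMS screening
#'   window and the baseline used by the slope fit
#' @param baseline_ms baseline window for the slope criterion
#' @return object of class `rejection_report`; see Details
#' @details The report contains `bad_trials_by_electrode` (with reason
#'   codes), `discarded_electrodes` (with the discarding stage),
#'   `common_bad_trials`, `eye_bad_trials`, `surviving_electrodes`,
#'   `good_trials`, `subject_verdict` (keep/reject per task), and
#'   `n_trials`. Discarded electrodes appear in no downstream set.
#' @export
run_rejection_cascade <- function(recording, config = rejection_config(),
                                  eye = NULL,
                                  manual_bad_electrodes = character(0),
                                  epoch_window_ms = c(-848, 1650),
                                  baseline_ms = c(-500, 0)) {
  stopifnot(inherits(recording, "eeg_recording"))
  n_events <- nrow(recording$events)
  if (!n_events) stop("recording has no events", call. = FALSE)

  ## Stage 1: impedance
  imp_discarded <- impedance_reject(recording, config)

  ## Stage 2: fixation breaks
  eye_bad <- integer(0)
  if (!is.null(eye)) {
    eye_bad <- as.integer(reject_fixation_breaks(eye, recording$events))
  }

  epochs <- epoch(recording, epoch_window_ms)
  keep_trials <- setdiff(epochs$trial_ids, eye_bad)
  keep_channels <- setdiff(recording$channel_labels, imp_discarded)
  epochs <- subset_epochs(epochs, trials = keep_trials,
                          channels = keep_channels)

  ## Stages 3-4: RMS bounds and PSD outliers
  rms_bad <- rms_reject(epochs, config)
  psd_bad <- psd_outlier_reject(epochs, config)
  badlists <- lapply(keep_channels, function(ch) {
    sort(unique(c(as.integer(rms_bad[[ch]]), as.integer(psd_bad[[ch]]))))
  })
  names(badlists) <- keep_channels

  ## Stage 5: consolidation (30% electrodes, 10% trials, priority union)
  cons <- consolidate(badlists, epochs$trial_ids, config)

  ## Stage 6: baseline-PSD slope on good trials of each remaining electrode
  remaining <- setdiff(keep_channels, cons$discarded_electrodes)
  base_est <- multitaper_psd(subset_epochs(epochs, channels = remaining),
                             baseline_ms, nw = 1, k = 1)
  slopes <- vapply(remaining, function(ch) {
    good <- setdiff(epochs$trial_ids,
                    union(badlists[[ch]], cons$common_bad_trials))
    rows <- match(good, base_est$trial_ids)
    if (!length(rows)) return(NA_real_)
    avg <- apply(base_est$power[rows, ch, , drop = FALSE], 3, mean)
    fit_spectral_slope(base_est$freqs, avg, config$slope_range)
  }, 0)
  slope_discarded <- remaining[!is.na(slopes) & slopes < config$slope_min]

  ## Stage 7: manual exclusions
  manual <- intersect(manual_bad_electrodes, recording$channel_labels)

  surviving <- setdiff(remaining, union(slope_discarded, manual))
  discarded <- c(
    stats::setNames(rep("impedance", length(imp_discarded)), imp_discarded),
    stats::setNames(rep("bad-fraction", length(cons$discarded_electrodes)),
                    cons$discarded_electrodes),
    stats::setNames(rep("slope", length(slope_discarded)), slope_discarded),
    stats::setNames(rep("manual", length(setdiff(manual, imp_discarded))),
                    setdiff(manual, imp_discarded)))

  ## Stage 8: subject verdict per task
  verdict <- reject_subject(surviving, config)

  good_trials <- setdiff(epochs$trial_ids, cons$common_bad_trials)
  reasons <- lapply(keep_channels, function(ch) {
    ids <- badlists[[ch]]
    src <- ifelse(ids %in% as.integer(rms_bad[[ch]]),
                  ifelse(ids %in% as.integer(psd_bad[[ch]]), "rms+psd",
                         "rms"), "psd")
    stats::setNames(src, ids)
  })
  names(reasons) <- keep_channels

  structure(list(bad_trials_by_electrode = badlists,
                 flag_stage = reasons,
                 discarded_electrodes = discarded,
                 common_bad_trials = cons$common_bad_trials,
                 bad_fraction = cons$bad_fraction,
                 slopes = slopes,
                 eye_bad_trials = eye_bad,
                 surviving_electrodes = surviving,
                 good_trials = good_trials,
                 subject_verdict = verdict,
                 n_trials = n_events,
                 config = config),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("Rejection report: %d trials screened\n", x$n_trials))
  cat(sprintf("  eye-bad trials: %d | common bad trials: %d | good trials: %d\n",
              length(x$eye_bad_trials), length(x$common_bad_trials),
              length(x$good_trials)))
  cat(sprintf("  discarded electrodes: %d (%s)\n",
              length(x$discarded_electrodes),
              if (length(x$discarded_electrodes))
                paste(names(x$discarded_electrodes),
                      unname(x$discarded_electrodes), sep = ":",
                      collapse = ", ") else "none"))
  cat(sprintf("  subject verdict: visual %s, auditory %s\n",
              ifelse(x$subject_verdict["visual"], "keep", "reject"),
              ifelse(x$subject_verdict["auditory"], "keep", "reject")))
  invisible(x)
}

#' Serialize a rejection report to JSON
#'
#' @param report a [run_rejection_cascade()] result
#' @param path output JSON path
#' @return invisibly, the path
#' @export
write_rejection_report <- function(report, path) {
  stopifnot(inherits(report, "rejection_report"))
  jsonlite::write_json(
    list(bad_trials_by_electrode = report$bad_trials_by_electrode,
         discarded_electrodes = as.list(report$discarded_electrodes),
         common_bad_trials = report$common_bad_trials,
         eye_bad_trials = report$eye_bad_trials,
         surviving_electrodes = report$surviving_electrodes,
         good_trials = report$good_trials,
         subject_verdict = as.list(report$subject_verdict),
         n_trials = report$n_trials),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
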