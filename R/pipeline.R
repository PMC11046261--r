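#' End-to-end band-power analysis of one session
#'
#' Runs the full pipeline on a continuous recording: artifact-rejection
#' cascade (with the fixation-break filter when an eye trace is given),
#' epoching, multitaper PSDs of the baseline (-500..0 ms) and stimulus
#' (250..750 ms) windows, and baseline-normalized band-power changes for
#' the requested bands, under unipolar or bipolar referencing.
#'
#' @param recording an [new_recording()] with events
#' @param task `"visual"` or `"auditory"`; selects the analysis electrode
#'   set (or bipolar pair list)
#' @param bands named list of length-2 numeric band edges in Hz
#' @param eye optional [eye_trace()]
#' @param referencing `"unipolar"` or `"bipolar"`
#' @param reject_config a [rejection_config()]
#' @param stim_ms,base_ms analysis windows (half-open) in ms
#' @param epoch_window_ms epoching window in ms
#' @param nw,k taper parameters for the analysis PSDs
#' @return object of class `session_analysis`: `band_changes` (named list
#'   of [delta_power()] results), `report` (the rejection report),
#'   `stim_psd` / `base_psd` (the spectral estimates over analysis
#'   channels), `analysis_channels`, `n_good_trials`
#' @export
analyze_session <- function(recording,
                            task = c("visual", "auditory"),
                            bands = canonical_bands(),
                            eye = NULL,
                            referencing = c("unipolar", "bipolar"),
                            reject_config = rejection_config(),
                            stim_ms = c(250, 750), base_ms = c(-500, 0),
                            epoch_window_ms = c(-848, 1650),
                            nw = 1, k = 1) {
  task <- match.arg(task)
  referencing <- match.arg(referencing)
  report <- run_rejection_cascade(recording, reject_config, eye = eye,
                                  epoch_window_ms = epoch_window_ms)
  good <- setdiff(report$good_trials, report$eye_bad_trials)
  epochs <- epoch(recording, epoch_window_ms)
  epochs <- subset_epochs(epochs, trials = intersect(epochs$trial_ids, good))
  sets <- electrode_sets()
  if (referencing == "unipolar") {
    chans <- intersect(if (task == "visual") sets$visual_unipolar else
      sets$auditory_unipolar, report$surviving_electrodes)
    if (!length(chans)) stop("no surviving analysis electrodes", call. = FALSE)
    epochs <- subset_epochs(epochs, channels = chans)
  } else {
    pairs <- if (task == "visual") visual_bipolar_pairs() else
      auditory_bipolar_pairs()
    ok <- pairs[, 1] %in% report$surviving_electrodes &
      pairs[, 2] %in% report$surviving_electrodes
    if (!any(ok)) stop("no surviving bipolar pairs", call. = FALSE)
    epochs <- bipolar_rereference(epochs, pairs[ok, , drop = FALSE])
    chans <- epochs$channel_labels
  }
  stim_psd <- multitaper_psd(epochs, stim_ms, nw = nw, k = k)
  base_psd <- multitaper_psd(epochs, base_ms, nw = nw, k = k)
  band_changes <- lapply(bands, function(b)
    delta_power(stim_psd, base_psd, b))
  structure(list(band_changes = band_changes, report = report,
                 stim_psd = stim_psd, base_psd = base_psd,
                 analysis_channels = chans, task = task,
                 referencing = referencing,
                 n_good_trials = dim(epochs$data)[1]),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf("Session analysis (%s task, %s referencing): %d good trials, %d channels\n",
              x$task, x$referencing, x$n_good_trials,
              length(x$analysis_channels)))
  for (nm in names(x$band_changes)) {
    bc <- x$band_changes[[nm]]
    cat(sprintf("  %-17s %3g-%3g Hz: %+.3f dB\n", nm, bc$band[1],
                bc$band[2], bc$delta_db))
  }
  invisible(x)
}

#' Stimulus-period band power per condition
#'
#' Trial-averaged stimulus-window band power split by condition, per
#' electrode — the input of [condition_selectivity()].
#'
#' @param stim_psd a [multitaper_psd()] estimate of the stimulus window
#' @param band length-2 numeric band in Hz
#' @return matrix electrodes x conditions of band power
#' @export
band_power_by_condition <- function(stim_psd, band) {
  stopifnot(inherits(stim_psd, "spectral_estimate"))
  bins <- which(stim_psd$freqs >= band[1] & stim_psd$freqs <= band[2])
  conds <- sort(unique(stim_psd$trial_condition))
  out <- vapply(conds, function(cc) {
    rows <- which(stim_psd$trial_condition == cc)
    apply(stim_psd$power[rows, , bins, drop = FALSE], 2,
          function(m) sum(colMeans(m)))
  }, numeric(length(stim_psd$channel_labels)))
  out <- matrix(out, nrow = length(stim_psd$channel_labels),
                dimnames = list(stim_psd$channel_labels, conds))
  out
}

#' Detection performance of the cascade against simulator ground truth
#'
#' Scores a rejection report against the ground truth of the session it
#' was run on. An injected artifact event counts as detected when its
#' trial is flagged where the artifact occurred: in the bad-trial list of
#' at least one affected electrode, in the common bad set, or by the
#' fixation-break filter. The false-flag rate is the fraction of clean
#' trials (no injected artifact or fixation break) that the pipeline
#' discards at the trial level (common bad set or eye filter). Artifacts
#' confined to non-priority electrodes are intentionally not promoted to
#' the common set by the cascade, which is why detection is scored at the
#' affected electrodes.
#'
#' @param truth the `truth` element of a [simulate_session()] result
#' @param report a [run_rejection_cascade()] result for the same session
#' @return list with `sensitivity`, `by_type` (named detection rates),
#'   `clean_flag_rate`, and the underlying counts
#' @export
cascade_confusion <- function(truth, report) {
  stopifnot(inherits(report, "rejection_report"))
  tr <- truth$artifact_trials
  trial_flagged <- sort(unique(c(report$common_bad_trials,
                                 report$eye_bad_trials)))
  detected <- if (nrow(tr)) mapply(function(t, els) {
    t %in% trial_flagged ||
      any(vapply(els, function(el) {
        t %in% report$bad_trials_by_electrode[[el]]
      }, TRUE))
  }, tr$trial, lapply(tr$electrodes, unlist)) else logical(0)
  clean <- setdiff(seq_len(report$n_trials),
                   c(tr$trial, truth$fixation_break_trials))
  list(sensitivity = if (length(detected)) mean(detected) else NA_real_,
       by_type = if (nrow(tr)) tapply(detected, tr$type, mean) else NULL,
       clean_flag_rate = if (length(clean))
         mean(clean %in% trial_flagged) else NA_real_,
       n_artifact_events = nrow(tr), n_clean_trials = length(clean))
}

#' Write the summary report bundle of a session analysis
#'
#' Emits the per-band, per-electrode band-power tables and the rejection
#' summary as CSV/JSON, change-spectrogram and scalp-map figures as PNG,
#' and a provenance record (package version, seed, configuration). The
#' CSV tables are the authoritative output; figures are a thin
#' presentation layer over them.
#'
#' @param analysis an [analyze_session()] result
#' @param out_dir output directory (created if needed)
#' @param seed seed to record in the provenance block
#' @param figures emit PNG figures (set `FALSE` for table-only output)
#' @return invisibly, a character vector of the files written
#' @export
summary_report <- function(analysis, out_dir, seed = NA_integer_,
                           figures = TRUE) {
  stopifnot(inherits(analysis, "session_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  tab <- do.call(rbind, lapply(names(analysis$band_changes), function(nm) {
    bc <- analysis$band_changes[[nm]]
    data.frame(band = nm, band_lo = bc$band[1], band_hi = bc$band[2],
               electrode = names(bc$per_electrode),
               delta_db = unname(bc$per_electrode),
               pooled_delta_db = bc$delta_db)
  }))
  f <- file.path(out_dir, "band_power_changes.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "rejection_report.json")
  write_rejection_report(analysis$report, f)
  files <- c(files, f)
  prov <- list(package = "rippleGamma",
               version = as.character(utils::packageVersion("rippleGamma")),
               seed = seed, task = analysis$task,
               referencing = analysis$referencing,
               n_good_trials = analysis$n_good_trials,
               analysis_channels = analysis$analysis_channels)
  f <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (figures) {
    for (nm in names(analysis$band_changes)) {
      bc <- analysis$band_changes[[nm]]
      if (!all(names(bc$per_electrode) %in% acticap64_labels())) next
      f <- file.path(out_dir, paste0("scalp_", nm, ".png"))
      grDevices::png(f, width = 700, height = 700, res = 120)
      print(scalp_map(bc$per_electrode, title = nm))
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}
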