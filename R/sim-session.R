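#' Simulate a full synthetic EEG session
#'
#' Builds a continuous recording emulating a passive stimulus-train task:
#' a 1/f background, event markers for every stimulus of the shuffled
#' condition sequence, the configured band-power effects, artifacts and an
#' eye trace with seeded fixation breaks. Every injection is recorded in
#' the returned ground truth, so downstream stages can be validated
#' against known answers. The same `(config, seed)` pair yields a
#' bit-identical session.
#'
#' @param config a [sim_config()]
#' @param seed integer seed controlling every random draw
#' @return list of class `sim_session` with elements `recording`
#'   ([new_recording()], events included), `events` (the event table),
#'   `eye` ([eye_trace()] or `NULL`) and `truth` (ground truth list with
#'   `effects`, `artifact_trials`, `fixation_break_trials`, `seed`)
#' @export
#' @examples
#' cfg <- sim_config(channel_labels = c("Oz", "TP9", "Fp1"),
#'                   condition_table = data.frame(condition = 1:2,
#'                                                n_trials = 5))
#' ses <- simulate_session(cfg, seed = 1)
#' nrow(ses$events)
simulate_session <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  n_trials <- sum(config$condition_table$n_trials)
  spacing <- ms_to_samp((config$stimulus_duration +
                           config$interstimulus_interval) * 1000, fs)
  lead <- as.integer(round(config$lead_in_s * fs))
  n_samples <- as.integer(2L * lead + n_trials * spacing)

  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 4L))
  cond_seq <- withr::with_seed(seeds[1], {
    sample(rep(config$condition_table$condition,
               config$condition_table$n_trials))
  })
  events <- data.frame(onset = lead + 1L + (seq_len(n_trials) - 1L) * spacing,
                       condition = cond_seq)

  recording <- simulate_background(config, n_samples, seed = seeds[2])
  recording$events <- events

  stim_ms <- config$stimulus_duration * 1000
  effects <- list()
  for (ef in config$band_effects) {
    win <- ef$window_ms %||% c(0, stim_ms)
    recording <- inject_band_response(recording, events, ef$band,
                                      ef$electrodes, ef$delta_db,
                                      window_ms = win, ramp_ms = ef$ramp_ms,
                                      conditions = ef$conditions)
    effects[[length(effects) + 1L]] <-
      data.frame(band_lo = ef$band[1], band_hi = ef$band[2],
                 delta_db = ef$delta_db,
                 electrodes = I(list(ef$electrodes)),
                 conditions = I(list(ef$conditions %||%
                                       config$condition_table$condition)))
  }
  effects <- if (length(effects)) do.call(rbind, effects) else
    data.frame(band_lo = numeric(0), band_hi = numeric(0),
               delta_db = numeric(0), electrodes = I(list()),
               conditions = I(list()))

  if (!is.null(config$artifacts)) {
    inj <- inject_artifacts(recording, config$artifacts, seed = seeds[3])
    recording <- inj$recording
    artifact_trials <- inj$truth
  } else {
    artifact_trials <- data.frame(trial = integer(0), type = character(0),
                                  electrodes = I(list()))
  }

  eye <- NULL
  fixation_breaks <- integer(0)
  if (!is.null(config$eye)) {
    es <- config$eye
    eye_res <- withr::with_seed(seeds[4], {
      smooth_jitter <- function() {
        raw <- stats::filter(stats::rnorm(n_samples), rep(1 / 50, 50),
                             sides = 2)
        raw[is.na(raw)] <- 0
        as.numeric(raw) * es$noise_sd_deg / (1 / sqrt(50))
      }
      x <- smooth_jitter()
      y <- smooth_jitter()
      breaks <- which(stats::runif(n_trials) < es$break_rate)
      dur <- ms_to_samp(es$duration_ms, fs)
      for (tr in breaks) {
        start_ms <- stats::runif(1, -400, 630 - es$duration_ms)
        idx <- events$onset[tr] + ms_to_samp(start_ms, fs) + seq_len(dur) - 1L
        ok <- idx >= 1L & idx <= n_samples
        axis <- sample(c("x", "y"), 1L)
        step <- sample(c(-1, 1), 1L) * es$excursion_deg
        if (axis == "x") x[idx[ok]] <- x[idx[ok]] + step else
          y[idx[ok]] <- y[idx[ok]] + step
      }
      list(x = x, y = y, breaks = breaks)
    })
    ## EEG blinks leave a gap (out-of-range sentinel) in the eye trace
    blink_rows <- artifact_trials$trial[artifact_trials$type == "blink"]
    for (tr in blink_rows) {
      idx <- events$onset[tr] + window_offsets(c(-100, 150), fs)
      ok <- idx >= 1L & idx <= n_samples
      eye_res$x[idx[ok]] <- NA_real_
      eye_res$y[idx[ok]] <- NA_real_
    }
    eye <- eye_trace(eye_res$x, eye_res$y, fs)
    fixation_breaks <- sort(unique(c(eye_res$breaks, blink_rows)))
  }

  truth <- structure(list(effects = effects,
                          artifact_trials = artifact_trials,
                          fixation_break_trials = fixation_breaks,
                          seed = seed),
                     class = "sim_ground_truth")
  structure(list(recording = recording, events = events, eye = eye,
                 truth = truth, config = config, seed = seed),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("Synthetic EEG session: %d trials, %d channels, seed %d\n",
              nrow(x$events), nrow(x$recording$data), x$seed))
  cat(sprintf("  %d band effect(s), %d artifact event(s), %d fixation break(s)\n",
              nrow(x$truth$effects), nrow(x$truth$artifact_trials),
              length(x$truth$fixation_break_trials)))
  invisible(x)
}

#' Serialize / load a simulated session
#'
#' Writes the recording as a BrainVision triplet, the eye trace as CSV and
#' the ground truth as JSON under `dir`. `read_session()` restores the
#' parts that were written (ground-truth list columns come back as plain
#' lists).
#'
#' @param session a [simulate_session()] result
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sim_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_brainvision(session$recording, file.path(dir, "session"))
  if (!is.null(session$eye)) {
    write_eye_trace(session$eye, file.path(dir, "eye.csv"))
  }
  tr <- session$truth
  jsonlite::write_json(
    list(effects = data.frame(band_lo = tr$effects$band_lo,
                              band_hi = tr$effects$band_hi,
                              delta_db = tr$effects$delta_db),
         effect_electrodes = tr$effects$electrodes,
         artifact_trials = data.frame(trial = tr$artifact_trials$trial,
                                      type = tr$artifact_trials$type),
         artifact_electrodes = tr$artifact_trials$electrodes,
         fixation_break_trials = tr$fixation_break_trials,
         seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @param dir directory previously written by [write_session()]
#' @return `read_session()`: list with `recording`, `eye`, `truth`
#' @export
read_session <- function(dir) {
  recording <- read_brainvision(file.path(dir, "session.vhdr"))
  eye_path <- file.path(dir, "eye.csv")
  eye <- if (file.exists(eye_path)) read_eye_trace(eye_path) else NULL
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(recording = recording, eye = eye, truth = truth)
}
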