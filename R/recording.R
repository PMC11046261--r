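#' Construct a continuous multichannel EEG recording
#'
#' Container for continuous EEG: a channels x samples matrix in microvolts,
#' channel labels, sampling rate, per-electrode impedances and an event
#' table of stimulus onsets.
#'
#' @param data numeric matrix, channels x samples, in microvolts
#' @param sampling_rate sampling rate in Hz
#' @param channel_labels character vector, one label per row of `data`
#' @param impedances numeric vector of electrode impedances in kOhm
#'   (optional, `NA` allowed)
#' @param events data.frame with columns `onset` (1-based sample index of
#'   stimulus onset) and `condition` (integer condition code), or `NULL`
#' @return object of class `eeg_recording`
#' @export
new_recording <- function(data, sampling_rate,
                          channel_labels = rownames(data),
                          impedances = NULL, events = NULL) {
  if (!is.matrix(data)) stop("data must be a channels x samples matrix",
                             call. = FALSE)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("Ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("one channel label per data row required", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (!is.null(impedances)) {
    if (length(impedances) != nrow(data)) {
      stop("one impedance per channel required", call. = FALSE)
    }
    if (any(impedances < 0, na.rm = TRUE)) {
      stop("impedances must be >= 0", call. = FALSE)
    }
    names(impedances) <- channel_labels
  }
  events <- validate_events(events, ncol(data))
  rownames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, impedances = impedances,
                 events = events),
            class = "eeg_recording")
}

validate_events <- function(events, n_samples) {
  if (is.null(events)) {
    return(data.frame(onset = integer(0), condition = integer(0)))
  }
  stopifnot(is.data.frame(events), all(c("onset", "condition") %in% names(events)))
  if (is.unsorted(events$onset, strictly = TRUE)) {
    stop("event onsets must be strictly increasing", call. = FALSE)
  }
  if (nrow(events) && (events$onset[1] < 1L ||
                       events$onset[nrow(events)] > n_samples)) {
    stop("event onsets must lie within the recording", call. = FALSE)
  }
  events
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat(sprintf("  %d events, impedances %s\n", nrow(x$events),
              if (is.null(x$impedances)) "absent" else
                sprintf("%.1f-%.1f kOhm", min(x$impedances), max(x$impedances))))
  invisible(x)
}

#' Cut trials around stimulus onsets
#'
#' Extracts one epoch per event over the half-open sample window
#' `[onset + start, onset + end)` where start/end are the millisecond
#' window bounds converted to samples. Events whose window would extend
#' past either edge of the recording are dropped with a warning.
#'
#' @param recording an [new_recording()] object
#' @param window_ms length-2 numeric, (start_ms, end_ms) relative to onset
#' @param events optional event table overriding `recording$events`
#' @return object of class `epoch_set`: `data` is a trials x channels x
#'   samples array; `trial_ids` index the original event rows
#' @export
#' @examples
#' rec <- new_recording(matrix(rnorm(2 * 4000), 2), 1000,
#'                      c("Oz", "TP9"),
#'                      events = data.frame(onset = c(1500, 3000),
#'                                          condition = c(1L, 2L)))
#' ep <- epoch(rec, c(-500, 750))
#' dim(ep$data)
epoch <- function(recording, window_ms, events = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  stop_if_not_window(window_ms)
  events <- validate_events(events %||% recording$events, ncol(recording$data))
  fs <- recording$sampling_rate
  offs <- window_offsets(window_ms, fs)
  n_samp <- length(offs)
  first <- events$onset + offs[1]
  last <- events$onset + offs[n_samp]
  keep <- first >= 1L & last <= ncol(recording$data)
  if (any(!keep)) {
    warning(sum(!keep), " event(s) too close to the recording edges dropped",
            call. = FALSE)
  }
  kept <- which(keep)
  n_ch <- nrow(recording$data)
  arr <- array(NA_real_, dim = c(length(kept), n_ch, n_samp),
               dimnames = list(NULL, recording$channel_labels, NULL))
  for (i in seq_along(kept)) {
    arr[i, , ] <- recording$data[, events$onset[kept[i]] + offs, drop = FALSE]
  }
  structure(list(data = arr, window = window_ms, sampling_rate = fs,
                 channel_labels = recording$channel_labels,
                 trial_condition = events$condition[kept],
                 trial_ids = kept),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples, window %g..%g ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$window[1], x$window[2]))
  invisible(x)
}

## Restrict an epoch_set to a subset of trials and/or channels (by id/label).
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  ti <- if (is.null(trials)) seq_along(epochs$trial_ids) else
    match(trials, epochs$trial_ids)
  if (anyNA(ti)) stop("unknown trial id", call. = FALSE)
  ci <- if (is.null(channels)) seq_along(epochs$channel_labels) else
    match(channels, epochs$channel_labels)
  if (anyNA(ci)) stop("unknown channel label", call. = FALSE)
  epochs$data <- epochs$data[ti, ci, , drop = FALSE]
  epochs$channel_labels <- epochs$channel_labels[ci]
  epochs$trial_condition <- epochs$trial_condition[ti]
  epochs$trial_ids <- epochs$trial_ids[ti]
  epochs
}

#' Re-reference epochs to bipolar derivations
#'
#' Each output channel is the first pair member minus the second, labelled
#' `"A-B"`. Bipolar referencing is anti-symmetric: swapping a pair negates
#' the derived trace.
#'
#' @param epochs an [epoch()] result
#' @param pairs 2-column character matrix (anode, cathode); see
#'   [auditory_bipolar_pairs()] and [visual_bipolar_pairs()]
#' @return an `epoch_set` whose channels are the bipolar derivations
#' @export
bipolar_rereference <- function(epochs, pairs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(dim(pairs)) || ncol(pairs) != 2L) {
    stop("pairs must be a 2-column matrix", call. = FALSE)
  }
  ia <- match(pairs[, 1], epochs$channel_labels)
  ib <- match(pairs[, 2], epochs$channel_labels)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(pairs[, 1][is.na(ia)], pairs[, 2][is.na(ib)]))
    stop("unknown label(s) in bipolar pairs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labels <- paste0(pairs[, 1], "-", pairs[, 2])
  d <- epochs$data[, ia, , drop = FALSE] - epochs$data[, ib, , drop = FALSE]
  dimnames(d)[[2]] <- labels
  epochs$data <- d
  epochs$channel_labels <- labels
  epochs
}
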