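#' Construct an eye-position trace
#'
#' Two-channel gaze trace (x, y in degrees of visual angle) sampled at the
#' EEG rate. Samples with `NA` coordinates or excursions beyond
#' `blink_range` degrees are treated as blinks by the fixation filter.
#'
#' @param x,y gaze coordinates in degrees
#' @param sampling_rate sampling rate in Hz (must match the EEG)
#' @return object of class `eye_trace` (data.frame with time_ms, x, y)
#' @export
eye_trace <- function(x, y, sampling_rate = 1000) {
  stopifnot(length(x) == length(y), sampling_rate > 0)
  structure(
    data.frame(time_ms = (seq_along(x) - 1L) * 1000 / sampling_rate,
               x = x, y = y),
    sampling_rate = sampling_rate, class = c("eye_trace", "data.frame"))
}

#' Write / read an eye trace as CSV
#' @param eye an [eye_trace()]
#' @param path CSV path
#' @return invisibly the path, or the `eye_trace` for the reader
#' @export
write_eye_trace <- function(eye, path) {
  utils::write.csv(as.data.frame(eye), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eye_trace
#' @export
read_eye_trace <- function(path) {
  d <- utils::read.csv(path)
  fs <- if (nrow(d) > 1) 1000 / (d$time_ms[2] - d$time_ms[1]) else 1000
  eye_trace(d$x, d$y, fs)
}

#' Flag trials with fixation breaks
#'
#' A trial is flagged when, during the checked window around its stimulus
#' onset, any eye sample leaves the square fixation window (half-width
#' `half_width_deg` on either axis around `fixation_center`) or is a blink
#' (`NA` or outside `blink_range` degrees, the tracker's out-of-range
#' sentinel). Trials whose checked window is not covered by the trace are
#' flagged with reason `"no data"`.
#'
#' @param eye an [eye_trace()]
#' @param events event table with 1-based `onset` sample indices
#' @param fixation_center length-2 numeric, fixation-spot position in
#'   degrees
#' @param window_ms checked window relative to onset (half-open)
#' @param half_width_deg half-width of the square fixation window in
#'   degrees (5-degree square window by default)
#' @param blink_range samples with |x| or |y| beyond this are blinks
#' @return integer vector of flagged trial indices (rows of `events`) with
#'   a `reason` attribute
#' @export
reject_fixation_breaks <- function(eye, events, fixation_center = c(0, 0),
                                   window_ms = c(-500, 750),
                                   half_width_deg = 2.5, blink_range = 30) {
  stopifnot(inherits(eye, "eye_trace"))
  stop_if_not_window(window_ms)
  fs <- attr(eye, "sampling_rate")
  offs <- window_offsets(window_ms, fs)
  n <- nrow(eye)
  bad <- integer(0)
  reason <- character(0)
  for (i in seq_len(nrow(events))) {
    idx <- events$onset[i] + offs
    if (idx[1] < 1L || idx[length(idx)] > n) {
      bad <- c(bad, i); reason <- c(reason, "no data"); next
    }
    ex <- eye$x[idx]; ey <- eye$y[idx]
    blink <- is.na(ex) | is.na(ey) | abs(ex) > blink_range |
      abs(ey) > blink_range
    outside <- abs(ex - fixation_center[1]) > half_width_deg |
      abs(ey - fixation_center[2]) > half_width_deg
    if (any(blink)) {
      bad <- c(bad, i); reason <- c(reason, "blink")
    } else if (any(outside)) {
      bad <- c(bad, i); reason <- c(reason, "fixation break")
    }
  }
  structure(bad, reason = reason)
}
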