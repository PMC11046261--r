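## Shared fixture builders. Everything is generated in code at test time;
## no data files are read.

## A recording holding one sine channel (or several identical ones) with
## evenly spaced events, long enough for the -848..1650 ms epoch window.
sine_recording <- function(freq_hz, amp_uv, n_events = 5, fs = 1000,
                           labels = "Oz", spacing_ms = 2600,
                           noise_sd = 0) {
  spacing <- round(spacing_ms * fs / 1000)
  n <- (n_events + 1L) * spacing + 2000L
  t <- (seq_len(n) - 1L) / fs
  x <- amp_uv * sin(2 * pi * freq_hz * t)
  data <- matrix(rep(x, length(labels)), nrow = length(labels),
                 byrow = TRUE)
  if (noise_sd > 0) data <- data + noise_sd * matrix(
    stats::rnorm(length(data)), nrow = nrow(data))
  new_recording(data, fs, labels,
                impedances = rep(7, length(labels)),
                events = data.frame(onset = spacing * seq_len(n_events),
                                    condition = 1L))
}

## Epochs built directly from a trials x channels x samples array.
epochs_from_array <- function(arr, window_ms, fs = 1000,
                              labels = NULL, conditions = NULL) {
  labels <- labels %||% paste0("Ch", seq_len(dim(arr)[2]))
  dimnames(arr) <- list(NULL, labels, NULL)
  structure(list(data = arr, window = window_ms, sampling_rate = fs,
                 channel_labels = labels,
                 trial_condition = conditions %||% rep(1L, dim(arr)[1]),
                 trial_ids = seq_len(dim(arr)[1])),
            class = c("epoch_set"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent zero-phase high-pass used as an oracle against the
## cascade's filtering (signal::filtfilt directly, per trace).
oracle_highpass <- function(x, fs, cutoff = 1.6) {
  bt <- signal::butter(4, cutoff / (fs / 2), type = "high")
  signal::filtfilt(bt, x)
}
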