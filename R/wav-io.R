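#' Write a mono waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer for mono audio: 16-bit PCM (`"pcm16"`) or
#' 32-bit IEEE float (`"float32"`). A sidecar JSON file with the ripple
#' specification and synthesis seed is written when the waveform carries
#' them as attributes (see [synthesize_ripple()]).
#'
#' @param waveform numeric vector in `[-1, 1]`
#' @param sample_rate sampling rate in Hz
#' @param path output file path
#' @param format `"pcm16"` or `"float32"`
#' @param sidecar write a `<path>.json` sidecar with spec/seed metadata if
#'   available
#' @return invisibly, the path
#' @export
write_wav <- function(waveform, sample_rate = 44100, path,
                      format = c("pcm16", "float32"), sidecar = TRUE) {
  format <- match.arg(format)
  if (anyNA(waveform) || any(!is.finite(waveform))) {
    stop("waveform must be finite", call. = FALSE)
  }
  n <- length(waveform)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per_sample <- bits %/% 8L
  data_bytes <- n * bytes_per_sample
  audio_format <- if (format == "pcm16") 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per_sample), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(-32767L, pmin(32767L, round(waveform * 32767))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(waveform), con, size = 4, endian = "little")
  }
  if (sidecar && !is.null(attr(waveform, "spec"))) {
    spec <- attr(waveform, "spec")
    meta <- list(spec = unclass(spec), seed = attr(waveform, "seed"),
                 format = format, sample_rate = sample_rate, n_samples = n)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path WAV file path
#' @return numeric waveform with attribute `sample_rate`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data <- NULL; sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      audio_format <- readBin(con, "integer", size = 2, endian = "little")
      n_channels <- readBin(con, "integer", size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (n_channels != 1L) stop("only mono WAV supported", call. = FALSE)
      fmt <- list(audio_format = audio_format, bits = bits)
      if (size > 16L) invisible(readBin(con, "raw", n = size - 16L))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk", call. = FALSE)
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        data <- readBin(con, "integer", n = size %/% 2L, size = 2,
                        endian = "little") / 32767
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        data <- readBin(con, "numeric", n = size %/% 4L, size = 4,
                        endian = "little")
      } else {
        stop("unsupported WAV encoding", call. = FALSE)
      }
    } else {
      invisible(readBin(con, "raw", n = size))
    }
    if (!is.null(data)) break
  }
  if (is.null(data)) stop("no data chunk found", call. = FALSE)
  structure(data, sample_rate = sample_rate)
}
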