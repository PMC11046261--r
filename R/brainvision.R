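#' Write a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr` (text header), `<basename>.vmrk` (text marker
#' file with one stimulus marker per event) and `<basename>.eeg`
#' (multiplexed binary). `INT_16` data are stored at a resolution of
#' 0.1 uV/bit, matching 16-bit acquisition; `IEEE_FLOAT_32` stores
#' microvolts losslessly at single precision.
#'
#' @param recording an [new_recording()] object
#' @param basename output path without extension
#' @param binary_format `"INT_16"` or `"IEEE_FLOAT_32"`
#' @param resolution microvolts per bit for `INT_16`
#' @return invisibly, the header path
#' @export
write_brainvision <- function(recording, basename,
                              binary_format = c("INT_16", "IEEE_FLOAT_32"),
                              resolution = 0.1) {
  stopifnot(inherits(recording, "eeg_recording"))
  binary_format <- match.arg(binary_format)
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  res <- if (binary_format == "INT_16") resolution else 1
  header <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(recording$data)),
    paste0("SamplingInterval=",
           format(1e6 / recording$sampling_rate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(nrow(recording$data)),
            recording$channel_labels, format(res, scientific = FALSE))
  )
  if (!is.null(recording$impedances)) {
    header <- c(header, "", "[Comment]", "Impedance [kOhm]:",
                sprintf("%s: %g", recording$channel_labels,
                        recording$impedances))
  }
  writeLines(header, vhdr, useBytes = TRUE)
  markers <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0")
  if (nrow(recording$events)) {
    markers <- c(markers, sprintf(
      "Mk%d=Stimulus,S%3d,%d,1,0", seq_len(nrow(recording$events)) + 1L,
      recording$events$condition, recording$events$onset))
  }
  writeLines(markers, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con), add = TRUE)
  if (binary_format == "INT_16") {
    q <- as.integer(round(recording$data / resolution))
    if (any(abs(q) > 32767L)) {
      stop("signal exceeds INT_16 range at this resolution", call. = FALSE)
    }
    writeBin(as.vector(q), con, size = 2, endian = "little")
  } else {
    writeBin(as.vector(recording$data), con, size = 4, endian = "little")
  }
  invisible(vhdr)
}

parse_bv_section <- function(lines, section) {
  hits <- grep("^\\[", lines)
  start <- which(lines == paste0("[", section, "]"))
  if (!length(start)) return(character(0))
  nxt <- hits[hits > start[1]]
  end <- if (length(nxt)) nxt[1] - 1L else length(lines)
  body <- lines[seq.int(start[1] + 1L, end)]
  body[nzchar(body) & !startsWith(body, ";")]
}

bv_keyvals <- function(body) {
  kv <- regmatches(body, regexec("^([^=]+)=(.*)$", body))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
}

#' Read a BrainVision triplet
#'
#' Reads a `.vhdr`/`.vmrk`/`.eeg` triplet (multiplexed binary, `INT_16` or
#' `IEEE_FLOAT_32`) into an [new_recording()]. Stimulus markers are parsed
#' into the event table; impedances are recovered from the header comment
#' section when present.
#'
#' @param header_path path to the `.vhdr` file
#' @return an `eeg_recording`
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) {
    stop("header file not found: ", header_path, call. = FALSE)
  }
  lines <- readLines(header_path, warn = FALSE, encoding = "UTF-8")
  common <- bv_keyvals(parse_bv_section(lines, "Common Infos"))
  binfo <- bv_keyvals(parse_bv_section(lines, "Binary Infos"))
  chans <- bv_keyvals(parse_bv_section(lines, "Channel Infos"))
  dir <- dirname(header_path)
  data_path <- file.path(dir, common[["DataFile"]])
  marker_path <- file.path(dir, common[["MarkerFile"]])
  for (p in c(data_path, marker_path)) {
    if (!file.exists(p)) stop("missing triplet member: ", p, call. = FALSE)
  }
  if (toupper(common[["DataFormat"]]) != "BINARY" ||
      toupper(common[["DataOrientation"]]) != "MULTIPLEXED") {
    stop("only multiplexed binary BrainVision data supported", call. = FALSE)
  }
  n_ch <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])
  ch_fields <- strsplit(unname(chans), ",", fixed = TRUE)
  labels <- vapply(ch_fields, `[`, "", 1L)
  res <- vapply(ch_fields, function(f) {
    if (length(f) >= 3L && nzchar(f[3])) as.numeric(f[3]) else 1
  }, 0)
  units <- vapply(ch_fields, function(f) if (length(f) >= 4L) f[4] else "",
                  "")
  if (any(nzchar(units) & !units %in% c("µV", "uV", "\xb5V"))) {
    stop("channel unit is not microvolts", call. = FALSE)
  }
  fmt <- toupper(binfo[["BinaryFormat"]])
  file_bytes <- file.info(data_path)$size
  bps <- if (fmt == "INT_16") 2L else 4L
  n_total <- file_bytes %/% bps
  if (n_total %% n_ch != 0L) {
    stop(sprintf(
      "truncated binary: %d values is not a multiple of %d channels (expected complete multiplexed frames)",
      n_total, n_ch), call. = FALSE)
  }
  con <- file(data_path, "rb")
  on.exit(close(con), add = TRUE)
  raw_vals <- if (fmt == "INT_16") {
    readBin(con, "integer", n = n_total, size = 2, endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n_total, size = 4, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  data <- matrix(raw_vals, nrow = n_ch) * res
  mlines <- readLines(marker_path, warn = FALSE, encoding = "UTF-8")
  mk <- parse_bv_section(mlines, "Marker Infos")
  ev <- data.frame(onset = integer(0), condition = integer(0))
  if (length(mk)) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",", fixed = TRUE)
    is_stim <- vapply(parts, function(p) identical(p[1], "Stimulus"), TRUE)
    parts <- parts[is_stim]
    if (length(parts)) {
      ev <- data.frame(
        onset = vapply(parts, function(p) as.integer(p[3]), 0L),
        condition = vapply(parts, function(p)
          as.integer(sub("^S\\s*", "", p[2])), 0L))
    }
  }
  imp <- NULL
  cm <- parse_bv_section(lines, "Comment")
  imp_lines <- grep("^[A-Za-z0-9]+: ", cm, value = TRUE)
  if (length(imp_lines) == n_ch) {
    imp_kv <- regmatches(imp_lines, regexec("^([^:]+): (.*)$", imp_lines))
    imp <- as.numeric(vapply(imp_kv, `[`, "", 3L))
    names(imp) <- vapply(imp_kv, `[`, "", 2L)
    imp <- unname(imp[labels])
  }
  new_recording(data, fs, labels, impedances = imp, events = ev)
}
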