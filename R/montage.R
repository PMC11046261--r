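#' 64-channel 10-10 montage labels
#'
#' Channel labels of the standard 64-electrode actiCap layout (international
#' 10-10 scheme, FCz reference not included as a data channel), in
#' acquisition order. This is the canonical label order used for tie-breaks
#' throughout the package.
#'
#' @return character vector of 64 labels
#' @export
#' @examples
#' length(acticap64_labels())
acticap64_labels <- function() {
  c("Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9",
    "CP5", "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8",
    "TP10", "CP6", "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2", "F4",
    "F8", "Fp2", "AF7", "AF3", "AFz", "F1", "F5", "FT7", "FC3", "C1",
    "C5", "TP7", "CP3", "P1", "P5", "PO7", "PO3", "POz", "PO4", "PO8",
    "P6", "P2", "CPz", "CP4", "TP8", "C6", "C2", "FC4", "FT8", "F6",
    "F2", "AF4", "AF8", "Iz")
}

#' Electrode sets used by the analysis and rejection stages
#'
#' Named electrode groups: unipolar analysis sets for the visual and
#' auditory tasks, artifact-rejection priority sets, occipital/temporal
#' group sets used for the subject-level verdict, and the frontal set that
#' carries ocular artifacts in the simulator.
#'
#' @return named list of character vectors
#' @export
electrode_sets <- function() {
  list(
    visual_unipolar   = c("P1", "P2", "P3", "P4", "PO3", "POz", "PO4",
                          "O1", "Oz", "O2"),
    auditory_unipolar = c("TP9", "TP7", "TP8", "TP10"),
    visual_priority   = c("O1", "Oz", "O2", "P1", "P2", "P3", "P4",
                          "PO3", "POz", "PO4"),
    auditory_priority = c("TP9", "TP7", "TP8", "TP10"),
    occipital_group   = c("O1", "Oz", "O2", "PO7", "PO3", "POz", "PO4",
                          "PO8", "Iz"),
    temporal_group    = c("FT9", "FT7", "T7", "TP7", "TP9", "FT10",
                          "FT8", "T8", "TP8", "TP10"),
    frontal           = c("Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4",
                          "AF8", "F7", "F8")
  )
}

#' Bipolar derivations for the auditory-task analysis
#'
#' Eight neighbouring-electrode pairs over the temporal regions; each output
#' channel is the first member minus the second.
#'
#' @return 2-column character matrix (anode, cathode)
#' @export
auditory_bipolar_pairs <- function() {
  m <- rbind(c("TP9", "TP7"), c("TP7", "T7"), c("TP7", "P7"),
             c("TP7", "CP5"), c("TP10", "TP8"), c("TP8", "T8"),
             c("TP7", "P8"), c("TP7", "CP6"))
  colnames(m) <- c("anode", "cathode")
  m
}

#' Bipolar derivations for the visual-task analysis
#'
#' Nine neighbouring-electrode pairs over occipital and parieto-occipital
#' regions.
#'
#' @return 2-column character matrix (anode, cathode)
#' @export
visual_bipolar_pairs <- function() {
  m <- rbind(c("PO3", "P1"), c("PO3", "P3"), c("POz", "PO3"),
             c("PO4", "P2"), c("PO4", "P4"), c("POz", "PO4"),
             c("Oz", "POz"), c("Oz", "O1"), c("Oz", "O2"))
  colnames(m) <- c("anode", "cathode")
  m
}

## Parse a 10-10 label into (row prefix, lateral position). Used only for
## the schematic scalp-map layout.
parse_1010_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) == 0L) stop("not a 10-10 label: ", label, call. = FALSE)
  list(prefix = m[2], pos = m[3])
}

#' Schematic 2-D positions for 10-10 electrode labels
#'
#' Top-view schematic layout on the unit disc: anterior-posterior position
#' from the label's row prefix (Fp at the front, Iz at the back), lateral
#' position from the label's number (odd left, even right, z on the
#' midline). These positions are a schematic for disk-style scalp maps, not
#' digitised head coordinates.
#'
#' @param labels character vector of 10-10 labels
#' @return data.frame with columns label, x, y
#' @export
#' @examples
#' head(montage_positions(acticap64_labels()))
montage_positions <- function(labels) {
  row_frac <- c(Fp = 0.10, AF = 0.20, F = 0.30, FT = 0.40, FC = 0.40,
                C = 0.50, T = 0.50, TP = 0.60, CP = 0.60, P = 0.70,
                PO = 0.80, O = 0.90, I = 1.00)
  lat_frac <- c(z = 0, "1" = 0.25, "2" = 0.25, "3" = 0.5, "4" = 0.5,
                "5" = 0.75, "6" = 0.75, "7" = 1, "8" = 1,
                "9" = 1.25, "10" = 1.25)
  xy <- t(vapply(labels, function(lb) {
    p <- parse_1010_label(lb)
    if (!p$prefix %in% names(row_frac)) {
      stop("unknown 10-10 row prefix in label: ", lb, call. = FALSE)
    }
    rf <- row_frac[[p$prefix]]
    y <- cospi(rf)
    lat <- lat_frac[[p$pos]]
    ## T7/T8 and the 9/10 electrodes sit on (or just outside) the head rim
    half_width <- sinpi(rf)
    x <- lat * half_width * 0.8
    side <- if (p$pos == "z") 0 else if (as.integer(p$pos) %% 2L == 1L) -1 else 1
    c(x = side * x, y = y)
  }, numeric(2)))
  data.frame(label = labels, x = xy[, "x"], y = xy[, "y"],
             row.names = NULL, stringsAsFactors = FALSE)
}
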