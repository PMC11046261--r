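test_result <- function(statistic, p_value, df, n, variance_ratio = NA_real_,
                        estimate = NA_real_, method = "") {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 variance_ratio = variance_ratio, n = n,
                 estimate = estimate, method = method),
            class = "rg_test_result")
}

#' @export
print.rg_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df %.4g, p %.4g", x$method, x$statistic,
              x$df, x$p_value))
  if (!is.na(x$variance_ratio)) cat(sprintf(", F %.4g", x$variance_ratio))
  cat("\n")
  invisible(x)
}

#' Paired t test at every frequency bin
#'
#' Compares matched stimulus and baseline spectra (one row per subject or
#' replicate) with a standard paired t test at each frequency bin, and
#' reports the significance tier of each bin (`"p<0.01"`,
#' `"0.01<=p<0.05"`, `"ns"`). Bins with zero variance of the differences
#' are reported as the degenerate case (`t = 0`, `p = 1` when the mean
#' difference is zero, otherwise `p = 0`) with a warning.
#'
#' @param stim,base numeric matrices, subjects x frequency bins
#' @param freqs optional frequency grid for labelling
#' @return data.frame with columns freq, t, df, p, tier
#' @export
paired_t_per_frequency <- function(stim, base, freqs = NULL) {
  stim <- as.matrix(stim); base <- as.matrix(base)
  stopifnot(all(dim(stim) == dim(base)), nrow(stim) >= 2L)
  d <- stim - base
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1L))
  degenerate <- s == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " bin(s) with zero variance of differences reported as degenerate",
            call. = FALSE)
  }
  t_stat <- ifelse(degenerate, ifelse(m == 0, 0, Inf * sign(m)),
                   m / (s / sqrt(n)))
  p <- ifelse(degenerate, ifelse(m == 0, 1, 0),
              2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE))
  tier <- ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "0.01<=p<0.05", "ns"))
  data.frame(freq = freqs %||% seq_len(ncol(d)), t = t_stat, df = n - 1L,
             p = p, tier = tier, row.names = NULL)
}

#' Welch (unequal-variance) t test with variance ratio
#'
#' Two-sided unpaired t test with the Welch-Satterthwaite degrees of
#' freedom, reporting the variance ratio `F = var(a) / var(b)` alongside
#' the test.
#'
#' @param a,b numeric vectors (each of length >= 2)
#' @return an `rg_test_result` with fields statistic, p_value, df,
#'   variance_ratio, n
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
              n = c(length(a), length(b)),
              variance_ratio = stats::var(a) / stats::var(b),
              estimate = unname(diff(rev(ht$estimate))),
              method = "Welch two-sample t test")
}

#' Pearson correlation with two-sided p value
#'
#' @param a,b numeric vectors of equal length >= 3 with nonzero variance
#' @return an `rg_test_result`; `estimate` holds r
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("zero variance in an input", call. = FALSE)
  }
  ht <- stats::cor.test(a, b, method = "pearson")
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
              n = length(a), estimate = unname(ht$estimate),
              method = "Pearson correlation")
}

#' Condition-selectivity index of band power
#'
#' Dispersion of stimulus-period band power across stimulus conditions,
#' computed per electrode and averaged over the electrode set. The default
#' orientation is the standard coefficient of variation, across-condition
#' SD divided by across-condition mean (`"sd_over_mean"`); the reciprocal
#' orientation (`"mean_over_sd"`) is available because both readings of a
#' mean-to-SD power ratio appear in practice. Low values indicate poor
#' tuning toward any stimulus condition. The index is invariant to overall
#' gain and non-negative.
#'
#' @param band_power numeric matrix, electrodes x conditions (stimulus-
#'   period band power per condition), or a vector for one electrode
#' @param orientation `"sd_over_mean"` (default) or `"mean_over_sd"`
#' @return object of class `selectivity_index` with fields `value`
#'   (electrode-averaged), `per_electrode`, `orientation`
#' @export
#' @examples
#' condition_selectivity(rbind(c(1, 3)))$value  # sqrt(2) / 2
condition_selectivity <- function(band_power,
                                  orientation = c("sd_over_mean",
                                                  "mean_over_sd")) {
  orientation <- match.arg(orientation)
  if (is.null(dim(band_power))) band_power <- matrix(band_power, nrow = 1L)
  if (ncol(band_power) < 2L) stop("need >= 2 conditions", call. = FALSE)
  m <- apply(band_power, 1, mean)
  s <- apply(band_power, 1, stats::sd)
  if (any(m == 0)) stop("zero mean power for an electrode", call. = FALSE)
  per <- if (orientation == "sd_over_mean") s / m else m / s
  structure(list(value = mean(per), per_electrode = per,
                 orientation = orientation,
                 n_conditions = ncol(band_power)),
            class = "selectivity_index")
}

#' @export
print.selectivity_index <- function(x, ...) {
  cat(sprintf("Condition selectivity (%s): %.4f over %d conditions\n",
              x$orientation, x$value, x$n_conditions))
  invisible(x)
}
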