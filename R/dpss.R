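## Cache of computed taper families, keyed by "n/nw/k". Tapers for the
## window lengths in routine use (250, 500, 2000 samples) are computed once
## per R session.
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw` via the symmetric tridiagonal matrix that commutes with the
#' concentration operator. Tapers are unit-energy (`sum(u^2) = 1`),
#' mutually orthogonal, and signed so that symmetric tapers have positive
#' mean. The default `nw = 1, k = 1` is the single-taper configuration
#' used for all power spectra in this package.
#'
#' @param n taper length in samples
#' @param nw time-bandwidth product (half-bandwidth is `nw / n` cycles per
#'   sample)
#' @param k number of tapers (at most `2 * nw - 1` are well concentrated)
#' @return n x k matrix, one taper per column
#' @export
#' @examples
#' u <- dpss_tapers(500, nw = 1, k = 1)
#' sum(u^2)
dpss_tapers <- function(n, nw = 1, k = 1) {
  stopifnot(n >= 2, nw > 0, k >= 1)
  key <- paste(n, nw, k, sep = "/")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- seq_len(n) - 1L
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (seq_len(n - 1L)) * (n - seq_len(n - 1L)) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  A[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-12) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[2, j] < 0) {
      V[, j] <- -V[, j]   # antisymmetric tapers: positive initial slope
    }
  }
  .dpss_cache[[key]] <- V
  V
}
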