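utils::globalVariables(c("x", "y", "hx", "hy", "value", "label"))

#' Disk-style scalp map of per-electrode values
#'
#' Draws each electrode as a colored disk at its schematic 10-10 position
#' (see [montage_positions()]), with a head outline. The underlying
#' (label, x, y, value) table is always computed and attached; when
#' `csv_path` is given it is also written as CSV so downstream use never
#' depends on graphics.
#'
#' @param values named numeric vector, one value per electrode label
#' @param csv_path optional path for the CSV table
#' @param title plot title
#' @param limits optional symmetric color limits (dB)
#' @return a ggplot object with the data table attached as attribute
#'   `table`
#' @export
#' @examples
#' v <- stats::setNames(rep(0, 64), acticap64_labels())
#' p <- scalp_map(v)
scalp_map <- function(values, csv_path = NULL, title = NULL,
                      limits = NULL) {
  if (is.null(names(values))) stop("values must be named by electrode label",
                                   call. = FALSE)
  pos <- montage_positions(names(values))
  tab <- data.frame(pos, value = unname(values))
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  theta <- seq(0, 2 * pi, length.out = 181)
  head_df <- data.frame(hx = 1.12 * cos(theta), hy = 1.12 * sin(theta))
  lim <- limits %||% (c(-1, 1) * max(abs(tab$value), 1e-12))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path(data = head_df,
                       ggplot2::aes(x = hx, y = hy),
                       inherit.aes = FALSE, linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(fill = value), shape = 21,
                        size = 6, stroke = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = label), size = 1.8,
                       vjust = -1.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = lim,
                                  name = "dB") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(title)) p <- p + ggplot2::ggtitle(title)
  attr(p, "table") <- tab
  p
}
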