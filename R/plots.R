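#' Heat-map colour for an observed recombination rate
#'
#' Piecewise-linear blend anchored at r = 0 (yellow, `#FFFF00`), r = 0.2
#' (teal, `#008080`) and r = 0.5 (burgundy, `#800020`); used by the
#' recombination heat map so that blocks of yellow flag suppression or
#' pseudo-linkage and burgundy flags free recombination.
#'
#' @param r Numeric vector of rates in `[0, 0.5]`; `NA` gives grey.
#' @return Character vector of hex colours.
#' @export
r_color <- function(r) {
  anchors <- c("#FFFF00", "#008080", "#800020")
  low <- grDevices::colorRamp(anchors[1:2])
  high <- grDevices::colorRamp(anchors[2:3])
  vapply(r, function(v) {
    if (is.na(v)) return("#BEBEBE")
    v <- min(max(v, 0), 0.5)
    rgb <- if (v <= 0.2) low(v / 0.2) else high((v - 0.2) / 0.3)
    grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  }, character(1))
}

.r_scale <- function() {
  ggplot2::scale_fill_gradientn(
    colours = c("#FFFF00", "#008080", "#800020"),
    values = scales::rescale(c(0, 0.2, 0.5), from = c(0, 0.5)),
    limits = c(0, 0.5),
    na.value = "#BEBEBE",
    name = "r"
  )
}

#' Triangular recombination heat map
#'
#' @param object A `recomb_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recomb_matrix <- function(object, ...) {
  coords <- object$coords
  coords$idx <- seq_len(nrow(coords))
  long <- tidy.recomb_matrix(object)
  long <- dplyr::left_join(
    long,
    stats::setNames(coords[, c("chrom", "center_mbp", "idx")],
                    c("chrom_i", "center_i_mbp", "idx_i")),
    by = c("chrom_i", "center_i_mbp"))
  long <- dplyr::left_join(
    long,
    stats::setNames(coords[, c("chrom", "center_mbp", "idx")],
                    c("chrom_j", "center_j_mbp", "idx_j")),
    by = c("chrom_j", "center_j_mbp"))
  bounds <- coords |>
    dplyr::summarise(at = min(.data$idx), .by = "chrom")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$idx_i, y = .data$idx_j,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    .r_scale() +
    ggplot2::geom_vline(data = bounds,
                        ggplot2::aes(xintercept = .data$at - 0.5),
                        linewidth = 0.2, colour = "grey40") +
    ggplot2::geom_hline(data = bounds,
                        ggplot2::aes(yintercept = .data$at - 0.5),
                        linewidth = 0.2, colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = bounds$at, labels = bounds$chrom,
                                expand = c(0, 0)) +
    ggplot2::scale_y_continuous(breaks = bounds$at, labels = bounds$chrom,
                                expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Render a recombination heat map to an image file
#'
#' @param x A `recomb_matrix`.
#' @param path Output path (`.png` or `.svg`).
#' @param width,height,dpi Device settings.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(x, path, width = 7, height = 6, dpi = 150) {
  p <- autoplot.recomb_matrix(x)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' LOD profile plot of a genome scan
#'
#' @param object A `scan_profile`.
#' @param threshold Optional LOD threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_profile <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mbp, y = .data$lod)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "LOD",
                  title = attr(object, "trait")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' Segregation-distortion plot
#'
#' First-parent allele frequency along the genome with the 1:1 expectation.
#' @param profile Output of [distortion_profile()].
#' @return A ggplot object.
#' @export
plot_distortion <- function(profile) {
  profile$mbp <- ceiling(profile$pos_bp / 1e6)
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$mbp, y = .data$freq_a)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (Mbp)", y = "freq(A) among homozygotes") +
    ggplot2::theme_minimal()
}
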