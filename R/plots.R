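# ggplot2 visualisations: label maps with the fixed five-colour tissue
# palette, contrast transfer curves, and report summaries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# fixed palette matching the figure convention: background, ventricle,
# gray matter, white matter, fine structure
tissue_palette <- function() {
  c("0" = "#1b1b1b", "1" = "#3f7fbf", "2" = "#b7b7b7", "3" = "#e377c2",
    "4" = "#ff7f0e")
}

label_raster_df <- function(labels, pitch) {
  tibble::tibble(
    x = rep((seq_len(ncol(labels)) - 0.5) * pitch,
            each = nrow(labels)),
    y = rep((seq_len(nrow(labels)) - 0.5) * pitch,
            times = ncol(labels)),
    label = factor(as.vector(labels))
  )
}

#' Plot a segmentation map
#'
#' @param object A `miraf_seg`.
#' @param ... Unused.
#' @return A ggplot raster of the label image (axes in micrometres).
#' @export
autoplot.miraf_seg <- function(object, ...) {
  df <- label_raster_df(object$labels, object$pitch)
  pal <- tissue_palette()
  lv <- levels(df$label)
  cols <- ifelse(lv %in% names(pal), pal[lv],
                 scales_fallback(length(lv)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = stats::setNames(cols, lv),
                               name = "cluster") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

scales_fallback <- function(n) grDevices::hcl.colors(max(n, 3), "Dark 3")[seq_len(n)]

#' Plot a phantom's ground-truth label map
#'
#' @param object A `miraf_phantom`.
#' @param ... Unused.
#' @return A ggplot raster of the class map.
#' @export
autoplot.miraf_phantom <- function(object, ...) {
  autoplot.miraf_seg(list(labels = object$labels, pitch = object$pitch)) +
    ggplot2::labs(fill = "tissue class")
}

#' Plot a contrast transfer curve
#'
#' @param object A [contrast_curve()] tibble.
#' @param threshold Resolvability threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot of modulation contrast versus spatial frequency
#'   (log-10 frequency axis).
#' @export
autoplot.miraf_contrast <- function(object, threshold = 0.2, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frequency, y = .data$contrast)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$aliased)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spatial frequency (lp/mm)",
                  y = "modulation contrast", shape = "aliased") +
    ggplot2::theme_minimal()
}

#' Plot an experiment report summary
#'
#' @param object A `miraf_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of ARI against ground truth per modality.
#' @export
autoplot.miraf_report <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$modality,
                                                      .data$ari_truth),
                                   y = .data$ari_truth)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ARI vs ground truth") +
    ggplot2::theme_minimal()
}
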