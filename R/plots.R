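#' Plot an accumulated ion image
#'
#' @param images An `accumulated_images` list from [accumulate()].
#' @param mass Mass label to display.
#' @param log1p Display log1p-transformed counts (default `TRUE`; filter
#'   background and coccolith counts differ by orders of magnitude).
#' @return A ggplot.
#' @export
plot_ion_image <- function(images, mass = "44Ca", log1p = TRUE) {
  stopifnot(mass %in% names(images))
  m <- images[[mass]]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$counts <- m[cbind(df$row, df$col)]
  if (log1p) df$counts <- log1p(df$counts)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = if (log1p) "log1p(counts)" else "counts") +
    ggplot2::labs(title = paste(mass, "accumulated counts"),
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.roi_map <- function(object, ...) {
  cls <- matrix("background", nrow(object$labels), ncol(object$labels))
  for (id in names(object$classes)) {
    cls[object$labels == as.integer(id)] <- object$classes[[id]]
  }
  df <- tidyr::expand_grid(row = seq_len(nrow(cls)), col = seq_len(ncol(cls)))
  df$class <- cls[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(background = "grey20",
                                          coccolith = "goldenrod",
                                          contaminant = "firebrick")) +
    ggplot2::labs(x = "column", y = "row", fill = "ROI class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.depth_profile <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$plane_end, .data$ratio)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "acquisition plane (depth)",
      y = sprintf("%s/44Ca ion-count ratio",
                  attr(object, "element") %||% "El"),
      title = sprintf("Depth profile, ROI %s",
                      attr(object, "roi_label") %||% "?")) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = object$plane_start[window[1]], xmax = object$plane_end[window[2]],
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' @export
autoplot.cv_decomposition <- function(object, ...) {
  ggplot2::ggplot(object$within,
                  ggplot2::aes(.data$group, .data$cv)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_crossbar(
      data = dplyr::filter(object$among, !.data$exceeds_one),
      ggplot2::aes(y = .data$among_lith_cv, ymin = .data$among_lith_cv,
                   ymax = .data$among_lith_cv),
      colour = "firebrick", linewidth = 0.7, width = 0.6) +
    ggplot2::labs(
      x = NULL, y = "coefficient of variation",
      title = sprintf("%s: within-lith (boxes) vs among-lith (bars) CV",
                      object$element),
      subtitle = "groups without a bar: among-lith CV exceeds 1") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tukey_grouping <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -1.2, size = 3.4) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s/44Ca ion-count ratio (mean +/- SE)",
                              object$element),
                  caption = "groups sharing a letter are not significantly different (Tukey HSD)") +
    ggplot2::theme_minimal()
}
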