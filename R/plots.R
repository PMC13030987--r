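#' Plot per-cube density maps
#'
#' Tiles the cubes of each z-slab, filled by the count of one class.
#'
#' @param object A `cube_grid`.
#' @param cell_class Class to display (default: first grid class).
#' @param layers Optional subset of `iz` slab indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cube_grid <- function(object, cell_class = object$classes[1], layers = NULL, ...) {
  df <- object$cubes
  df$count <- cube_counts(object, cell_class)
  df <- df[df$in_mask, ]
  if (!is.null(layers)) df <- df[df$iz %in% layers, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u_um, y = .data$v_um, fill = .data$count)) +
    ggplot2::geom_tile(width = object$cube_size, height = object$cube_size) +
    ggplot2::facet_wrap(~iz, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "u (µm)", y = "v (µm)", fill = cell_class,
      title = sprintf("Per-cube %s density (%g µm cubes)", cell_class, object$cube_size)
    )
}

#' Plot density-cluster maps
#'
#' Tiles high-density cubes colored by cluster label over each z-slab.
#'
#' @param object A `density_clustering`.
#' @param layers Optional subset of `iz` slab indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_clustering <- function(object, layers = NULL, ...) {
  df <- object$cubes[object$cubes$in_mask, ]
  if (!is.null(layers)) df <- df[df$iz %in% layers, ]
  df$cluster <- factor(ifelse(df$cluster_label == 0L, NA, df$cluster_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u_um, y = .data$v_um, fill = .data$cluster)) +
    ggplot2::geom_tile(width = object$cube_size, height = object$cube_size) +
    ggplot2::facet_wrap(~iz, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "u (µm)", y = "v (µm)", fill = "cluster",
      title = sprintf("%s high-density clusters (threshold %g)",
                      object$cell_class, object$q3_threshold)
    )
}

#' Plot Moran's I per class
#'
#' @param object A `moran_result` tibble from [morans_i()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moran_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cell_class, y = .data$I)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Moran's I", title = "Spatial autocorrelation by cell type")
}

#' Plot precision-recall curves
#'
#' @param object A `pr_curve` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$recall, y = .data$precision, colour = .data$cell_class)
  ) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "class",
                  title = sprintf("Precision-recall (IOU ≥ %g)", object$iou_threshold))
}

#' Plot neighborhood composition by density quartile
#'
#' Stacked bars of the 16 quartile-by-presence categories.
#'
#' @param object A `neighborhood_table` from [quartile_neighborhoods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neighborhood_table <- function(object, ...) {
  pres <- attr(object, "presence_classes")
  df <- as_tibble(object)
  df$composition <- paste0(
    pres[1], ifelse(df[[paste0("has_", pres[1])]], "+", "-"), " ",
    pres[2], ifelse(df[[paste0("has_", pres[2])]], "+", "-")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$quartile_bin), fill = .data$composition)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(
      x = sprintf("%s density quartile", attr(object, "reference_class")),
      y = "fraction of cubes", fill = "composition",
      title = "Neighborhood composition by density quartile"
    )
}
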