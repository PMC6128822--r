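#' Plot methods for topography and coverage results
#'
#' `autoplot.kmeans_solution()` draws the silhouette plot (per-point
#' silhouettes grouped by cluster, the diagnostic used for model
#' selection); `autoplot.k_selection()` the mean-silhouette-vs-k curve;
#' `autoplot.coverage_table()` coverage percent per electrode across radii
#' (top electrodes only); `plot_hotspots()` a 2D scatter of hotspot
#' coordinates coloured by group or cluster.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kmeans_solution
#' @export
autoplot.kmeans_solution <- function(object, ...) {
  if (is.null(object$silhouettes)) {
    abort("solution has no silhouettes (k = 1 or not computed).")
  }
  df <- tibble(
    cluster = factor(object$assignments),
    silhouette = object$silhouettes
  )
  df <- df[order(df$cluster, -df$silhouette), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$silhouette,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "silhouette value",
      title = sprintf("Silhouette plot, k = %d (mean %.3f)",
                      object$k, object$mean_silhouette)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kmeans_solution
#' @method autoplot k_selection
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object$diagnostics,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = object$diagnostics[object$diagnostics$k == object$best$k, ],
      colour = "red", size = 3
    ) +
    ggplot2::labs(x = "k", y = "mean silhouette") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kmeans_solution
#' @param top_n Number of best electrodes to display (default 8).
#' @method autoplot coverage_table
#' @export
autoplot.coverage_table <- function(object, top_n = 8, ...) {
  max_r <- max(object$radius_mm)
  top <- object[object$radius_mm == max_r, ]
  keep <- top$electrode[order(-top$percent)][seq_len(min(top_n,
                                                         nrow(top)))]
  df <- object[object$electrode %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_mm,
                                   y = .data$percent,
                                   colour = .data$electrode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "radius (mm)", y = "% of hotspots within radius") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kmeans_solution
#' @param set A `hotspot_set`.
#' @param colour_by Column to colour by (default `"group"`), or a
#'   `kmeans_solution` to colour by cluster.
#' @param axes Which two mm axes to plot (default x and z, a coronal-like
#'   view).
#' @export
plot_hotspots <- function(set, colour_by = "group",
                          axes = c("x_mm", "z_mm")) {
  df <- as_tibble(set)
  if (inherits(colour_by, "kmeans_solution")) {
    df$cluster <- factor(colour_by$assignments)
    col <- "cluster"
  } else {
    col <- colour_by
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                   y = .data[[axes[2]]],
                                   colour = .data[[col]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(axes[1], "(MNI)"),
                  y = paste(axes[2], "(MNI)")) +
    ggplot2::theme_minimal()
}
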