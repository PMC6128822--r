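#' Tidy a k-means topography solution
#'
#' `tidy()` returns one row per cluster (centroid coordinates, size, share
#' of points, mean silhouette); `glance()` returns a one-row model summary;
#' `augment()`-style per-point output is available via
#' `tidy(x, "points")`.
#'
#' @param x A `kmeans_solution`.
#' @param what `"clusters"` (default) or `"points"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kmeans_solution
#' @export
tidy.kmeans_solution <- function(x, what = c("clusters", "points"), ...) {
  what <- match.arg(what)
  if (what == "points") {
    return(tibble(
      point = seq_along(x$assignments),
      cluster = x$assignments,
      silhouette = x$silhouettes %||% rep(NA_real_,
                                          length(x$assignments))
    ))
  }
  n <- length(x$assignments)
  sil_by <- if (!is.null(x$silhouettes)) {
    tapply(x$silhouettes, x$assignments, mean)
  } else {
    rep(NA_real_, x$k)
  }
  tibble(
    cluster = seq_len(x$k),
    x_mm = x$centroids[, 1],
    y_mm = x$centroids[, 2],
    z_mm = x$centroids[, 3],
    size = x$sizes,
    share = x$sizes / n,
    mean_silhouette = as.numeric(sil_by)
  )
}

#' @rdname tidy.kmeans_solution
#' @method glance kmeans_solution
#' @export
glance.kmeans_solution <- function(x, ...) {
  tibble(
    k = x$k,
    n = length(x$assignments),
    wcss = x$wcss,
    mean_silhouette = x$mean_silhouette,
    n_restarts = x$n_restarts
  )
}

#' @rdname tidy.kmeans_solution
#' @method tidy k_selection
#' @export
tidy.k_selection <- function(x, ...) {
  x$diagnostics
}

#' @rdname tidy.kmeans_solution
#' @method glance k_selection
#' @export
glance.k_selection <- function(x, ...) {
  tibble(
    selected_k = x$best$k,
    mean_silhouette = x$best$mean_silhouette,
    weak_structure = x$weak_structure,
    n_restarts = x$n_restarts
  )
}

#' @rdname tidy.kmeans_solution
#' @method tidy contingency_result
#' @export
tidy.contingency_result <- function(x, ...) {
  as_tibble(as.data.frame(x$table))
}

#' @rdname tidy.kmeans_solution
#' @method glance contingency_result
#' @export
glance.contingency_result <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p = x$p,
         low_expected = x$low_expected)
}

#' @rdname tidy.kmeans_solution
#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) {
  x$summary
}
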