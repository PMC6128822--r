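#' Hotspot-to-electrode Euclidean distance matrix
#'
#' Straight-line 3D distances (mm) from every hotspot to every electrode
#' position. Rows are hotspots (in the order of `set`), columns are
#' electrodes (named by label).
#'
#' @param set A `hotspot_set` (or data frame with `x_mm`, `y_mm`, `z_mm`).
#' @param electrodes An `electrode_set` from [load_electrodes()].
#' @return Numeric matrix, hotspots x electrodes, in mm.
#' @export
hotspot_electrode_distances <- function(set, electrodes) {
  H <- hotspot_coords(set)
  if (!nrow(H)) abort("empty hotspot set.")
  E <- as.matrix(electrodes[, c("x", "y", "z")])
  if (!nrow(E)) abort("empty electrode set.")
  D2 <- outer(rowSums(H^2), rowSums(E^2), "+") - 2 * H %*% t(E)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  dimnames(D) <- list(NULL, electrodes$label)
  D
}

#' Coverage of hotspots around scalp electrodes at fixed radii
#'
#' For each electrode and radius, the percentage of hotspots lying within
#' that straight-line distance of the electrode. The radii default to the
#' 2-5 cm range relevant to TMS depth of effect. The best electrode per
#' radius is the one covering the largest percentage; ties are reported
#' jointly, judged after rounding the percentages to `round_digits`
#' decimals (default 0, i.e. integer percents, the convention of printed
#' coverage tables).
#'
#' @param distances Hotspot x electrode distance matrix from
#'   [hotspot_electrode_distances()].
#' @param radii_mm Radii in mm, positive and increasing
#'   (default `c(20, 30, 40, 50)`).
#' @param round_digits Decimal places at which ties for best electrode are
#'   judged (default 0).
#' @return A `coverage_table`: tibble with columns `electrode`,
#'   `radius_mm`, `n_within`, `percent`; attributes `n_hotspots` and `best`
#'   (tibble of radius, best electrode labels, percent).
#' @export
coverage_at_radii <- function(distances, radii_mm = c(20, 30, 40, 50),
                              round_digits = 0) {
  if (is.null(dim(distances)) || nrow(distances) == 0) {
    abort("empty hotspot set.")
  }
  if (any(radii_mm <= 0) || is.unsorted(radii_mm, strictly = TRUE)) {
    abort("`radii_mm` must be positive and strictly increasing.")
  }
  n <- nrow(distances)
  labels <- colnames(distances)
  counts <- vapply(
    radii_mm,
    function(r) colSums(distances <= r),
    numeric(ncol(distances))
  )
  counts <- matrix(counts, ncol = length(radii_mm),
                   dimnames = list(labels, NULL))
  pct <- 100 * counts / n
  long <- tibble(
    electrode = rep(labels, times = length(radii_mm)),
    radius_mm = rep(radii_mm, each = length(labels)),
    n_within = as.integer(counts),
    percent = as.numeric(pct)
  )
  best <- lapply(seq_along(radii_mm), function(j) {
    p <- round(pct[, j], round_digits)
    winners <- labels[p == max(p)]
    tibble(
      radius_mm = radii_mm[j],
      best_electrodes = paste(winners, collapse = "/"),
      percent = max(pct[, j])
    )
  })
  structure(
    long,
    n_hotspots = n,
    best = dplyr::bind_rows(best),
    round_digits = round_digits,
    class = c("coverage_table", class(long))
  )
}

#' @rdname coverage_at_radii
#' @param x A `coverage_table`.
#' @export
best_electrodes <- function(x) {
  attr(x, "best")
}

#' Coverage by drug-of-choice subgroup
#'
#' Repeats the coverage computation for the full hotspot set and for each
#' subgroup defined by a grouping column, and formats a compact report: one
#' row per group, one best-electrode + percent entry per radius (the layout
#' of printed TMS-targeting coverage tables).
#'
#' @param set A `hotspot_set` with the grouping column filled in.
#' @param electrodes An `electrode_set`.
#' @param radii_mm Radii in mm (default `c(20, 30, 40, 50)`).
#' @param by Grouping column (default `"group"`).
#' @param round_digits Tie-judging precision, see [coverage_at_radii()].
#' @return A `coverage_report`: list with `all` (the pooled
#'   `coverage_table`), `groups` (named list of per-group tables; groups
#'   with no hotspots are absent), and `summary` (tibble: group, radius_mm,
#'   best_electrodes, percent, n_hotspots).
#' @export
subgroup_coverage <- function(set, electrodes,
                              radii_mm = c(20, 30, 40, 50),
                              by = "group", round_digits = 0) {
  if (!by %in% names(set)) abort(paste0("grouping column not found: ", by))
  d_all <- hotspot_electrode_distances(set, electrodes)
  all_cov <- coverage_at_radii(d_all, radii_mm, round_digits)
  groups <- split(seq_len(nrow(set)), set[[by]])
  group_cov <- lapply(groups, function(ix) {
    if (!length(ix)) return(NULL)
    coverage_at_radii(d_all[ix, , drop = FALSE], radii_mm, round_digits)
  })
  group_cov <- group_cov[!vapply(group_cov, is.null, logical(1))]
  summ <- dplyr::bind_rows(
    dplyr::mutate(best_electrodes(all_cov), group = "all",
                  n_hotspots = attr(all_cov, "n_hotspots")),
    dplyr::bind_rows(lapply(names(group_cov), function(g) {
      dplyr::mutate(best_electrodes(group_cov[[g]]), group = g,
                    n_hotspots = attr(group_cov[[g]], "n_hotspots"))
    }))
  )
  summ <- summ[, c("group", "radius_mm", "best_electrodes", "percent",
                   "n_hotspots")]
  structure(
    list(all = all_cov, groups = group_cov, summary = summ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>\n")
  print(tidyr::pivot_wider(
    dplyr::mutate(
      x$summary,
      cell = sprintf("%.0f%% %s", .data$percent, .data$best_electrodes)
    )[, c("group", "radius_mm", "cell")],
    names_from = "radius_mm", values_from = "cell",
    names_glue = "{radius_mm} mm"
  ))
  invisible(x)
}
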