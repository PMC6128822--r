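#' Cross-tabulate a factor against cluster membership
#'
#' Pearson chi-square test (no continuity correction) of whether a factor
#' (drug group, gender) is distributed independently of cluster assignment.
#' A warning flags expected cell counts below 5, where the chi-square
#' approximation is questionable.
#'
#' @param set A `hotspot_set` (or any data frame) holding the factor
#'   column.
#' @param solution A `kmeans_solution` whose assignments align with the
#'   rows of `set`, or an integer vector of cluster labels.
#' @param factor Name of the factor column (default `"group"`).
#' @return A `contingency_result`: list with `table`, `expected`, `chi2`,
#'   `df`, `p`, `low_expected` flag.
#' @examples
#' pts <- sample_hotspots(mixture_spec(), 150, seed = 1)
#' sol <- kmeans_fit(pts, 3, n_restarts = 20, seed = 2)
#' cross_tab(pts, sol, "group")$p
#' @export
cross_tab <- function(set, solution, factor = "group") {
  if (!factor %in% names(set)) {
    abort(paste0("factor column not found: ", factor))
  }
  labels <- set[[factor]]
  if (anyNA(labels)) abort("factor labels missing for some points.")
  assignments <- if (inherits(solution, "kmeans_solution")) {
    solution$assignments
  } else {
    as.integer(solution)
  }
  if (length(assignments) != nrow(set)) {
    abort("assignments do not align with the point set.")
  }
  tab <- table(factor = labels, cluster = assignments)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("degenerate contingency table (single row or column).")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ht$expected < 5)
  if (low) {
    warn("some expected cell counts are below 5; chi-square approximation may be poor.")
  }
  structure(
    list(
      table = tab,
      expected = ht$expected,
      chi2 = unname(ht$statistic),
      df = unname(ht$parameter),
      p = unname(ht$p.value),
      low_expected = low,
      factor = factor
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "<contingency_result> %s x cluster: chi2 = %.3f, df = %d, p = %.4g%s\n",
    x$factor, x$chi2, x$df, x$p,
    if (x$low_expected) " (low expected counts)" else ""
  ))
  print(x$table)
  invisible(x)
}
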