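#' Per-point silhouette scores
#'
#' For point i with mean distance a(i) to the other members of its own
#' cluster and b(i) the smallest mean distance to the points of any other
#' cluster, s(i) = (b - a) / max(a, b). Two conventions are applied:
#' members of singleton clusters score 0, and points with a = b = 0
#' (coincident degenerate clusters) score 0.
#'
#' @param points Data frame with mm coordinate columns, or an n x 3 matrix.
#' @param assignments Integer cluster labels, at least 2 distinct,
#'   every cluster non-empty.
#' @return Numeric vector of silhouettes in `[-1, 1]`, with
#'   `mean` attribute.
#' @export
silhouette_scores <- function(points, assignments) {
  P <- coord_matrix(points)
  n <- nrow(P)
  a <- as.integer(assignments)
  if (length(a) != n) abort("one assignment per point required.")
  k <- max(a)
  sizes <- tabulate(a, k)
  if (sum(sizes > 0) < 2L) {
    abort("silhouettes need at least 2 non-empty clusters.")
  }
  d <- as.matrix(stats::dist(P))
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), a)] <- 1
  sums <- d %*% ind                       # n x k: total distance to cluster
  own <- sums[cbind(seq_len(n), a)]
  a_i <- ifelse(sizes[a] > 1L, own / (sizes[a] - 1L), 0)
  means_other <- sweep(sums, 2L, pmax(sizes, 1L), "/")
  means_other[, sizes == 0L] <- Inf
  means_other[cbind(seq_len(n), a)] <- Inf
  b_i <- apply(means_other, 1L, min)
  s <- ifelse(
    sizes[a] == 1L, 0,
    ifelse(pmax(a_i, b_i) == 0, 0, (b_i - a_i) / pmax(a_i, b_i))
  )
  structure(as.numeric(s), mean = mean(s))
}

#' Select the number of clusters by mean silhouette
#'
#' Fits [kmeans_fit()] for every k in `k_range` and selects the k with the
#' largest mean silhouette (ties broken toward smaller k). When even the
#' best mean silhouette is below `weak_threshold` the winning solution is
#' flagged as weak structure -- the data do not support a confident cluster
#' count.
#'
#' @param points Data frame with mm coordinate columns, or an n x 3 matrix.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param n_restarts Random restarts per k (default 1000).
#' @param seed Optional RNG seed for the whole scan.
#' @param weak_threshold Mean-silhouette level below which the selection is
#'   flagged (documented convention, default 0.25).
#' @return A `k_selection`: list with `best` (the winning
#'   `kmeans_solution`), `diagnostics` (tibble of k, wcss,
#'   mean_silhouette), `weak_structure` flag.
#' @export
select_k <- function(points, k_range = 2:10, n_restarts = 1000,
                     seed = NULL, weak_threshold = 0.25) {
  if (!length(k_range)) abort("`k_range` is empty.")
  k_range <- sort(unique(as.integer(k_range)))
  P <- coord_matrix(points)
  check_k(P, max(k_range))
  fits <- with_seed_or_current(seed, {
    lapply(k_range, function(k) {
      kmeans_fit(P, k, n_restarts = n_restarts, seed = NULL)
    })
  })
  diagnostics <- tibble(
    k = k_range,
    wcss = vapply(fits, function(f) f$wcss, numeric(1)),
    mean_silhouette = vapply(fits, function(f) f$mean_silhouette,
                             numeric(1))
  )
  best_i <- which.max(diagnostics$mean_silhouette) # ties -> first = smallest k
  best <- fits[[best_i]]
  structure(
    list(
      best = best,
      diagnostics = diagnostics,
      weak_structure = diagnostics$mean_silhouette[best_i] < weak_threshold,
      seed = seed,
      n_restarts = n_restarts
    ),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf(
    "<k_selection> selected k = %d (mean silhouette %.3f%s)\n",
    x$best$k, x$best$mean_silhouette,
    if (x$weak_structure) ", weak structure" else ""
  ))
  print(x$diagnostics)
  invisible(x)
}
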