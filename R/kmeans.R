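# Squared Euclidean distances from every point to every centroid.
# P: n x d, C: k x d -> n x k, clamped at 0 against rounding.
dist2_to_centroids <- function(P, C, P2 = rowSums(P^2)) {
  D <- outer(P2, rowSums(C^2), "+") - 2 * tcrossprod(P, C)
  D[D < 0] <- 0
  D
}

coord_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3L)
    return(unname(points))
  }
  if (is.data.frame(points)) {
    cols <- if (all(c("x_mm", "y_mm", "z_mm") %in% names(points))) {
      c("x_mm", "y_mm", "z_mm")
    } else if (all(c("x", "y", "z") %in% names(points))) {
      c("x", "y", "z")
    } else {
      abort("`points` needs columns x_mm/y_mm/z_mm (or x/y/z).")
    }
    return(unname(as.matrix(points[, cols])))
  }
  abort("`points` must be a data frame or an n x 3 matrix.")
}

#' k-means++ initial centroid seeding
#'
#' The D-squared weighted seeding of k-means++: the first centroid is drawn
#' uniformly from the points; each subsequent centroid is drawn with
#' probability proportional to the squared distance from each point to its
#' nearest already-chosen centroid.
#'
#' @param points Data frame with mm coordinate columns, or an n x 3 matrix.
#' @param k Number of centroids; must not exceed the number of distinct
#'   points.
#' @param seed Optional RNG seed.
#' @return A k x 3 matrix of initial centroids.
#' @export
kmeanspp_seed <- function(points, k, seed = NULL) {
  P <- coord_matrix(points)
  check_k(P, k)
  with_seed_or_current(seed, kmeanspp_seed_impl(P, k))
}

kmeanspp_seed_impl <- function(P, k, P2 = rowSums(P^2)) {
  n <- nrow(P)
  centers <- matrix(0, k, ncol(P))
  first <- sample.int(n, 1L)
  centers[1L, ] <- P[first, ]
  if (k > 1L) {
    d2 <- dist2_to_centroids(P, centers[1L, , drop = FALSE], P2)[, 1L]
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        pick <- sample.int(n, 1L)   # all mass on chosen points; uniform
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- P[pick, ]
      if (j < k) {
        d2 <- pmin(d2, dist2_to_centroids(
          P, centers[j, , drop = FALSE], P2
        )[, 1L])
      }
    }
  }
  centers
}

check_k <- function(P, k) {
  n_distinct <- nrow(unique(P))
  if (k < 1) abort("`k` must be >= 1.")
  if (k > n_distinct) {
    abort(sprintf("k = %d exceeds the %d distinct points.", k, n_distinct))
  }
  invisible(TRUE)
}

# One complete k-means run: k-means++ seeding, batch Lloyd iterations to
# convergence, then an online phase that moves single points whenever the
# move lowers the within-cluster sum of squares (using the exact n/(n-1),
# n/(n+1) corrected change formulas). Empty clusters are repaired by
# re-seeding them at the point farthest from its centroid.
kmeans_once <- function(P, k, P2 = rowSums(P^2), batch_tol = 1e-10,
                        max_batch_iter = 100L, max_online_sweeps = 100L) {
  n <- nrow(P)
  C <- kmeanspp_seed_impl(P, k, P2)
  a <- integer(n)
  wcss_prev <- Inf
  for (iter in seq_len(max_batch_iter)) {
    D <- dist2_to_centroids(P, C, P2)
    a_new <- max.col(-D, ties.method = "first")
    # empty-cluster repair: farthest point becomes the empty centroid
    counts <- tabulate(a_new, k)
    while (any(counts == 0L)) {
      empty <- which(counts == 0L)[1L]
      dmin <- D[cbind(seq_len(n), a_new)]
      far <- which.max(dmin)
      C[empty, ] <- P[far, ]
      D[, empty] <- dist2_to_centroids(P, C[empty, , drop = FALSE], P2)[, 1L]
      a_new <- max.col(-D, ties.method = "first")
      counts <- tabulate(a_new, k)
    }
    wcss <- sum(D[cbind(seq_len(n), a_new)])
    if (wcss > wcss_prev + 1e-8 * (1 + wcss_prev)) {
      abort("internal error: batch k-means objective increased.")
    }
    converged <- identical(a_new, a) || (wcss_prev - wcss) < batch_tol
    a <- a_new
    C <- rowsum(P, a) / as.numeric(tabulate(a, k))
    wcss_prev <- wcss
    if (converged) break
  }
  # online phase
  ns <- tabulate(a, k)
  wcss <- sum(dist2_to_centroids(P, C, P2)[cbind(seq_len(n), a)])
  for (sweep_i in seq_len(max_online_sweeps)) {
    D <- dist2_to_centroids(P, C, P2)
    da <- D[cbind(seq_len(n), a)]
    remove_gain <- ifelse(ns[a] > 1L, ns[a] / (ns[a] - 1) * da, -Inf)
    add_cost <- sweep(D, 2L, ns / (ns + 1), "*")
    add_cost[cbind(seq_len(n), a)] <- Inf
    best_b <- max.col(-add_cost, ties.method = "first")
    delta <- add_cost[cbind(seq_len(n), best_b)] - remove_gain
    i <- which.min(delta)
    if (!is.finite(delta[i]) || delta[i] >= -1e-12) break
    b <- best_b[i]; old <- a[i]; x <- P[i, ]
    C[old, ] <- (C[old, ] * ns[old] - x) / (ns[old] - 1L)
    C[b, ] <- (C[b, ] * ns[b] + x) / (ns[b] + 1L)
    ns[old] <- ns[old] - 1L
    ns[b] <- ns[b] + 1L
    a[i] <- b
    wcss_new <- wcss + delta[i]
    if (wcss_new > wcss + 1e-8) {
      abort("internal error: online k-means objective increased.")
    }
    wcss <- wcss_new
  }
  wcss <- sum(dist2_to_centroids(P, C, P2)[cbind(seq_len(n), a)])
  dimnames(C) <- NULL
  list(centroids = C, assignments = a, wcss = wcss)
}

#' Fit k-means with repeated random seeding
#'
#' The clustering engine of the topography analysis: k-means++ seeding
#' followed by a two-phase optimization -- batch Lloyd updates to
#' convergence, then online single-point moves accepted whenever they lower
#' the within-cluster sum of squared point-to-centroid distances (wcss) --
#' repeated `n_restarts` times with random seeding; the restart with the
#' lowest wcss wins (ties to the earliest restart). Distances are
#' unweighted Euclidean over the 3 MNI mm coordinates.
#'
#' @param points Data frame with mm coordinate columns (e.g. a
#'   `hotspot_set`), or an n x 3 matrix.
#' @param k Number of clusters.
#' @param n_restarts Random restarts (default 1000).
#' @param seed Optional RNG seed.
#' @param compute_silhouettes Attach per-point silhouettes (default TRUE;
#'   needs k >= 2).
#' @return A `kmeans_solution`: list with `k`, `centroids`, `assignments`,
#'   `wcss`, `silhouettes`, `mean_silhouette`, `sizes`, `n_restarts`,
#'   `seed`.
#' @examples
#' pts <- sample_hotspots(mixture_spec(), 100, seed = 1)
#' sol <- kmeans_fit(pts, k = 3, n_restarts = 25, seed = 2)
#' sol$centroids
#' @export
kmeans_fit <- function(points, k, n_restarts = 1000, seed = NULL,
                       compute_silhouettes = TRUE) {
  P <- coord_matrix(points)
  check_k(P, k)
  P2 <- rowSums(P^2)
  best <- with_seed_or_current(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- kmeans_once(P, k, P2)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
    best
  })
  sil <- NULL
  mean_sil <- NA_real_
  if (compute_silhouettes && k >= 2L) {
    sil <- silhouette_scores(P, best$assignments)
    mean_sil <- mean(sil)
  }
  structure(
    list(
      k = k,
      centroids = best$centroids,
      assignments = best$assignments,
      wcss = best$wcss,
      silhouettes = sil,
      mean_silhouette = mean_sil,
      sizes = tabulate(best$assignments, k),
      n_restarts = n_restarts,
      seed = seed
    ),
    class = "kmeans_solution"
  )
}

#' @export
print.kmeans_solution <- function(x, ...) {
  cat(sprintf(
    "<kmeans_solution> k = %d, wcss = %.1f, mean silhouette = %s, sizes = %s\n",
    x$k, x$wcss,
    ifelse(is.na(x$mean_silhouette), "NA",
           sprintf("%.3f", x$mean_silhouette)),
    paste(x$sizes, collapse = "/")
  ))
  invisible(x)
}
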