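# Neighbourhood offsets for 3D connectivity: 6 = faces, 18 = faces+edges,
# 26 = faces+edges+corners.
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be 6, 18 or 26.")
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1
  )
  unname(g[keep, , drop = FALSE])
}

# Connected components of a logical 3D array by vectorized frontier BFS.
# Returns an integer array of labels (0 = background).
label_components <- function(supra, connectivity = 6L) {
  shape <- dim(supra)
  n1 <- shape[1]; n12 <- shape[1] * shape[2]
  lab <- array(0L, shape)
  todo <- which(supra)
  if (!length(todo)) return(lab)
  offs <- connectivity_offsets(connectivity)
  cur <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      co <- arrayInd(frontier, shape)
      nb <- co[rep(seq_len(nrow(co)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(co)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * n1 + (nb[, 3] - 1L) * n12)
      lin <- lin[supra[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      frontier <- lin
    }
  }
  lab
}

#' Label suprathreshold clusters in a t-map
#'
#' Thresholds a t-map one-sided (positive tail) at voxel-level p < `voxel_p`
#' inside a mask and partitions the surviving voxels into connected
#' components. Components are returned largest-first, with descending peak t
#' as tie-break.
#'
#' @param map A [stat_map()].
#' @param voxel_p One-sided voxel-level p threshold in (0, 1), e.g. 0.005.
#' @param mask A [mask_volume()] on the same grid.
#' @param connectivity 6 (faces, default), 18 or 26.
#' @return A `cluster_table`: tibble with columns `label_id`,
#'   `size_voxels`, `peak_t`, `peak_voxel` (list of 0-based index triples),
#'   `x_mm`, `y_mm`, `z_mm` and list-column `members` (1-based linear voxel
#'   indices). Attributes record `voxel_p`, `connectivity` and `df`.
#' @export
label_clusters <- function(map, voxel_p, mask, connectivity = 6L) {
  stopifnot(inherits(map, "stat_map"), inherits(mask, "mask_volume"))
  check_same_grid(map$grid, mask$grid, "map and mask")
  if (voxel_p <= 0 || voxel_p >= 1) abort("`voxel_p` must be in (0, 1).")
  t_thr <- qt(1 - voxel_p, df = map$df)
  supra <- map$grid$data > t_thr & mask$grid$data > 0
  lab <- label_components(supra, connectivity)
  build_cluster_table(lab, map, voxel_p, connectivity)
}

build_cluster_table <- function(lab, map, voxel_p, connectivity) {
  shape <- dim(lab)
  ids <- which(lab > 0L)
  grid <- map$grid
  if (!length(ids)) {
    out <- tibble(
      label_id = integer(), size_voxels = integer(), peak_t = numeric(),
      peak_voxel = list(), x_mm = numeric(), y_mm = numeric(),
      z_mm = numeric(), members = list()
    )
  } else {
    byc <- unname(split(ids, lab[ids]))
    recs <- lapply(byc, function(members) {
      tv <- grid$data[members]
      best <- members[order(-tv, members)][1]
      pk <- arrayInd(best, shape)[1, ] - 1L
      mm <- voxel_to_mm(grid, pk)
      list(size = length(members), peak_t = max(tv), peak_voxel = pk,
           mm = mm, members = members)
    })
    out <- tibble(
      label_id = seq_along(recs),
      size_voxels = vapply(recs, function(r) r$size, integer(1)),
      peak_t = vapply(recs, function(r) r$peak_t, numeric(1)),
      peak_voxel = lapply(recs, function(r) r$peak_voxel),
      x_mm = vapply(recs, function(r) r$mm[["x"]], numeric(1)),
      y_mm = vapply(recs, function(r) r$mm[["y"]], numeric(1)),
      z_mm = vapply(recs, function(r) r$mm[["z"]], numeric(1)),
      members = lapply(recs, function(r) r$members)
    )
    out <- out[order(-out$size_voxels, -out$peak_t), ]
    out$label_id <- seq_len(nrow(out))
  }
  structure(out,
    voxel_p = voxel_p, connectivity = as.integer(connectivity),
    df = map$df, grid_shape = shape, affine = grid$affine,
    class = c("cluster_table", class(out))
  )
}

# Separable Gaussian smoothing along each axis. `periodic = TRUE` uses
# circular convolution (stationary output -- exact for null-field
# simulation); otherwise zero-padded. `rescale = TRUE` divides by the
# theoretical standard deviation of circularly smoothed unit white noise so
# the output is marginally N(0, 1) when the input is.
smooth_3d <- function(arr, fwhm_mm, voxel_mm, periodic = TRUE,
                      rescale = FALSE) {
  shape <- dim(arr)
  if (length(fwhm_mm) == 1) fwhm_mm <- rep(fwhm_mm, 3)
  if (all(fwhm_mm <= 0)) return(arr)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  var_scale <- 1
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- shape[ax]
    r <- max(1L, ceiling(4 * s))
    if (2L * r + 1L > n) {
      abort("smoothing kernel larger than the volume extent.")
    }
    w <- exp(-(-r:r)^2 / (2 * s^2))
    w <- w / sum(w)
    var_scale <- var_scale * sum(w^2)
    K <- kernel_matrix(w, r, n, periodic)
    arr <- apply_along_axis(arr, K, ax)
  }
  if (rescale) arr <- arr / sqrt(var_scale)
  arr
}

kernel_matrix <- function(w, r, n, periodic) {
  K <- matrix(0, n, n)
  for (d in -r:r) {
    j <- seq_len(n)
    i <- j + d
    if (periodic) {
      i <- ((i - 1L) %% n) + 1L
      K[cbind(i, j)] <- K[cbind(i, j)] + w[d + r + 1L]
    } else {
      ok <- i >= 1L & i <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + w[d + r + 1L]
    }
  }
  K
}

apply_along_axis <- function(arr, K, axis) {
  shape <- dim(arr)
  if (axis == 1) {
    array(K %*% matrix(arr, shape[1]), shape)
  } else if (axis == 2) {
    p <- aperm(arr, c(2, 1, 3))
    p <- array(K %*% matrix(p, shape[2]), c(shape[2], shape[1], shape[3]))
    aperm(p, c(2, 1, 3))
  } else {
    p <- aperm(arr, c(3, 1, 2))
    p <- array(K %*% matrix(p, shape[3]), c(shape[3], shape[1], shape[2]))
    aperm(p, c(2, 3, 1))
  }
}

#' Monte-Carlo cluster-extent threshold
#'
#' Derives the minimum cluster size controlling the family-wise cluster
#' error at `cluster_alpha`, by simulating null fields: white Gaussian noise
#' smoothed to the target FWHM (Gaussian autocorrelation), re-standardized,
#' thresholded one-sided at `voxel_p` inside the mask, and labelled; the
#' maximum cluster size per iteration forms the null distribution, and the
#' threshold is the smallest k with P(max size >= k) <= `cluster_alpha`.
#'
#' @param mask A [mask_volume()].
#' @param smoothness_fwhm_mm Spatial smoothness of the null fields (mm FWHM,
#'   scalar; 0 = independent voxels).
#' @param voxel_p One-sided voxel-level p threshold.
#' @param cluster_alpha Target family-wise cluster error rate.
#' @param n_iterations Number of null fields (>= 100).
#' @param connectivity 6, 18 or 26.
#' @param seed Optional RNG seed.
#' @return An `extent_threshold`: list with `min_cluster_size_voxels`,
#'   `null_max_sizes` (the stored null distribution) and the parameters.
#' @export
monte_carlo_extent_threshold <- function(mask, smoothness_fwhm_mm, voxel_p,
                                         cluster_alpha,
                                         n_iterations = 1000,
                                         connectivity = 6L, seed = NULL) {
  stopifnot(inherits(mask, "mask_volume"))
  if (sum(mask$grid$data) == 0) abort("mask is empty.")
  if (n_iterations < 100) abort("`n_iterations` must be >= 100.")
  if (voxel_p <= 0 || voxel_p >= 1 || cluster_alpha <= 0 ||
      cluster_alpha > 1) {
    abort("`voxel_p` and `cluster_alpha` must be in (0, 1].")
  }
  shape <- dim(mask$grid$data)
  vx <- voxel_sizes(mask$grid)
  z_thr <- qnorm(1 - voxel_p)
  inmask <- mask$grid$data > 0
  max_sizes <- with_seed_or_current(seed, {
    vapply(seq_len(n_iterations), function(i) {
      field <- array(rnorm(prod(shape)), shape)
      if (smoothness_fwhm_mm > 0) {
        field <- smooth_3d(field, smoothness_fwhm_mm, vx,
                           periodic = TRUE, rescale = TRUE)
      }
      supra <- field > z_thr & inmask
      if (!any(supra)) return(0L)
      lab <- label_components(supra, connectivity)
      max(tabulate(lab[lab > 0L]))
    }, integer(1))
  })
  k <- 1L
  while (mean(max_sizes >= k) > cluster_alpha) k <- k + 1L
  structure(
    list(
      voxel_p = voxel_p, cluster_alpha = cluster_alpha,
      min_cluster_size_voxels = k,
      smoothness_fwhm_mm = smoothness_fwhm_mm,
      n_iterations = n_iterations, connectivity = as.integer(connectivity),
      seed = seed, null_max_sizes = max_sizes
    ),
    class = "extent_threshold"
  )
}

#' @export
print.extent_threshold <- function(x, ...) {
  cat(sprintf(
    "<extent_threshold> >= %d voxels (voxel p < %g, cluster alpha %g, %g mm FWHM, %d iterations)\n",
    x$min_cluster_size_voxels, x$voxel_p, x$cluster_alpha,
    x$smoothness_fwhm_mm, x$n_iterations
  ))
  invisible(x)
}

#' Apply a cluster-extent threshold
#'
#' Retains only clusters at least as large as the Monte-Carlo minimum size
#' and annotates each survivor with its empirical cluster-level p: the
#' fraction of null maximum sizes at least as large as the observed size.
#'
#' @param clusters A `cluster_table` from [label_clusters()].
#' @param thr An `extent_threshold` with matching `voxel_p` and
#'   `connectivity`.
#' @return The surviving rows with an added `cluster_p` column.
#' @export
apply_extent_threshold <- function(clusters, thr) {
  stopifnot(inherits(thr, "extent_threshold"))
  if (!isTRUE(all.equal(attr(clusters, "voxel_p"), thr$voxel_p)) ||
      !identical(attr(clusters, "connectivity"), thr$connectivity)) {
    abort("cluster table and extent threshold parameters differ.")
  }
  keep <- clusters$size_voxels >= thr$min_cluster_size_voxels
  out <- clusters[keep, ]
  out$cluster_p <- vapply(
    out$size_voxels,
    function(s) mean(thr$null_max_sizes >= s),
    numeric(1)
  )
  out
}

#' Binary mask dilation
#'
#' Iterative 3D binary dilation with the structuring element implied by
#' `connectivity`. Zero iterations is the identity; the result always
#' contains the input. Note: region-of-interest atlases sometimes label this
#' setting a "2D" dilation in their GUIs; here masks are 3D volumes and the
#' dilation is 3D.
#'
#' @param mask A [mask_volume()].
#' @param iterations Non-negative integer.
#' @param connectivity 6 (default), 18 or 26.
#' @return The dilated [mask_volume()].
#' @export
dilate_mask <- function(mask, iterations, connectivity = 6L) {
  stopifnot(inherits(mask, "mask_volume"))
  if (iterations < 0) abort("`iterations` must be >= 0.")
  m <- mask$grid$data > 0
  offs <- connectivity_offsets(connectivity)
  for (i in seq_len(iterations)) {
    out <- m
    for (r in seq_len(nrow(offs))) {
      out <- out | shift_3d(m, offs[r, ])
    }
    m <- out
  }
  mask_volume(volume_grid(array(as.numeric(m), dim(m)),
                          mask$grid$affine))
}

# Shift a 3D logical array by an integer offset, filling with FALSE.
shift_3d <- function(a, d) {
  shape <- dim(a)
  out <- array(FALSE, shape)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- shape[ax]
    if (d[ax] >= 0) {
      dst[[ax]] <- seq_len(n - d[ax]) + d[ax]
      src[[ax]] <- seq_len(n - d[ax])
    } else {
      dst[[ax]] <- seq_len(n + d[ax])
      src[[ax]] <- seq_len(n + d[ax]) - d[ax]
    }
    if (!length(dst[[ax]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
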