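# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately uses a different algorithm from the package code
# it checks.

unit_grid <- function(shape, voxel = 3, origin = c(-90, -126, -72)) {
  volume_grid(array(0, shape), mni_affine(rep(voxel, 3), origin))
}

full_mask <- function(shape, voxel = 3, origin = c(-90, -126, -72)) {
  mask_volume(volume_grid(array(1, shape),
                          mni_affine(rep(voxel, 3), origin)))
}

# Connected components by iterative label propagation: start with unique
# labels, repeatedly replace each voxel's label by the minimum over itself
# and its suprathreshold neighbours until stable. O(n * diameter) but a
# completely different algorithm from the package's frontier BFS.
oracle_label <- function(supra, connectivity) {
  shape <- dim(supra)
  offs <- cuetopo:::connectivity_offsets(connectivity)
  lab <- array(0, shape)
  lab[supra] <- seq_len(sum(supra))
  repeat {
    prev <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- oracle_shift(lab, offs[r, ])
      upd <- supra & sh > 0 & (lab == 0 | sh < lab)
      lab[upd] <- sh[upd]
    }
    if (identical(lab, prev)) break
  }
  lab
}

oracle_shift <- function(a, d) {
  shape <- dim(a)
  out <- array(0, shape)
  idx_src <- idx_dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- shape[ax]
    if (d[ax] >= 0) {
      idx_dst[[ax]] <- seq_len(n - d[ax]) + d[ax]
      idx_src[[ax]] <- seq_len(n - d[ax])
    } else {
      idx_dst[[ax]] <- seq_len(n + d[ax])
      idx_src[[ax]] <- seq_len(n + d[ax]) - d[ax]
    }
    if (!length(idx_dst[[ax]])) return(out)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Sizes of the components of a labelled array, as a sorted vector.
component_sizes <- function(lab) {
  sort(as.numeric(table(lab[lab > 0])))
}

# Global optimum of 2-means by exhaustive enumeration of all 2-partitions.
oracle_kmeans2 <- function(P) {
  n <- nrow(P)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    a <- as.integer(intToBits(code))[1:n]
    g1 <- P[a == 1, , drop = FALSE]
    g2 <- P[a == 0, , drop = FALSE]
    if (!nrow(g1) || !nrow(g2)) next
    w <- sum(sweep(g1, 2, colMeans(g1))^2) +
      sum(sweep(g2, 2, colMeans(g2))^2)
    if (w < best) best <- w
  }
  best
}

# Silhouettes by the textbook double loop.
oracle_silhouette <- function(P, a) {
  n <- nrow(P)
  d <- as.matrix(dist(P))
  vapply(seq_len(n), function(i) {
    own <- which(a == a[i] & seq_len(n) != i)
    if (!length(own)) return(0)
    ai <- mean(d[i, own])
    bi <- min(vapply(setdiff(unique(a), a[i]), function(cl) {
      mean(d[i, a == cl])
    }, numeric(1)))
    if (max(ai, bi) == 0) 0 else (bi - ai) / max(ai, bi)
  }, numeric(1))
}

# Pearson chi-square from first principles.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

make_stat_map <- function(arr, df = 100, voxel = 3) {
  stat_map(volume_grid(arr, mni_affine(rep(voxel, 3))), df)
}
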