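test_that("a single suprathreshold voxel forms one size-1 cluster", {
  arr <- array(0, c(5, 5, 5))
  arr[3, 3, 3] <- 10
  map <- make_stat_map(arr, df = 50)
  cl <- label_clusters(map, 0.005, full_mask(c(5, 5, 5)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size_voxels, 1L)
  expect_equal(cl$peak_t, 10)
  expect_equal(cl$peak_voxel[[1]], c(2L, 2L, 2L)) # 0-based
})

test_that("connectivity semantics distinguish corner contact", {
  arr <- array(0, c(4, 4, 4))
  arr[1, 1, 1] <- 8
  arr[2, 2, 2] <- 8 # shares only a corner
  map <- make_stat_map(arr, df = 50)
  mask <- full_mask(c(4, 4, 4))
  expect_equal(nrow(label_clusters(map, 0.005, mask, 6)), 2L)
  expect_equal(nrow(label_clusters(map, 0.005, mask, 18)), 2L)
  expect_equal(nrow(label_clusters(map, 0.005, mask, 26)), 1L)
  # edge contact joins at 18 but not 6
  arr2 <- array(0, c(4, 4, 4))
  arr2[1, 1, 1] <- 8
  arr2[2, 2, 1] <- 8
  map2 <- make_stat_map(arr2, df = 50)
  expect_equal(nrow(label_clusters(map2, 0.005, mask, 6)), 2L)
  expect_equal(nrow(label_clusters(map2, 0.005, mask, 18)), 1L)
})

test_that("component labelling agrees with a flood-fill oracle", {
  for (conn in c(6L, 18L, 26L)) {
    supra <- withr::with_seed(40L + conn, {
      array(runif(12^3) < 0.15, c(12, 12, 12))
    })
    lab_pkg <- cuetopo:::label_components(supra, conn)
    lab_or <- oracle_label(supra, conn)
    expect_equal(max(lab_pkg), length(unique(lab_or[lab_or > 0])),
                 info = paste("connectivity", conn))
    expect_equal(component_sizes(lab_pkg), component_sizes(lab_or),
                 info = paste("connectivity", conn))
    # partition property: labels cover exactly the suprathreshold set
    expect_equal(lab_pkg > 0, supra)
  }
})

test_that("cluster tables partition the suprathreshold set", {
  arr <- withr::with_seed(44L, array(rnorm(10^3, sd = 2), c(10, 10, 10)))
  map <- make_stat_map(arr, df = 60)
  mask <- full_mask(c(10, 10, 10))
  cl <- label_clusters(map, 0.05, mask)
  members <- unlist(cl$members)
  expect_equal(anyDuplicated(members), 0L)
  t_thr <- qt(0.95, 60)
  expect_setequal(members, which(arr > t_thr))
  # ordering: sizes descending
  expect_true(all(diff(cl$size_voxels) <= 0))
  # peak is a member and attains the member max
  for (i in seq_len(nrow(cl))) {
    expect_equal(cl$peak_t[i], max(arr[cl$members[[i]]]))
  }
})

test_that("vacuous cluster alpha gives a threshold of one voxel", {
  mask <- full_mask(c(8, 8, 8))
  thr <- monte_carlo_extent_threshold(mask, 0, 0.01, 1,
                                      n_iterations = 100, seed = 1)
  expect_equal(thr$min_cluster_size_voxels, 1L)
})

test_that("unsmoothed MC threshold matches an independent-voxel oracle", {
  mask <- full_mask(c(20, 20, 20))
  thr <- monte_carlo_extent_threshold(mask, 0, 0.005, 0.05,
                                      n_iterations = 400, seed = 2)
  # oracle: direct Bernoulli fields, oracle labelling
  oracle_max <- withr::with_seed(1002L, {
    vapply(1:400, function(i) {
      supra <- array(runif(8000) < 0.005, c(20, 20, 20))
      if (!any(supra)) return(0)
      max(component_sizes(oracle_label(supra, 6L)))
    }, numeric(1))
  })
  k <- 1L
  while (mean(oracle_max >= k) > 0.05) k <- k + 1L
  expect_equal(thr$min_cluster_size_voxels, k)
})

test_that("extent threshold is monotone in voxel p and in smoothness", {
  mask <- full_mask(c(14, 14, 14))
  t_strict <- monte_carlo_extent_threshold(mask, 4, 0.005, 0.05,
                                           n_iterations = 150, seed = 3)
  t_loose <- monte_carlo_extent_threshold(mask, 4, 0.01, 0.05,
                                          n_iterations = 150, seed = 3)
  expect_lte(t_strict$min_cluster_size_voxels,
             t_loose$min_cluster_size_voxels)
  ks <- vapply(c(0, 4, 8), function(fw) {
    monte_carlo_extent_threshold(mask, fw, 0.005, 0.05,
                                 n_iterations = 150,
                                 seed = 4)$min_cluster_size_voxels
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("apply_extent_threshold keeps 48 and drops 47 at min size 48", {
  arr <- array(0, c(12, 12, 12))
  arr[1:4, 1:4, 1:3] <- 10             # 48 voxels
  # second cluster: 47 voxels in a separated slab
  slab <- expand.grid(x = 6:12, y = 6:12, z = 8)[1:47, ]
  arr[cbind(slab$x, slab$y, slab$z)] <- 9
  map <- make_stat_map(arr, df = 100)
  cl <- label_clusters(map, 0.005, full_mask(c(12, 12, 12)))
  expect_equal(sort(cl$size_voxels), c(47L, 48L))
  thr <- structure(
    list(voxel_p = 0.005, cluster_alpha = 0.05,
         min_cluster_size_voxels = 48L, smoothness_fwhm_mm = 8,
         n_iterations = 1000, connectivity = 6L, seed = 1,
         null_max_sizes = c(rep(10L, 950), rep(60L, 50))),
    class = "extent_threshold"
  )
  kept <- apply_extent_threshold(cl, thr)
  expect_equal(kept$size_voxels, 48L)
  expect_true(all(kept$cluster_p <= 0.05))
  expect_equal(kept$cluster_p, mean(thr$null_max_sizes >= 48))
  # mismatched parameters are rejected
  thr_bad <- thr
  thr_bad$voxel_p <- 0.01
  expect_error(apply_extent_threshold(cl, thr_bad), "differ")
  # empty input passes through empty
  cl0 <- label_clusters(make_stat_map(array(0, c(4, 4, 4)), 100),
                        0.005, full_mask(c(4, 4, 4)))
  expect_equal(nrow(apply_extent_threshold(cl0, thr)), 0L)
})

test_that("mask dilation grows by the structuring element", {
  arr <- array(0, c(7, 7, 7))
  arr[4, 4, 4] <- 1
  m <- mask_volume(volume_grid(arr, mni_affine()))
  expect_equal(dilate_mask(m, 0)$grid$data, m$grid$data)
  expect_equal(sum(dilate_mask(m, 1, 6)$grid$data), 7)
  expect_equal(sum(dilate_mask(m, 1, 18)$grid$data), 19)
  expect_equal(sum(dilate_mask(m, 1, 26)$grid$data), 27)
  # iteration 3 from the atlas-style setting: monotone growth, superset
  d3 <- dilate_mask(m, 3, 6)
  expect_true(all(d3$grid$data >= m$grid$data))
  expect_equal(sum(d3$grid$data), 63) # octahedron |x|+|y|+|z| <= 3
})

test_that("smoothed rescaled null fields stay standard normal", {
  field <- withr::with_seed(55L, array(rnorm(24^3), c(24, 24, 24)))
  sm <- cuetopo:::smooth_3d(field, 8, c(3, 3, 3), periodic = TRUE,
                            rescale = TRUE)
  expect_equal(mean(sm), 0, tolerance = 0.05)
  expect_equal(sd(as.numeric(sm)), 1, tolerance = 0.05)
  expect_error(
    cuetopo:::smooth_3d(array(0, c(4, 4, 4)), 20, c(3, 3, 3)),
    "kernel larger"
  )
})
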