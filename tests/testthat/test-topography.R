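two_blob_points <- function(n_each = 8, gap = 1000, spread = 1,
                            seed = 70L) {
  withr::with_seed(seed, {
    rbind(
      matrix(rnorm(3 * n_each, sd = spread), ncol = 3),
      matrix(rnorm(3 * n_each, sd = spread), ncol = 3) + gap
    )
  })
}

test_that("k-means++ seeding hits degenerate cases exactly", {
  P <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 0, 0, 10), ncol = 3,
              byrow = TRUE)
  seeds <- kmeanspp_seed(P, 4, seed = 1)
  expect_equal(nrow(seeds), 4L)
  # a permutation of the points
  expect_equal(seeds[order(seeds[, 1], seeds[, 2], seeds[, 3]), ],
               P[order(P[, 1], P[, 2], P[, 3]), ])
  s1 <- kmeanspp_seed(P, 1, seed = 2)
  expect_true(any(apply(P, 1, function(p) all(p == s1[1, ]))))
  expect_error(kmeanspp_seed(P, 5), "distinct")
})

test_that("D-squared seeding separates two tight distant groups", {
  P <- two_blob_points()
  hits <- withr::with_seed(71L, {
    vapply(1:1000, function(i) {
      s <- cuetopo:::kmeanspp_seed_impl(P, 2)
      (s[1, 1] < 500) != (s[2, 1] < 500)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.99)
})

test_that("kmeans_fit reaches the exhaustive-enumeration global optimum", {
  for (rep in 1:5) {
    P <- withr::with_seed(80L + rep,
                          matrix(rnorm(8 * 3, sd = 10), ncol = 3))
    sol <- kmeans_fit(P, 2, n_restarts = 50, seed = rep)
    expect_equal(sol$wcss, oracle_kmeans2(P), tolerance = 1e-9)
  }
})

test_that("k equal to n gives zero wcss", {
  P <- matrix(rnorm(15), ncol = 3)
  sol <- kmeans_fit(P, 5, n_restarts = 5, seed = 1,
                    compute_silhouettes = FALSE)
  expect_lt(sol$wcss, 1e-12)
})

test_that("best-of-many restarts dominates the single restart", {
  P <- withr::with_seed(85L, matrix(rnorm(90, sd = 20), ncol = 3))
  one <- kmeans_fit(P, 4, n_restarts = 1, seed = 9,
                    compute_silhouettes = FALSE)
  many <- kmeans_fit(P, 4, n_restarts = 100, seed = 9,
                     compute_silhouettes = FALSE)
  expect_lte(many$wcss, one$wcss + 1e-9)
})

test_that("the two-phase fit is competitive with stats::kmeans", {
  pts <- sample_hotspots(mixture_spec(), 261, seed = 5)
  P <- as.matrix(pts[, c("x_mm", "y_mm", "z_mm")])
  ours <- kmeans_fit(P, 3, n_restarts = 100, seed = 6)
  ref <- withr::with_seed(7L,
    stats::kmeans(P, 3, nstart = 100, iter.max = 100))
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("planted centroids are recovered on a study-sized cohort", {
  spec <- mixture_spec()
  pts <- sample_hotspots(spec, 261, seed = 10)
  sol <- kmeans_fit(pts, 3, n_restarts = 100, seed = 11)
  d <- sqrt(outer(rowSums(sol$centroids^2), rowSums(spec$centroids^2),
                  "+") - 2 * sol$centroids %*% t(spec$centroids))
  nearest <- apply(d, 1, which.min)
  expect_equal(sort(nearest), 1:3) # each planted centroid matched once
  expect_true(all(d[cbind(1:3, nearest)] < 6))
})

test_that("assignment invariants hold: nearest centroid wins", {
  pts <- sample_hotspots(mixture_spec(), 100, seed = 12)
  sol <- kmeans_fit(pts, 4, n_restarts = 20, seed = 13)
  P <- as.matrix(pts[, c("x_mm", "y_mm", "z_mm")])
  D <- cuetopo:::dist2_to_centroids(P, sol$centroids)
  expect_equal(sol$assignments, unname(max.col(-D, "first")))
  expect_true(all(sol$silhouettes >= -1 & sol$silhouettes <= 1))
  expect_gte(sol$wcss, 0)
})

test_that("clustering is invariant to point order and rigid translation", {
  P <- two_blob_points(n_each = 15, gap = 80, spread = 5, seed = 75L)
  base <- kmeans_fit(P, 2, n_restarts = 50, seed = 1)
  perm <- withr::with_seed(76L, sample.int(nrow(P)))
  reord <- kmeans_fit(P[perm, ], 2, n_restarts = 50, seed = 2)
  shifted <- kmeans_fit(sweep(P, 2, c(100, -50, 7), "+"), 2,
                        n_restarts = 50, seed = 3)
  expect_equal(reord$wcss, base$wcss, tolerance = 1e-9)
  expect_equal(shifted$wcss, base$wcss, tolerance = 1e-9)
  sort_c <- function(C) C[order(C[, 1]), ]
  expect_equal(sort_c(reord$centroids), sort_c(base$centroids),
               tolerance = 1e-9)
  expect_equal(sort_c(shifted$centroids),
               sort_c(base$centroids) +
                 matrix(c(100, -50, 7), 2, 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("silhouettes match hand computation and cluster::silhouette", {
  # 6 hand-placed points, 2 clusters
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0,
                10, 0, 0, 11, 0, 0, 10, 1, 0), ncol = 3, byrow = TRUE)
  a <- c(1, 1, 1, 2, 2, 2)
  s <- silhouette_scores(P, a)
  expect_equal(as.numeric(s), oracle_silhouette(P, a), tolerance = 1e-12)
  ref <- cluster::silhouette(a, dist(P))
  expect_equal(as.numeric(s), as.numeric(ref[, "sil_width"]),
               tolerance = 1e-12)

  # separation limit
  Pf <- two_blob_points(n_each = 10, gap = 100, spread = 1, seed = 77L)
  af <- rep(1:2, each = 10)
  expect_gt(mean(silhouette_scores(Pf, af)), 0.95)

  # coincident points in 2 forced clusters: s = 0 by convention
  P0 <- matrix(0, 4, 3)
  expect_equal(as.numeric(silhouette_scores(P0, c(1, 1, 2, 2))),
               rep(0, 4))
  # singletons score 0
  expect_equal(as.numeric(silhouette_scores(P, c(1, 1, 1, 1, 1, 2)))[6], 0)
  expect_error(silhouette_scores(P, rep(1, 6)), "2 non-empty")
})

test_that("select_k recovers the planted component count", {
  pts3 <- sample_hotspots(mixture_spec(), 261, seed = 20)
  sel3 <- select_k(pts3, 2:6, n_restarts = 100, seed = 21)
  expect_equal(sel3$best$k, 3L)
  expect_false(sel3$weak_structure)
  expect_equal(sel3$diagnostics$k, 2:6)

  spec2 <- mixture_spec(centroids = rbind(c(0, 60, 0), c(40, 10, 40)),
                        weights = c(0.5, 0.5), dispersion_mm = 8)
  pts2 <- sample_hotspots(spec2, 150, seed = 22)
  sel2 <- select_k(pts2, 2:6, n_restarts = 100, seed = 23)
  expect_equal(sel2$best$k, 2L)

  # a single Gaussian cloud has no silhouette structure
  cloud <- mixture_spec(centroids = rbind(c(0, 40, 20)), weights = 1,
                        dispersion_mm = 15)
  ptsc <- sample_hotspots(cloud, 150, seed = 24)
  selc <- select_k(ptsc, 2:5, n_restarts = 50, seed = 25)
  # no silhouette structure: every k scores well below the planted case
  expect_lt(max(selc$diagnostics$mean_silhouette),
            min(sel3$diagnostics$mean_silhouette[sel3$diagnostics$k == 3]))
  # the weak-structure flag fires at its configured threshold
  selw <- select_k(ptsc, 2:5, n_restarts = 50, seed = 25,
                   weak_threshold = 0.45)
  expect_true(selw$weak_structure)
  expect_false(sel3$weak_structure)
  expect_error(select_k(ptsc, integer(0)), "empty")
})

test_that("planted mixing proportions are recovered within 3 SE", {
  spec <- mixture_spec()
  pts <- sample_hotspots(spec, 261, seed = 26)
  sol <- kmeans_fit(pts, 3, n_restarts = 100, seed = 27)
  d <- sqrt(outer(rowSums(sol$centroids^2), rowSums(spec$centroids^2),
                  "+") - 2 * sol$centroids %*% t(spec$centroids))
  match_comp <- apply(d, 1, which.min)
  shares <- sol$sizes / 261
  for (cl in 1:3) {
    w <- spec$weights[match_comp[cl]]
    se <- sqrt(w * (1 - w) / 261)
    expect_lt(abs(shares[cl] - w), 3 * se)
  }
})

test_that("chi-square cross-tabulation matches first principles", {
  set <- tibble::tibble(group = rep(c("cocaine", "alcohol"), each = 30))
  # identical distribution across clusters
  a_even <- rep(rep(1:2, each = 15), 2)
  ct0 <- cross_tab(set, a_even)
  expect_equal(ct0$chi2, 0)
  expect_equal(ct0$p, 1)

  # the 10/20 vs 20/10 table
  set2 <- tibble::tibble(group = rep(c("g1", "g2"), each = 30))
  a2 <- c(rep(1, 10), rep(2, 20), rep(1, 20), rep(2, 10))
  ct <- cross_tab(set2, a2)
  expect_equal(ct$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(ct$chi2, oracle_chisq(unclass(ct$table)),
               tolerance = 1e-12)
  expect_equal(ct$df, 1L)
  expect_equal(ct$p, pchisq(20 / 3, 1, lower.tail = FALSE))

  expect_error(cross_tab(set2, rep(1, 60)), "degenerate")
  expect_warning(
    cross_tab(tibble::tibble(group = rep(c("a", "b"), 4)),
              rep(1:2, each = 4)),
    "below 5"
  )
})

test_that("chi-square p-values are uniform under the null", {
  ps <- withr::with_seed(90L, {
    vapply(1:60, function(i) {
      g <- sample(c("cocaine", "alcohol", "nicotine"), 90, TRUE)
      a <- sample(1:3, 90, TRUE)
      suppressWarnings(
        cross_tab(tibble::tibble(group = g), a)$p
      )
    }, numeric(1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("tidiers expose clusters, points and model summaries", {
  pts <- sample_hotspots(mixture_spec(), 80, seed = 30)
  sol <- kmeans_fit(pts, 3, n_restarts = 20, seed = 31)
  td <- tidy(sol)
  expect_equal(nrow(td), 3L)
  expect_equal(sum(td$size), 80L)
  expect_equal(sum(td$share), 1)
  gl <- glance(sol)
  expect_equal(gl$k, 3L)
  expect_equal(gl$wcss, sol$wcss)
  tp <- tidy(sol, "points")
  expect_equal(nrow(tp), 80L)
})
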