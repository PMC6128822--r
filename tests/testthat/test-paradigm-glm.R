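test_that("paradigm arithmetic matches the task description", {
  p <- build_paradigm()
  expect_equal(attr(p, "total_duration_s"), 720) # 12 minutes
  expect_equal(sum(p$condition == "Drug"), 6L)
  expect_equal(sum(p$condition == "Neutral"), 6L)
  expect_true(all(p$duration_s == 24))
  # blocks tile the task without overlap
  expect_equal(p$onset_s, seq(0, 720 - 24, by = 24))

  p1 <- build_paradigm(n_epochs = 1)
  expect_equal(attr(p1, "total_duration_s"), 120)
  expect_equal(sum(p1$condition == "Drug"), 1L)

  # the cycle fill also covers every condition each 120 s on average
  pc <- build_paradigm(epoch_fill = "cycle")
  expect_equal(attr(pc, "total_duration_s"), 720)
  expect_equal(sum(pc$condition %in% c("Drug", "Neutral", "Blur",
                                       "Rest")), 30L)

  expect_error(build_paradigm(block_s = 23), "integer multiple")
})

test_that("hrf is a unit-peak double gamma with the canonical shape", {
  expect_equal(hrf(0), 0)
  grid <- seq(0, 32, by = 0.1)
  vals <- hrf(grid)
  expect_equal(max(vals), 1, tolerance = 1e-6)
  tmax <- grid[which.max(vals)]
  expect_gte(tmax, 4.5)
  expect_lte(tmax, 6.5)
  expect_lt(abs(hrf(32)), 0.01)
  # undershoot exists and is negative after ~10 s
  expect_lt(min(vals[grid > 10 & grid < 25]), 0)
  expect_equal(hrf(-1), 0)
})

test_that("build_design is deterministic with equal per-epoch loading", {
  p <- build_paradigm()
  d1 <- build_design(p, 2.2, 327)
  d2 <- build_design(p, 2.2, 327)
  expect_identical(d1$X, d2$X)
  expect_setequal(colnames(d1$X), c("Drug", "Neutral", "Blur",
                                    "intercept"))
  # Drug regressor mass per steady-state epoch is equal (epochs 2..6;
  # epoch 1 differs only by the convolution ramp-in)
  vol_t <- (0:326) * 2.2
  drug <- d1$X[, "Drug"]
  mass <- vapply(2:6, function(e) {
    sum(drug[vol_t >= (e - 1) * 120 & vol_t < e * 120])
  }, numeric(1))
  expect_true(all(mass > 0))
  # epochs are identical up to the TR-grid sampling of their boundaries
  expect_lt(diff(range(mass)) / mean(mass), 0.02)
  # exact equality on the microtime grid: per-epoch integral of the
  # convolved regressor, by direct numeric integration
  dt <- 0.01
  tg <- seq(0, 720, by = dt)
  box <- as.numeric((tg %% 120) < 24)
  hr <- hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(hr), type = "open")[seq_along(tg)] * dt
  ints <- vapply(2:6, function(e) {
    sum(conv[tg >= (e - 1) * 120 & tg < e * 120]) * dt
  }, numeric(1))
  expect_lt(diff(range(ints)) / mean(ints), 1e-6)
})

test_that("zero motion columns are dropped and bad motion is rejected", {
  p <- build_paradigm(n_epochs = 2)
  d <- build_design(p, 2.2, 109, motion = matrix(0, 109, 6))
  expect_equal(attr(d, "dropped"),
               paste0("motion_", c("x", "y", "z", "yaw", "pitch", "roll")))
  expect_equal(ncol(d$X), 4L) # 3 conditions + intercept
  expect_error(build_design(p, 2.2, 109, motion = matrix(1, 109, 5)),
               "n_volumes x 6")
  # constant nonzero motion column collides with the intercept
  expect_error(
    build_design(p, 2.2, 109,
                 motion = cbind(matrix(rnorm(109 * 5), 109, 5), 1)),
    "rank deficient"
  )
})

test_that("first-level GLM recovers exact multiples of a regressor", {
  p <- build_paradigm(n_epochs = 2)
  n_vol <- floor(240 / 2.2)
  d <- build_design(p, 2.2, n_vol)
  shape <- c(4, 4, 3)
  drug <- d$X[, "Drug"]
  vol <- array(rep(3.5 * drug, each = prod(shape)), c(shape, n_vol))
  mask <- full_mask(shape)
  fit <- fit_first_level(vol, d, c(Drug = 1), mask)
  expect_equal(max(abs(fit$effect - 3.5)), 0, tolerance = 1e-9)
  expect_lt(max(fit$resid_var), 1e-18)
  expect_equal(fit$df, n_vol - ncol(d$X))
})

test_that("first-level type-I error is near nominal under pure noise", {
  p <- build_paradigm(n_epochs = 3)
  n_vol <- floor(360 / 2.2)
  d <- build_design(p, 2.2, n_vol)
  shape <- c(12, 12, 12)
  mask <- full_mask(shape)
  vol <- withr::with_seed(31L,
    array(rnorm(prod(shape) * n_vol), c(shape, n_vol)))
  fit <- fit_first_level(vol, d, c(Drug = 1, Neutral = -1), mask)
  pvals <- pt(fit$t$grid$data, df = fit$df, lower.tail = FALSE)
  frac <- mean(pvals < 0.005)
  n <- prod(shape)
  se <- sqrt(0.005 * 0.995 / n)
  expect_lt(abs(frac - 0.005), 4 * se)
})

test_that("t-map is invariant to a joint volume/design permutation", {
  p <- build_paradigm(n_epochs = 2)
  n_vol <- floor(240 / 2.2)
  d <- build_design(p, 2.2, n_vol)
  shape <- c(3, 3, 3)
  mask <- full_mask(shape)
  vol <- withr::with_seed(32L, {
    sig <- array(rep(d$X[, "Drug"], each = prod(shape)), c(shape, n_vol))
    sig + array(rnorm(prod(shape) * n_vol), c(shape, n_vol))
  })
  fit <- fit_first_level(vol, d, c(Drug = 1, Neutral = -1), mask)
  perm <- withr::with_seed(33L, sample.int(n_vol))
  dp <- d
  dp$X <- d$X[perm, ]
  fit_p <- fit_first_level(vol[, , , perm], dp, c(Drug = 1, Neutral = -1),
                           mask)
  expect_equal(fit_p$t$grid$data, fit$t$grid$data, tolerance = 1e-9)
})

test_that("adding a constant changes only the intercept", {
  p <- build_paradigm(n_epochs = 2)
  n_vol <- floor(240 / 2.2)
  d <- build_design(p, 2.2, n_vol)
  shape <- c(2, 2, 2)
  mask <- full_mask(shape)
  vol <- withr::with_seed(34L,
    array(rnorm(prod(shape) * n_vol), c(shape, n_vol)))
  f1 <- fit_first_level(vol, d, c(Drug = 1, Neutral = -1), mask)
  f2 <- fit_first_level(vol + 100, d, c(Drug = 1, Neutral = -1), mask)
  expect_equal(f1$t$grid$data, f2$t$grid$data, tolerance = 1e-8)
  expect_equal(f1$effect, f2$effect, tolerance = 1e-9)
})

test_that("group-level t matches the closed form and guards degeneracy", {
  maps <- withr::with_seed(35L, {
    lapply(1:8, function(i) array(rnorm(8, mean = 0.4), c(2, 2, 2)))
  })
  gm <- fit_group_level(maps, mni_affine())
  v <- vapply(maps, function(m) m[1, 1, 1], numeric(1))
  t_hand <- mean(v) / (sd(v) / sqrt(8))
  expect_equal(gm$grid$data[1, 1, 1], t_hand, tolerance = 1e-12)
  expect_equal(gm$df, 7)

  same <- lapply(1:4, function(i) array(1, c(2, 2, 2)))
  gs <- fit_group_level(same, mni_affine())
  expect_true(all(gs$grid$data == 1e6))
  expect_true(attr(gs, "saturated"))
  expect_error(fit_group_level(same[1], mni_affine()), "at least 2")
})

test_that("a planted group effect peaks at the planted locus", {
  shape <- c(9, 9, 9)
  centre <- c(5, 5, 5)
  blob <- array(0, shape)
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    blob[i, j, k] <- exp(-sum((c(i, j, k) - centre)^2) / (2 * 1.5^2))
  }
  maps <- withr::with_seed(36L, {
    lapply(1:10, function(s) blob + array(rnorm(prod(shape), sd = 0.15),
                                          shape))
  })
  gm <- fit_group_level(maps, mni_affine())
  peak <- arrayInd(which.max(gm$grid$data), shape)[1, ]
  expect_true(all(abs(peak - centre) <= 2))
})
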