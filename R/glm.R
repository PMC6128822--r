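#' Fit the first-level GLM voxelwise
#'
#' Ordinary least squares of each in-mask voxel time course on the design
#' matrix, followed by the contrast t-statistic. For contrast weights c the
#' per-voxel statistic is t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c) with
#' df = n_volumes - rank(X). Voxels whose residual variance is exactly zero
#' but whose contrast effect is not (noiseless synthetic data) are assigned
#' the guard value `t_sentinel` and flagged via the `saturated` attribute.
#'
#' @param volume4d 4D numeric array (x, y, z, time).
#' @param design A `design_matrix` from [build_design()].
#' @param contrast Numeric contrast weights, either length `ncol(X)` or a
#'   named vector over a subset of columns (unnamed columns get weight 0),
#'   e.g. `c(Drug = 1, Neutral = -1)`.
#' @param mask A `mask_volume` on the same spatial grid.
#' @param affine Spatial affine of `volume4d` (defaults to the mask's).
#' @param t_sentinel Guard value replacing infinite t-statistics.
#' @return A `contrast_result`: list with `effect` (3D contrast-effect map),
#'   `t` (a [stat_map()]), `resid_var` (3D map), `df`.
#' @export
fit_first_level <- function(volume4d, design, contrast, mask,
                            affine = NULL, t_sentinel = 1e6) {
  stopifnot(inherits(design, "design_matrix"), inherits(mask, "mask_volume"))
  d <- dim(volume4d)
  if (length(d) != 4L) abort("`volume4d` must be a 4D array.")
  if (!identical(d[1:3], dim(mask$grid$data))) {
    abort("mask and volume shapes differ.")
  }
  X <- design$X
  if (d[4] != nrow(X)) abort("volume count does not match design rows.")
  cw <- expand_contrast(contrast, colnames(X))
  affine <- affine %||% mask$grid$affine

  inmask <- which(mask$grid$data > 0)
  Y <- matrix(volume4d, nrow = prod(d[1:3]), ncol = d[4])[inmask, ,
                                                          drop = FALSE]
  qrX <- qr(X)
  rk <- qrX$rank
  if (rk < ncol(X)) abort("singular normal equations: design rank deficient.")
  df <- nrow(X) - rk
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- t(qr.coef(qrX, t(Y)))              # voxels x p
  fitted <- beta %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  sigma2 <- rss / df
  eff <- drop(beta %*% cw)
  se <- sqrt(sigma2 * drop(t(cw) %*% XtXinv %*% cw))
  tv <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0,
                                        sign(eff) * t_sentinel))
  saturated <- se == 0 & eff != 0

  shape <- d[1:3]
  tmap <- array(0, shape); tmap[inmask] <- tv
  emap <- array(0, shape); emap[inmask] <- eff
  vmap <- array(0, shape); vmap[inmask] <- sigma2
  structure(
    list(
      effect = emap,
      t = stat_map(volume_grid(tmap, affine), df),
      resid_var = vmap,
      df = df
    ),
    saturated = any(saturated),
    class = "contrast_result"
  )
}

expand_contrast <- function(contrast, cols) {
  if (!is.null(names(contrast)) && any(nzchar(names(contrast)))) {
    bad <- setdiff(names(contrast), cols)
    if (length(bad)) {
      abort(paste0("contrast names not in design: ",
                   paste(bad, collapse = ", ")))
    }
    cw <- setNames(numeric(length(cols)), cols)
    cw[names(contrast)] <- contrast
  } else {
    if (length(contrast) != length(cols)) {
      abort("contrast length does not match design columns.")
    }
    cw <- as.numeric(contrast)
  }
  cw
}

#' Second-level one-sample t-map across subjects
#'
#' Random-effects group inference: a voxelwise one-sample t-test on
#' per-subject contrast-effect maps, pooled or within each group. df = n - 1
#' for the subjects entering each test. Degenerate voxels with zero
#' between-subject variance but nonzero mean are guarded at `t_sentinel`
#' and flagged.
#'
#' @param contrast_maps List of 3D arrays (one per subject), all on a
#'   common grid.
#' @param affine Shared 4x4 voxel-to-mm affine.
#' @param group_labels Optional per-subject labels; with `by_group = TRUE`
#'   one stat map per group is returned.
#' @param by_group Split by `group_labels` instead of pooling.
#' @param t_sentinel Guard value for infinite t.
#' @return A [stat_map()] (pooled), or a named list of them (by group).
#' @export
fit_group_level <- function(contrast_maps, affine, group_labels = NULL,
                            by_group = FALSE, t_sentinel = 1e6) {
  if (by_group) {
    stopifnot(!is.null(group_labels),
              length(group_labels) == length(contrast_maps))
    groups <- split(seq_along(contrast_maps), group_labels)
    return(lapply(groups, function(ix) {
      fit_group_level(contrast_maps[ix], affine, t_sentinel = t_sentinel)
    }))
  }
  n <- length(contrast_maps)
  if (n < 2) abort("need at least 2 subjects per test.")
  shape <- dim(contrast_maps[[1]])
  for (m in contrast_maps) {
    if (!identical(dim(m), shape)) abort("subject maps on different grids.")
  }
  Y <- vapply(contrast_maps, as.numeric, numeric(prod(shape)))
  mu <- rowMeans(Y)
  sd <- sqrt(rowSums((Y - mu)^2) / (n - 1))
  se <- sd / sqrt(n)
  tv <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * t_sentinel))
  out <- stat_map(volume_grid(array(tv, shape), affine), n - 1)
  attr(out, "saturated") <- any(se == 0 & mu != 0)
  out
}
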