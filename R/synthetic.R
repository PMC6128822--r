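#' Spatial mixture specification for synthetic hotspot cohorts
#'
#' Describes the generative model of hotspot coordinates: a mixture of
#' isotropic Gaussian components in frontal cortex. The defaults encode the
#' three-component frontal topography used throughout the package's worked
#' examples -- medial prefrontal/anterior cingulate, left lateral prefrontal
#' and right lateral prefrontal components at MNI (7, 50, 4), (-40, 24, 25)
#' and (30, 18, 41) with mixing proportions 0.40/0.32/0.28 -- and a 12 mm
#' isotropic within-component dispersion, which makes the components
#' overlapping but silhouette-separable.
#'
#' @param centroids k x 3 matrix (or list of length-3 vectors) of MNI mm
#'   component centres.
#' @param weights Mixing proportions, non-negative, summing to 1
#'   (tolerance 1e-9).
#' @param dispersion_mm Per-component isotropic standard deviation(s), > 0
#'   (scalar recycled).
#' @param group_weights Optional per-group mixing proportions over
#'   `c("cocaine", "alcohol", "nicotine")`; default equal.
#' @return A `mixture_spec` object.
#' @export
mixture_spec <- function(centroids = rbind(c(7, 50, 4),
                                           c(-40, 24, 25),
                                           c(30, 18, 41)),
                         weights = c(0.40, 0.32, 0.28),
                         dispersion_mm = 12,
                         group_weights = NULL) {
  if (is.list(centroids)) centroids <- do.call(rbind, centroids)
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3L || nrow(centroids) < 1L) {
    abort("`centroids` must be a k x 3 matrix with k >= 1.")
  }
  if (length(weights) != nrow(centroids)) {
    abort("`weights` length must match the number of centroids.")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be non-negative and sum to 1.")
  }
  dispersion_mm <- rep_len(dispersion_mm, nrow(centroids))
  if (any(dispersion_mm < 0)) abort("`dispersion_mm` must be >= 0.")
  if (!is.null(group_weights)) {
    if (any(group_weights < 0) || abs(sum(group_weights) - 1) > 1e-9) {
      abort("`group_weights` must be non-negative and sum to 1.")
    }
  }
  structure(
    list(centroids = unname(centroids), weights = as.numeric(weights),
         dispersion_mm = dispersion_mm,
         group_weights = group_weights),
    class = "mixture_spec"
  )
}

drug_groups <- c("cocaine", "alcohol", "nicotine")

#' Sample hotspot coordinates from a spatial mixture
#'
#' Draws `n` points component-first (categorical on the mixing weights),
#' then adds isotropic Gaussian scatter at the component's dispersion. Each
#' point keeps its true component label, so downstream clustering can be
#' scored against the generative truth, and carries a drug-group label drawn
#' from `spec$group_weights`.
#'
#' @param spec A [mixture_spec()].
#' @param n Number of points (>= 1).
#' @param seed Optional RNG seed.
#' @return A `hotspot_set` tibble with columns `subject_id`, `group`,
#'   `x_mm`, `y_mm`, `z_mm`, `peak_t`, `cluster_size`, `cluster_rank`,
#'   `component`.
#' @examples
#' pts <- sample_hotspots(mixture_spec(), n = 261, seed = 1)
#' table(pts$component) / nrow(pts)
#' @export
sample_hotspots <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (n < 1) abort("`n` must be >= 1.")
  gw <- spec$group_weights %||% rep(1 / 3, 3)
  with_seed_or_current(seed, {
    comp <- sample.int(length(spec$weights), n, replace = TRUE,
                       prob = spec$weights)
    xyz <- spec$centroids[comp, , drop = FALSE] +
      matrix(rnorm(3 * n), n, 3) * spec$dispersion_mm[comp]
    grp <- sample(drug_groups, n, replace = TRUE, prob = gw)
    pts <- tibble(
      subject_id = sprintf("point_%03d", seq_len(n)),
      group = grp,
      x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
      peak_t = NA_real_, cluster_size = NA_integer_,
      cluster_rank = 1L,
      component = comp
    )
    assemble_cohort(pts, mode = "full_complement")
  })
}

#' Build a synthetic subject cohort
#'
#' One record per subject across the three drug groups. A fraction
#' `responder_rate` of each group are responders: subjects whose cue
#' reactivity produces at least one corrected cluster. Responders get a true
#' activation locus drawn from the spatial mixture and a positive amplitude
#' (percent BOLD signal change); non-responders get amplitude 0 so the
#' responder bookkeeping is exercised end to end.
#'
#' @param n_per_group Counts for (cocaine, alcohol, nicotine); default the
#'   study-sized cohort `c(55, 53, 48)`.
#' @param responder_rate Proportion of responders in `[0, 1]`; default
#'   `103/156`.
#' @param spec A [mixture_spec()].
#' @param amplitude Percent signal change of responders (default 1).
#' @param bounds Optional spatial truncation: a list with `lower` and
#'   `upper` length-3 mm limits; responder loci are redrawn until inside
#'   (used in image-level mode so planted blobs stay on the simulated
#'   grid).
#' @param seed Optional RNG seed.
#' @return A `subject_truth` tibble: `subject_id`, `group`, `true_x_mm`,
#'   `true_y_mm`, `true_z_mm`, `amplitude`, `responder`, `component`.
#' @export
build_cohort <- function(n_per_group = c(cocaine = 55, alcohol = 53,
                                         nicotine = 48),
                         responder_rate = 103 / 156,
                         spec = mixture_spec(),
                         amplitude = 1,
                         bounds = NULL,
                         seed = NULL) {
  if (length(n_per_group) != 3L || any(n_per_group < 0)) {
    abort("`n_per_group` must be 3 non-negative counts.")
  }
  if (responder_rate < 0 || responder_rate > 1) {
    abort("`responder_rate` must be in [0, 1].")
  }
  if (is.null(names(n_per_group))) names(n_per_group) <- drug_groups
  with_seed_or_current(seed, {
    grp <- rep(names(n_per_group), times = n_per_group)
    n <- length(grp)
    if (n == 0) {
      return(tibble(
        subject_id = character(), group = character(),
        true_x_mm = numeric(), true_y_mm = numeric(),
        true_z_mm = numeric(), amplitude = numeric(),
        responder = logical(), component = integer()
      ))
    }
    responder <- runif(n) < responder_rate
    comp <- rep(NA_integer_, n)
    xyz <- matrix(NA_real_, n, 3)
    nr <- sum(responder)
    if (nr > 0) {
      comp[responder] <- sample.int(length(spec$weights), nr,
                                    replace = TRUE, prob = spec$weights)
      draw <- spec$centroids[comp[responder], , drop = FALSE] +
        matrix(rnorm(3 * nr), nr, 3) *
          spec$dispersion_mm[comp[responder]]
      if (!is.null(bounds)) {
        tries <- 0L
        repeat {
          bad <- which(
            draw[, 1] < bounds$lower[1] | draw[, 1] > bounds$upper[1] |
            draw[, 2] < bounds$lower[2] | draw[, 2] > bounds$upper[2] |
            draw[, 3] < bounds$lower[3] | draw[, 3] > bounds$upper[3]
          )
          if (!length(bad)) break
          tries <- tries + 1L
          if (tries > 100L) abort("could not draw loci inside `bounds`.")
          nb <- length(bad)
          draw[bad, ] <-
            spec$centroids[comp[responder][bad], , drop = FALSE] +
            matrix(rnorm(3 * nb), nb, 3) *
              spec$dispersion_mm[comp[responder][bad]]
        }
      }
      xyz[responder, ] <- draw
    }
    tibble(
      subject_id = sprintf("sub_%03d", seq_len(n)),
      group = grp,
      true_x_mm = xyz[, 1], true_y_mm = xyz[, 2], true_z_mm = xyz[, 3],
      amplitude = ifelse(responder, amplitude, 0),
      responder = responder,
      component = comp
    )
  })
}

#' Simulate a subject's 4D block-design time series
#'
#' Generates the image-level data the first-level GLM expects: a baseline of
#' 100 plus a Gaussian activation blob at the subject's true locus,
#' modulated by the HRF-convolved Drug regressor and scaled by the subject's
#' amplitude (percent signal change), in spatially smoothed Gaussian noise.
#' Defaults mirror a 3 mm isotropic acquisition at TR 2.2 s with 8 mm FWHM
#' spatial smoothing; the number of volumes is `floor(duration / TR)`.
#'
#' @param truth One row of a [build_cohort()] table (or a list with
#'   `true_x_mm`, `true_y_mm`, `true_z_mm`, `amplitude`).
#' @param paradigm A [build_paradigm()] result.
#' @param shape Grid dimensions (voxels).
#' @param affine 4x4 voxel-to-mm affine for the grid.
#' @param tr_s Repetition time (s), default 2.2.
#' @param noise_sd Temporal noise standard deviation in percent-signal
#'   units.
#' @param smoothness_fwhm_mm Spatial smoothness of the noise (mm FWHM).
#' @param blob_fwhm_mm FWHM of the planted activation blob (mm).
#' @param seed Optional RNG seed.
#' @return List with `data` (4D array), `mask` (a full-grid
#'   [mask_volume()]), `n_volumes`, `drug_locus_voxel` (0-based index of the
#'   blob centre, or NULL for non-responders).
#' @export
simulate_timeseries <- function(truth, paradigm, shape, affine,
                                tr_s = 2.2, noise_sd = 0.5,
                                smoothness_fwhm_mm = 8,
                                blob_fwhm_mm = 12, seed = NULL) {
  stopifnot(inherits(paradigm, "block_paradigm"))
  n_vol <- floor(attr(paradigm, "total_duration_s") / tr_s)
  grid <- volume_grid(array(0, shape), affine)
  vx <- voxel_sizes(grid)
  amp <- truth$amplitude
  responder <- is.finite(amp) && amp > 0
  locus_vox <- NULL
  signal <- NULL
  if (responder) {
    locus <- c(truth$true_x_mm, truth$true_y_mm, truth$true_z_mm)
    locus_vox <- mm_to_voxel(grid, locus)
    if (any(locus_vox < 0) || any(locus_vox >= shape)) {
      abort("blob centre outside the grid.")
    }
    sig_mm <- blob_fwhm_mm / (2 * sqrt(2 * log(2)))
    ax <- lapply(1:3, function(a) {
      mm <- ((seq_len(shape[a]) - 1)) # voxel indices, distance in vox units
      (mm - locus_vox[a]) * vx[a]
    })
    blob <- exp(-outer(
      outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"
    ) / (2 * sig_mm^2))
    design <- build_design(paradigm, tr_s, n_vol)
    reg <- design$X[, "Drug"]
    reg <- reg / max(reg)
    signal <- outer(as.numeric(blob) * amp, reg)
  }
  data4d <- with_seed_or_current(seed, {
    arr <- array(rnorm(prod(shape) * n_vol, sd = 1), c(shape, n_vol))
    if (noise_sd > 0 && smoothness_fwhm_mm > 0) {
      for (v in seq_len(n_vol)) {
        arr[, , , v] <- smooth_3d(arr[, , , v], smoothness_fwhm_mm, vx,
                                  periodic = TRUE, rescale = TRUE)
      }
    }
    arr <- arr * noise_sd
    arr
  })
  base <- array(100, c(shape, n_vol))
  data4d <- base + data4d
  if (responder) {
    data4d <- data4d + array(signal, c(shape, n_vol))
  }
  mask <- mask_volume(volume_grid(array(1, shape), affine))
  list(data = data4d, mask = mask, n_volumes = n_vol,
       drug_locus_voxel = locus_vox)
}
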