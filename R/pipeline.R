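default_config <- function() {
  list(
    mode = "coordinate",
    seed = 1L,
    points_mode = "full_complement",
    cohort = list(
      n_per_group = c(cocaine = 55, alcohol = 53, nicotine = 48),
      responder_rate = 103 / 156,
      clusters_per_responder_lambda = 1.53,
      amplitude = 1
    ),
    mixture = list(
      centroids = rbind(c(7, 50, 4), c(-40, 24, 25), c(30, 18, 41)),
      weights = c(0.40, 0.32, 0.28),
      dispersion_mm = 12
    ),
    paradigm = list(
      n_epochs = 6, block_s = 24, epoch_s = 120,
      epoch_fill = "repeat_rest", tr_s = 2.2
    ),
    image = list(
      shape = c(31, 26, 24),
      origin_mm = c(-45, 0, -15),
      voxel_mm = 3,
      noise_sd = 0.5,
      smoothness_fwhm_mm = 8,
      blob_fwhm_mm = 12
    ),
    glm = list(contrast = c(Drug = 1, Neutral = -1)),
    threshold = list(
      voxel_p = 0.005, cluster_alpha = 0.05,
      n_iterations = 1000, connectivity = 6
    ),
    kmeans = list(k_range = 2:10, n_restarts = 1000),
    coverage = list(radii = c(20, 30, 40, 50), electrodes = "builtin"),
    out_dir = NULL
  )
}

#' Parse coverage radii
#'
#' Accepts radii either as numeric millimetres or as a string with an
#' explicit unit, e.g. `"2,3,4,5 cm"`, normalized to mm.
#'
#' @param radii Numeric vector (mm) or a single string like `"2,3,4,5 cm"`.
#' @return Numeric radii in mm, sorted.
#' @export
parse_radii <- function(radii) {
  if (is.character(radii)) {
    stopifnot(length(radii) == 1L)
    s <- trimws(radii)
    unit <- if (grepl("cm\\s*$", s)) "cm" else "mm"
    nums <- as.numeric(strsplit(gsub("(cm|mm)\\s*$", "", s),
                                "[,;\\s]+")[[1]])
    nums <- nums[!is.na(nums)]
    if (!length(nums)) abort("no radii found in string.")
    if (unit == "cm") nums <- nums * 10
    radii <- nums
  }
  radii <- sort(as.numeric(radii))
  if (any(radii <= 0)) abort("radii must be positive.")
  radii
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a nested list or a YAML/JSON file, fills in defaults, checks
#' constraints (positive counts, non-empty k range, radii units converted
#' to mm) and returns a normalized `pipeline_config`. With `strict = TRUE`
#' unknown top-level keys and a missing seed are errors.
#'
#' @param raw Named list, or path to a YAML/JSON config document; `NULL`
#'   means all defaults.
#' @param strict Reject unknown keys and require an explicit seed.
#' @return A `pipeline_config` list.
#' @examples
#' cfg <- validate_config(list(coverage = list(radii = "2,3,4,5 cm")))
#' cfg$coverage$radii
#' @export
validate_config <- function(raw = NULL, strict = FALSE) {
  if (is.character(raw)) {
    ext <- tolower(tools::file_ext(raw))
    raw <- switch(ext,
      yaml = , yml = yaml::read_yaml(raw),
      json = jsonlite::fromJSON(raw, simplifyVector = TRUE),
      abort("config file must be .yaml/.yml or .json")
    )
  }
  raw <- raw %||% list()
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    msg <- paste0("unknown config keys: ", paste(unknown, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  cfg <- modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  if (!cfg$mode %in% c("coordinate", "image")) {
    abort("`mode` must be 'coordinate' or 'image'.")
  }
  if (!cfg$points_mode %in% c("full_complement", "one_per_individual")) {
    abort("`points_mode` must be 'full_complement' or 'one_per_individual'.")
  }
  if (strict && is.null(cfg$seed)) abort("`seed` is required (strict mode).")
  if (sum(cfg$cohort$n_per_group) < 1) {
    abort("config has zero subjects.")
  }
  if (cfg$cohort$responder_rate < 0 || cfg$cohort$responder_rate > 1) {
    abort("`responder_rate` must be in [0, 1].")
  }
  kr <- cfg$kmeans$k_range
  if (length(kr) == 2L && kr[1] > kr[2]) {
    abort("empty k range.")
  }
  cfg$kmeans$k_range <- if (length(kr) == 2L) kr[1]:kr[2] else
    sort(unique(as.integer(kr)))
  if (!length(cfg$kmeans$k_range)) abort("empty k range.")
  cfg$coverage$radii <- parse_radii(cfg$coverage$radii)
  cfg$mixture <- do.call(
    mixture_spec,
    cfg$mixture[intersect(names(cfg$mixture),
                          names(formals(mixture_spec)))]
  )
  structure(cfg, class = "pipeline_config")
}

derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}

#' Run the full topography-and-coverage pipeline
#'
#' Orchestrates all stages on a synthetic cohort, in one of two entry
#' modes. Coordinate-level mode (fast path) generates hotspot coordinates
#' directly from the spatial mixture and exercises topography + coverage.
#' Image-level mode simulates each subject's 4D time series, fits the
#' first-level GLM, applies Monte-Carlo cluster-extent correction, extracts
#' hotspots, then runs the same downstream stages. All randomness derives
#' from `config$seed`; rerunning the same config reproduces the report
#' exactly.
#'
#' @param config A `pipeline_config` from [validate_config()] (or a raw
#'   list/path, validated on the fly).
#' @param verbose Log stage-level counts (default TRUE).
#' @return A `run_report`: list with cohort bookkeeping (responder counts
#'   and fraction), the hotspot sets, k-selection diagnostics, the selected
#'   clustering with centroids and cluster shares, group contingency
#'   results, coverage report, and (image mode) per-subject recovery
#'   distances; plus a `provenance` entry (config, seeds, package
#'   version).
#' @export
run_pipeline <- function(config = NULL, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_config(config)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  if (config$mode == "coordinate") {
    sets <- simulate_coordinate_cohort(config, say)
  } else {
    sets <- run_image_cohort(config, say)
  }
  full <- sets$full
  restricted <- sets$restricted
  set <- if (config$points_mode == "full_complement") full else restricted
  say("points clustered: %d (%s)", nrow(set), config$points_mode)

  report <- list(
    mode = config$mode,
    points_mode = config$points_mode,
    n_subjects = attr(full, "n_subjects"),
    n_responders = attr(full, "n_responders"),
    responder_fraction = attr(full, "responder_fraction"),
    n_points_full = nrow(full),
    n_points_restricted = nrow(restricted)
  )
  if (!is.null(sets$recovery)) report$recovery <- sets$recovery

  n_distinct <- nrow(unique(hotspot_coords(set)))
  kr <- config$kmeans$k_range[config$kmeans$k_range <= n_distinct]
  if (nrow(set) >= 4 && length(kr) >= 1) {
    sel <- select_k(set, kr, n_restarts = config$kmeans$n_restarts,
                    seed = derive_seed(config$seed, 11))
    say("selected k = %d (mean silhouette %.3f)",
        sel$best$k, sel$best$mean_silhouette)
    report$k_diagnostics <- sel$diagnostics
    report$selected_k <- sel$best$k
    report$weak_structure <- sel$weak_structure
    report$centroids <- sel$best$centroids
    report$cluster_shares <- as.numeric(sel$best$sizes) / nrow(set)
    report$mean_silhouette <- sel$best$mean_silhouette
    if (length(unique(set$group)) >= 2 && sel$best$k >= 2) {
      ct <- suppressWarnings(cross_tab(set, sel$best, "group"))
      report$group_contingency <- list(
        chi2 = ct$chi2, df = ct$df, p = ct$p,
        low_expected = ct$low_expected
      )
    }
    report$solution <- sel$best
  } else {
    say("too few points for clustering (%d); topography skipped", nrow(set))
  }

  electrodes <- load_electrodes(config$coverage$electrodes)
  if (nrow(set) > 0) {
    cov <- subgroup_coverage(set, electrodes, config$coverage$radii)
    report$coverage <- cov
  }
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("cuetopo")),
    seed = config$seed,
    electrode_provenance = attr(electrodes, "provenance"),
    config = config_fingerprint(config)
  )
  report <- structure(report, class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, set, config$out_dir)
  report
}

config_fingerprint <- function(config) {
  flat <- unclass(config)
  flat$mixture <- list(
    centroids = unclass(flat$mixture$centroids),
    weights = flat$mixture$weights,
    dispersion_mm = flat$mixture$dispersion_mm
  )
  flat$out_dir <- NULL
  flat
}

simulate_coordinate_cohort <- function(config, say) {
  cohort <- build_cohort(
    n_per_group = unlist(config$cohort$n_per_group),
    responder_rate = config$cohort$responder_rate,
    spec = config$mixture,
    amplitude = config$cohort$amplitude,
    seed = derive_seed(config$seed, 1)
  )
  say("subjects in: %d, responders: %d", nrow(cohort),
      sum(cohort$responder))
  resp <- cohort[cohort$responder, ]
  lam <- config$cohort$clusters_per_responder_lambda
  pts <- with_seed_or_current(derive_seed(config$seed, 2), {
    n_extra <- stats::rpois(nrow(resp), lam)
    rows <- lapply(seq_len(nrow(resp)), function(i) {
      m <- 1L + n_extra[i]
      comp <- c(resp$component[i],
                if (m > 1) sample.int(length(config$mixture$weights),
                                      m - 1L, replace = TRUE,
                                      prob = config$mixture$weights))
      xyz <- config$mixture$centroids[comp, , drop = FALSE] +
        matrix(rnorm(3 * m), m, 3) *
          config$mixture$dispersion_mm[comp]
      xyz[1, ] <- c(resp$true_x_mm[i], resp$true_y_mm[i],
                    resp$true_z_mm[i])
      pt <- sort(3 + abs(rnorm(m, sd = 2)), decreasing = TRUE)
      tibble(
        subject_id = resp$subject_id[i], group = resp$group[i],
        x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
        peak_t = pt, cluster_size = NA_integer_,
        cluster_rank = seq_len(m), component = comp
      )
    })
    dplyr::bind_rows(rows)
  })
  n_subj <- nrow(cohort)
  list(
    full = assemble_cohort(pts, "full_complement", n_subjects = n_subj),
    restricted = assemble_cohort(pts, "one_per_individual",
                                 n_subjects = n_subj),
    recovery = NULL
  )
}

run_image_cohort <- function(config, say) {
  img0 <- config$image
  aff0 <- mni_affine(rep(img0$voxel_mm, 3), img0$origin_mm)
  margin <- 6
  lower <- img0$origin_mm + margin
  upper <- img0$origin_mm + (img0$shape - 1) * img0$voxel_mm - margin
  cohort <- build_cohort(
    n_per_group = unlist(config$cohort$n_per_group),
    responder_rate = config$cohort$responder_rate,
    spec = config$mixture,
    amplitude = config$cohort$amplitude,
    bounds = list(lower = lower, upper = upper),
    seed = derive_seed(config$seed, 1)
  )
  say("subjects in: %d (%d planted responders)", nrow(cohort),
      sum(cohort$responder))
  img <- config$image
  affine <- mni_affine(rep(img$voxel_mm, 3), img$origin_mm)
  shape <- img$shape
  mask <- mask_volume(volume_grid(array(1, shape), affine))
  paradigm <- do.call(build_paradigm,
                      config$paradigm[setdiff(names(config$paradigm),
                                              "tr_s")])
  thr <- monte_carlo_extent_threshold(
    mask, img$smoothness_fwhm_mm,
    config$threshold$voxel_p, config$threshold$cluster_alpha,
    config$threshold$n_iterations, config$threshold$connectivity,
    seed = derive_seed(config$seed, 3)
  )
  say("extent threshold: >= %d voxels", thr$min_cluster_size_voxels)
  n_vol <- floor(attr(paradigm, "total_duration_s") / config$paradigm$tr_s)
  design <- build_design(paradigm, config$paradigm$tr_s, n_vol)
  per_subject <- vector("list", nrow(cohort))
  recovery <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sim <- simulate_timeseries(
      cohort[i, ], paradigm, shape, affine,
      tr_s = config$paradigm$tr_s, noise_sd = img$noise_sd,
      smoothness_fwhm_mm = img$smoothness_fwhm_mm,
      blob_fwhm_mm = img$blob_fwhm_mm,
      seed = derive_seed(config$seed, 100 + i)
    )
    fit <- fit_first_level(sim$data, design, config$glm$contrast, mask)
    clus <- label_clusters(fit$t, config$threshold$voxel_p, mask,
                           config$threshold$connectivity)
    kept <- rank_clusters(apply_extent_threshold(clus, thr))
    hs <- extract_hotspots(fit$t, kept, mask,
                           subject_id = cohort$subject_id[i],
                           group = cohort$group[i])
    per_subject[[i]] <- hs
    if (cohort$responder[i] && nrow(hs)) {
      truth <- c(cohort$true_x_mm[i], cohort$true_y_mm[i],
                 cohort$true_z_mm[i])
      found <- c(hs$x_mm[1], hs$y_mm[1], hs$z_mm[1])
      recovery[[i]] <- tibble(
        subject_id = cohort$subject_id[i],
        planted = TRUE, detected = TRUE,
        dist_mm = sqrt(sum((found - truth)^2))
      )
    } else {
      recovery[[i]] <- tibble(
        subject_id = cohort$subject_id[i],
        planted = cohort$responder[i],
        detected = nrow(hs) > 0,
        dist_mm = NA_real_
      )
    }
  }
  n_subj <- nrow(cohort)
  say("responders detected: %d / %d planted",
      sum(vapply(recovery, function(r) r$planted & r$detected,
                 logical(1))),
      sum(cohort$responder))
  list(
    full = assemble_cohort(dplyr::bind_rows(per_subject),
                           "full_complement", n_subjects = n_subj),
    restricted = assemble_cohort(dplyr::bind_rows(per_subject),
                                 "one_per_individual",
                                 n_subjects = n_subj),
    recovery = dplyr::bind_rows(recovery)
  )
}

write_report <- function(report, set, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_file(as_tibble(set),
                   file.path(out_dir, "hotspots.tsv"))
  if (!is.null(report$k_diagnostics)) {
    write_table_file(report$k_diagnostics,
                     file.path(out_dir, "k_diagnostics.tsv"))
  }
  if (!is.null(report$coverage)) {
    write_table_file(report$coverage$summary,
                     file.path(out_dir, "coverage_summary.tsv"))
    write_table_file(as_tibble(report$coverage$all),
                     file.path(out_dir, "coverage_all.tsv"))
  }
  jsonlite::write_json(
    report_to_json(report),
    file.path(out_dir, "report.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}

report_to_json <- function(report) {
  out <- report[setdiff(names(report), c("solution", "coverage"))]
  if (!is.null(report$coverage)) {
    out$coverage_summary <- report$coverage$summary
  }
  if (!is.null(report$centroids)) {
    out$centroids <- unclass(report$centroids)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> %s mode: %d subjects, %d responders (%.0f%%), %d/%d points\n",
    x$mode, x$n_subjects, x$n_responders, 100 * x$responder_fraction,
    x$n_points_full, x$n_points_restricted
  ))
  if (!is.null(x$selected_k)) {
    cat(sprintf("  selected k = %d, cluster shares: %s\n", x$selected_k,
                paste(sprintf("%.0f%%", 100 * x$cluster_shares),
                      collapse = " / ")))
  }
  if (!is.null(x$coverage)) print(x$coverage)
  invisible(x)
}
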