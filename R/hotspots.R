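#' Rank corrected clusters by significance
#'
#' Orders clusters by ascending cluster-level p (equivalently descending
#' extent under an extent-based correction), breaking ties by descending
#' peak t and then by lexicographic peak voxel index. Rank 1 is the most
#' significant cluster; by convention its local maximum is the subject's
#' primary hotspot.
#'
#' @param clusters A `cluster_table`, typically the output of
#'   [apply_extent_threshold()] (a `cluster_p` column is used when present).
#' @param by `"cluster_p"` (default, extent-based significance) or
#'   `"peak_t"`.
#' @return The same table ordered by rank, with a `cluster_rank` column.
#' @export
rank_clusters <- function(clusters, by = c("cluster_p", "peak_t")) {
  by <- match.arg(by)
  if (nrow(clusters) == 0) {
    clusters$cluster_rank <- integer(0)
    return(clusters)
  }
  pk <- do.call(rbind, clusters$peak_voxel)
  o <- if (by == "cluster_p" && !is.null(clusters[["cluster_p"]])) {
    order(clusters$cluster_p, -clusters$size_voxels, -clusters$peak_t,
          pk[, 1], pk[, 2], pk[, 3])
  } else if (by == "peak_t") {
    order(-clusters$peak_t, -clusters$size_voxels,
          pk[, 1], pk[, 2], pk[, 3])
  } else {
    order(-clusters$size_voxels, -clusters$peak_t,
          pk[, 1], pk[, 2], pk[, 3])
  }
  out <- clusters[o, ]
  out$cluster_rank <- seq_len(nrow(out))
  out
}

#' Extract per-subject hotspots from corrected clusters
#'
#' Reduces a subject's corrected map to hotspot coordinates: for each
#' retained cluster, the member voxel with maximal t (the local maximum),
#' converted to MNI mm. A subject with no surviving clusters contributes an
#' empty table and counts as a non-responder downstream.
#'
#' @param map The subject's [stat_map()].
#' @param clusters Ranked, corrected `cluster_table` (see
#'   [rank_clusters()]).
#' @param mask The analysis [mask_volume()].
#' @param subject_id,group Identifiers carried into the output.
#' @param max_per_subject Cap on clusters per subject (default unlimited).
#' @return A tibble with columns `subject_id`, `group`, `x_mm`, `y_mm`,
#'   `z_mm`, `peak_t`, `cluster_size`, `cluster_rank`.
#' @export
extract_hotspots <- function(map, clusters, mask, subject_id = NA_character_,
                             group = NA_character_,
                             max_per_subject = Inf) {
  stopifnot(inherits(map, "stat_map"), inherits(mask, "mask_volume"))
  n_keep <- min(nrow(clusters), max_per_subject)
  rows <- lapply(seq_len(n_keep), function(i) {
    members <- clusters$members[[i]]
    inmask <- members[mask$grid$data[members] > 0]
    if (!length(inmask)) abort("cluster has no in-mask member voxel.")
    tv <- map$grid$data[inmask]
    best <- inmask[order(-tv, inmask)][1]
    pk <- arrayInd(best, dim(map$grid$data))[1, ] - 1L
    mm <- voxel_to_mm(map$grid, pk)
    tibble(
      subject_id = subject_id, group = group,
      x_mm = mm[["x"]], y_mm = mm[["y"]], z_mm = mm[["z"]],
      peak_t = max(tv),
      cluster_size = clusters$size_voxels[i],
      cluster_rank = if (!is.null(clusters$cluster_rank)) {
        clusters$cluster_rank[i]
      } else {
        i
      }
    )
  })
  dplyr::bind_rows(rows)
}

#' Assemble a cohort-level hotspot set
#'
#' Combines per-subject hotspot tables into the point set used by the
#' topography and coverage analyses, in one of two modes: the full
#' complement keeps every corrected cluster's hotspot; one-per-individual
#' keeps only each responder's rank-1 (most significant) hotspot. Responder
#' bookkeeping -- how many of `n_subjects` contributed at least one point --
#' is stored in attributes.
#'
#' @param per_subject A list of per-subject hotspot tibbles (as produced by
#'   [extract_hotspots()]), or one combined tibble.
#' @param mode `"full_complement"` or `"one_per_individual"`.
#' @param n_subjects Total cohort size including non-responders (defaults
#'   to the number of distinct subject ids seen, i.e. responders only).
#' @return A `hotspot_set` tibble; attributes `mode`, `n_subjects`,
#'   `n_responders`, `responder_fraction`.
#' @export
assemble_cohort <- function(per_subject,
                            mode = c("full_complement",
                                     "one_per_individual"),
                            n_subjects = NULL) {
  mode <- match.arg(mode)
  pts <- if (is.data.frame(per_subject)) {
    as_tibble(per_subject)
  } else {
    dplyr::bind_rows(per_subject)
  }
  if (nrow(pts) > 0 &&
      anyDuplicated(pts[, c("subject_id", "cluster_rank")])) {
    abort("duplicate (subject_id, cluster_rank) pairs.")
  }
  responders <- unique(pts$subject_id)
  if (mode == "one_per_individual" && nrow(pts) > 0) {
    pts <- pts[pts$cluster_rank == 1, ]
  }
  n_resp <- length(responders)
  n_subjects <- n_subjects %||% n_resp
  structure(
    pts,
    mode = mode,
    n_subjects = n_subjects,
    n_responders = n_resp,
    responder_fraction = if (n_subjects > 0) n_resp / n_subjects else 0,
    class = c("hotspot_set", class(pts))
  )
}

hotspot_coords <- function(set) {
  as.matrix(set[, c("x_mm", "y_mm", "z_mm")])
}
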