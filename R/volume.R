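#' Spatial volume containers
#'
#' A `volume_grid` is a 3D scalar lattice together with a 4x4 affine mapping
#' 0-based voxel indices to MNI millimetre (RAS) coordinates. A `stat_map`
#' wraps a `volume_grid` of t-values with its degrees of freedom, and a
#' `mask_volume` wraps a binary `volume_grid`. These are the containers that
#' all image-level stages (GLM fitting, cluster labelling, hotspot
#' extraction) operate on.
#'
#' @param data Numeric 3D array.
#' @param affine Numeric 4x4 matrix, voxel-index (0-based) to mm transform.
#'   Must be invertible with strictly positive voxel sizes (column norms of
#'   its upper-left 3x3 block).
#' @return `volume_grid()` returns an object of class `"volume_grid"` with
#'   fields `data`, `affine` and `shape`.
#' @examples
#' g <- volume_grid(array(0, c(4, 4, 4)), mni_affine(c(4, 4, 4)))
#' voxel_sizes(g)
#' @export
volume_grid <- function(data, affine) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) {
    abort("`affine` must be a 4x4 matrix.")
  }
  if (abs(det(affine)) < .Machine$double.eps * 100) {
    abort("`affine` must be invertible.")
  }
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) {
    abort("voxel sizes derived from `affine` must be strictly positive.")
  }
  structure(
    list(data = data, affine = affine, shape = dim(data)),
    class = "volume_grid"
  )
}

#' @rdname volume_grid
#' @param grid A `volume_grid`.
#' @param df Positive integer degrees of freedom of the t-statistics.
#' @export
stat_map <- function(grid, df) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.numeric(df) || length(df) != 1L || df < 1) {
    abort("`df` must be a single value >= 1.")
  }
  if (!all(is.finite(grid$data))) {
    abort("t-values must be finite.")
  }
  structure(list(grid = grid, df = df), class = "stat_map")
}

#' @rdname volume_grid
#' @export
mask_volume <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  v <- grid$data
  if (!all(v %in% c(0, 1))) {
    abort("mask values must all be 0 or 1.")
  }
  grid$data <- array(as.numeric(v), dim(v))
  structure(list(grid = grid), class = "mask_volume")
}

#' @rdname volume_grid
#' @export
voxel_sizes <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' A standard MNI-style affine
#'
#' Convenience constructor for a diagonal RAS affine with the given voxel
#' sizes and translation, in the spirit of a resampled MNI template grid.
#'
#' @param voxel_mm Length-3 voxel sizes in mm.
#' @param origin_mm Length-3 mm coordinate of voxel (0, 0, 0).
#' @return A 4x4 affine matrix.
#' @export
mni_affine <- function(voxel_mm = c(3, 3, 3), origin_mm = c(-90, -126, -72)) {
  a <- diag(c(voxel_mm, 1))
  a[1:3, 4] <- origin_mm
  a
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) abort(paste0(what, " must share shape and affine."))
  invisible(TRUE)
}

#' Convert between voxel indices and MNI millimetres
#'
#' `voxel_to_mm()` applies the grid affine to 0-based voxel indices;
#' `mm_to_voxel()` applies its inverse and rounds to the nearest lattice
#' point, so the two are exact inverses on voxel centres.
#'
#' @param grid A `volume_grid`.
#' @param index Integer vector of length 3 (or an n x 3 matrix), 0-based.
#' @param mm Numeric vector of length 3 (or an n x 3 matrix) of MNI mm.
#' @return A length-3 vector, or an n x 3 matrix when given a matrix.
#' @examples
#' g <- volume_grid(array(0, c(5, 5, 5)), mni_affine())
#' voxel_to_mm(g, c(0, 0, 0))
#' mm_to_voxel(g, voxel_to_mm(g, c(2, 3, 4)))
#' @export
voxel_to_mm <- function(grid, index) {
  idx <- rbind(index)
  if (ncol(idx) != 3L) abort("`index` must have 3 columns.")
  if (any(idx < 0) || any(t(idx) >= grid$shape)) {
    abort("voxel index out of bounds.")
  }
  out <- idx %*% t(grid$affine[1:3, 1:3])
  out <- sweep(out, 2, grid$affine[1:3, 4], "+")
  colnames(out) <- c("x", "y", "z")
  if (is.vector(index)) out[1, ] else out
}

#' @rdname voxel_to_mm
#' @export
mm_to_voxel <- function(grid, mm) {
  pts <- rbind(mm)
  if (ncol(pts) != 3L) abort("`mm` must have 3 columns.")
  inv <- solve(grid$affine)
  idx <- pts %*% t(inv[1:3, 1:3])
  idx <- sweep(idx, 2, inv[1:3, 4], "+")
  idx <- round(idx)
  storage.mode(idx) <- "integer"
  colnames(idx) <- NULL
  if (is.vector(mm)) idx[1, ] else idx
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over \pkg{RNifti} that move between files on disk and
#' `volume_grid` objects, preserving the voxel-to-mm affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `read_volume()` returns a `volume_grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    abort(sprintf("expected 3D image, got %dD.", length(d)))
  }
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  volume_grid(array(as.numeric(img), d), aff)
}

#' @rdname read_volume
#' @param grid A `volume_grid` to serialize.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- voxel_sizes(grid)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param data4d A 4D array (x, y, z, time).
#' @param affine 4x4 voxel-to-mm affine for the spatial axes.
#' @export
write_volume_4d <- function(data4d, affine, path) {
  stopifnot(length(dim(data4d)) == 4L)
  img <- RNifti::asNifti(data4d)
  RNifti::pixdim(img) <- c(sqrt(colSums(affine[1:3, 1:3]^2)), 1)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %s voxels, voxel size %s mm\n",
    paste(x$shape, collapse = " x "),
    paste(signif(voxel_sizes(x), 3), collapse = " x ")
  ))
  invisible(x)
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "<stat_map> %s voxels, df = %d, t range [%.2f, %.2f]\n",
    paste(x$grid$shape, collapse = " x "), x$df,
    min(x$grid$data), max(x$grid$data)
  ))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf(
    "<mask_volume> %s voxels, %d in mask\n",
    paste(x$grid$shape, collapse = " x "), sum(x$grid$data)
  ))
  invisible(x)
}
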