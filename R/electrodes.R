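#' Load an EEG scalp electrode coordinate table
#'
#' Reads electrode positions (label plus MNI mm) from a CSV with columns
#' `label,x,y,z`, or loads the built-in default: the standard 10-05
#' electrode positions (Oostenveld's extension of the 10-10 system)
#' digitized on the colin27 scalp in MNI millimetres, shipped with the
#' package. The extended 10-5 midpoint labels (e.g. AF5) are included so
#' that all labels commonly reported in targeting studies resolve.
#'
#' @param source `"builtin"` (default) or a CSV path.
#' @param strict Require the core frontal labels
#'   (FPz, FP1, FP2, AF3, AF7, F5) to be present (default TRUE for the
#'   builtin table).
#' @return An `electrode_set` tibble with columns `label`, `x`, `y`, `z`
#'   and a `provenance` attribute. Label matching elsewhere in the package
#'   is case-insensitive (FPz and Fpz are the same electrode).
#' @examples
#' el <- load_electrodes()
#' electrode_position(el, "FPz")
#' @export
load_electrodes <- function(source = "builtin", strict = NULL) {
  if (identical(source, "builtin")) {
    path <- system.file("extdata", "electrodes_1005_colin27.csv",
                        package = "cuetopo")
    provenance <- "standard_1005 (Oostenveld 10-05 positions, colin27 scalp, MNI mm)"
    strict <- strict %||% TRUE
  } else {
    path <- source
    provenance <- source
    strict <- strict %||% FALSE
  }
  if (!file.exists(path)) abort(paste0("electrode table not found: ", path))
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  req <- c("label", "x", "y", "z")
  if (!all(req %in% names(tab))) {
    abort("electrode CSV must have columns label,x,y,z.")
  }
  tab <- tab[, req]
  if (anyDuplicated(tolower(tab$label))) {
    abort("duplicate electrode labels.")
  }
  if (!all(is.finite(as.matrix(tab[, c("x", "y", "z")])))) {
    abort("electrode positions must be finite.")
  }
  if (strict) {
    core <- c("fpz", "fp1", "fp2", "af3", "af7", "f5")
    missing <- setdiff(core, tolower(tab$label))
    if (length(missing)) {
      abort(paste0("electrode table is missing required labels: ",
                   paste(missing, collapse = ", ")))
    }
  }
  structure(
    as_tibble(tab),
    provenance = provenance,
    class = c("electrode_set", class(as_tibble(tab)))
  )
}

#' @rdname load_electrodes
#' @param electrodes An `electrode_set`.
#' @param label Electrode label (case-insensitive).
#' @export
electrode_position <- function(electrodes, label) {
  i <- match(tolower(label), tolower(electrodes$label))
  if (is.na(i)) abort(paste0("electrode not found: ", label))
  unlist(electrodes[i, c("x", "y", "z")])
}

#' @rdname load_electrodes
#' @param path Output CSV path.
#' @export
write_electrodes <- function(electrodes, path) {
  readr::write_csv(electrodes[, c("label", "x", "y", "z")], path)
  invisible(path)
}
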