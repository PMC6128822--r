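#' Read and write tabular artifacts
#'
#' All tabular outputs of the pipeline (hotspot tables, per-k diagnostics,
#' coverage reports) pass through these helpers. TSV and CSV go through
#' \pkg{readr}, which serializes doubles with round-trip precision; JSON goes
#' through \pkg{jsonlite} with `digits = NA` for the same reason, so
#' `read_table_file(write_table_file(x))` reproduces `x` exactly.
#'
#' @param rows A data frame of homogeneous records.
#' @param path Output file path.
#' @param dialect One of `"tsv"`, `"csv"`, `"json"`. Defaults to the file
#'   extension.
#' @return `write_table_file()` returns `path` invisibly;
#'   `read_table_file()` returns a tibble.
#' @export
write_table_file <- function(rows, path, dialect = NULL) {
  rows <- as_tibble(rows)
  dialect <- tolower(dialect %||% tools::file_ext(path))
  switch(dialect,
    tsv = readr::write_tsv(rows, path),
    csv = readr::write_csv(rows, path),
    json = jsonlite::write_json(rows, path, dataframe = "rows",
                                digits = NA, auto_unbox = FALSE),
    abort(paste0("unknown table dialect: ", dialect))
  )
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  dialect <- tolower(dialect %||% tools::file_ext(path))
  out <- switch(dialect,
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    json = as_tibble(jsonlite::fromJSON(path)),
    abort(paste0("unknown table dialect: ", dialect))
  )
  as_tibble(out)
}
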