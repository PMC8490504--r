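#' Read a long reporter-area table
#'
#' Reads a tab-separated `areas.tsv` with columns `analyte`, `plex_id`,
#' `channel`, `area` (plus optional `role`, `subject_id`, `qc_flag`). A
#' Skyline-style small-molecule export can be mapped by renaming its columns
#' via `col_map`.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping file column names
#'   to the canonical names, e.g. `c("Molecule Name" = "analyte")`.
#' @return A validated area tibble.
#' @export
read_reporter_areas <- function(path, col_map = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(x))
    names(x)[idx[!is.na(idx)]] <- unname(col_map[!is.na(idx)])
  }
  as_area_table(x)
}

#' Read a subject metadata table
#' @param path Tab-separated file with at least `subject_id`, `pair_id`,
#'   `class`, `excluded_flag`.
#' @return Tibble.
#' @export
read_subjects <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a simulated study to disk
#'
#' Writes `areas.tsv`, `subjects.tsv`, `layout.tsv` and the hidden ground
#' truth `truth.json` (corrupted reference cells) into a directory.
#'
#' @param study A `kp_study` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "kp_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(study$areas, file.path(dir, "areas.tsv"))
  readr::write_tsv(study$subjects, file.path(dir, "subjects.tsv"))
  readr::write_tsv(study$layout, file.path(dir, "layout.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
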