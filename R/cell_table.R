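#' Per-nucleus cell table I/O
#'
#' The cell table is the pipeline's central record: one row per detected
#' nucleus with position, core radius, per-channel raw / background-
#' subtracted / normalized intensities, AP coordinate, region, clone
#' label, QC flags, depth band, and sample id. It serializes to a plain
#' UTF-8 comma-separated CSV ('.' decimal) with a fixed column order, and
#' round-trips through [read_cell_table()] to within float printing
#' precision.
#'
#' @name cell_table_io
NULL

#' Write a cell table to CSV
#' @param table cell table data.frame (must contain `cell_id`; unique per
#'   `sample_id`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cell_table <- function(table, path) {
  check_cell_ids(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#' @param path CSV path written by [write_cell_table()]
#' @return data.frame
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cell_ids(tab)
  tab
}

check_cell_ids <- function(tab) {
  if (!"cell_id" %in% names(tab)) stopf("cell table needs a cell_id column")
  key <- if ("sample_id" %in% names(tab))
    paste(tab$sample_id, tab$cell_id) else tab$cell_id
  if (anyDuplicated(key))
    stopf("duplicate cell_id within a sample: table integrity violated")
  invisible(tab)
}
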