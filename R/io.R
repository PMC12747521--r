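# CSV/JSON round trips for the tabular artefacts. All tables are plain
# data frames, so these are thin wrappers that fix the column conventions.

#' Write/read a trace table as CSV
#'
#' Columns: `cell_id`, `parent_id`, `frame`, `time_h`, `x_um`, `y_um`,
#' `cdk46_raw`, `cdk2`, `degron`, plus any others present (e.g.
#' `cdk46_corrected`, `class`).
#'
#' @param traces trace table data frame.
#' @param path CSV file path.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns
#'   the data frame.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  utils::read.csv(path)
}

#' Write simulation ground truth as CSV + JSON sidecar
#'
#' Writes `<stem>_cells.csv` (per-cell lineage, boundaries, durations),
#' `<stem>_frames.csv` (per-frame true positions and activities) and
#' `<stem>_config.json`.
#'
#' @param truth `sim_truth` from [simulate_traces()].
#' @param stem path stem (no extension).
#' @return the three paths, invisibly.
#' @export
write_sim_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "sim_truth"))
  p1 <- paste0(stem, "_cells.csv")
  p2 <- paste0(stem, "_frames.csv")
  p3 <- paste0(stem, "_config.json")
  utils::write.csv(truth$cells, p1, row.names = FALSE)
  utils::write.csv(truth$frames, p2, row.names = FALSE)
  jsonlite::write_json(unclass(truth$config), p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' Write a label map as 16-bit TIFF
#'
#' @param labels integer label matrix (values must fit in 16 bits).
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  tiff::writeTIFF(t(unclass(labels) / 65535), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  out <- t(round(m * 65535))
  storage.mode(out) <- "integer"
  out
}
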