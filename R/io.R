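#' Write a count matrix as MatrixMarket plus gene/barcode TSVs
#'
#' Standard sparse exchange layout: `matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv` in `dir`.
#'
#' @param counts genes x cells count matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return dense integer matrix with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Write / read per-cell metadata as TSV
#'
#' Columns: `cell_id`, `stage`, `read_pairs`, `frac_mapped`,
#' `frac_mito`, `egfp_reads`, `mapped_reads`.
#'
#' @param cells metadata data.frame.
#' @param path TSV path.
#' @return `path` (write) / the data.frame (read).
#' @export
write_cell_metadata <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_metadata
#' @export
read_cell_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read migration tracks as TSV
#'
#' Long format: `track_id`, `t_min`, `x_um`, `y_um` and optionally
#' `group`.
#'
#' @param tracks track data.frame.
#' @param path TSV path.
#' @return `path` (write) / the data.frame (read).
#' @export
write_tracks <- function(tracks, path) {
  utils::write.table(tracks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
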