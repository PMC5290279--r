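#' Reads-per-million (RPM) normalization
#'
#' Divides each cell's counts by its number of mapped reads and
#' multiplies by one million: `rpm(g, i) = count(g, i) * 1e6 /
#' mapped_reads(i)`. With `mapped_reads` defined as the reads aligned to
#' expressed genes (the column sums, the default), every cell's RPM
#' values sum to exactly one million.
#'
#' @param counts genes x cells count matrix.
#' @param mapped_reads per-cell mapped-read totals (named or in column
#'   order); defaults to the column sums of `counts`.
#' @return numeric matrix of RPM values, same dimensions and dimnames.
#' @export
to_rpm <- function(counts, mapped_reads = NULL) {
  if (is.null(mapped_reads)) {
    mapped_reads <- colSums(counts)
  }
  if (length(mapped_reads) != ncol(counts)) {
    stop("mapped_reads must have one entry per cell", call. = FALSE)
  }
  if (!is.null(names(mapped_reads)) && !is.null(colnames(counts))) {
    mapped_reads <- mapped_reads[colnames(counts)]
  }
  bad <- which(!is.finite(mapped_reads) | mapped_reads <= 0)
  if (length(bad) > 0) {
    nm <- if (!is.null(colnames(counts))) colnames(counts)[bad] else bad
    stop("degenerate cell(s) with zero mapped reads: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, 1e6 / mapped_reads, "*")
}

#' Select expressed genes for clustering input
#'
#' Keeps genes expressed above `rpm_threshold` RPM in more than
#' `min_cell_fraction` of the cells. Both inequalities are strict: a gene
#' at exactly the RPM threshold does not count as expressed, and a gene
#' expressed in exactly the threshold fraction of cells is excluded.
#'
#' @param expr genes x cells RPM matrix.
#' @param rpm_threshold expression threshold in RPM (default 10).
#' @param min_cell_fraction required fraction of expressing cells
#'   (default 0.05).
#' @return character vector of kept gene identifiers (row order of
#'   `expr`).
#' @export
select_genes <- function(expr, rpm_threshold = 10, min_cell_fraction = 0.05) {
  if (is.null(dim(expr)) || ncol(expr) == 0 || nrow(expr) == 0) {
    stop("empty expression matrix", call. = FALSE)
  }
  stopifnot(rpm_threshold >= 0, min_cell_fraction >= 0)
  frac_expressing <- rowMeans(expr > rpm_threshold)
  rownames(expr)[frac_expressing > min_cell_fraction]
}
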