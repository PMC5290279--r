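#' Per-cell quality-control thresholds
#'
#' The five criteria applied to each sequenced cell, with the study's
#' defaults: at least 5 million sequenced read-pairs; more than 80% of
#' read-pairs mapped; less than 5% of reads on the mitochondrial
#' chromosome; at least one read aligned to eGFP; and at least ten raw
#' reads aligned to at least one canonical interneuron marker
#' (Dlx1, Dlx2, Dlx5, Dlx6, Gad1, Gad2). Inequality strictness follows
#' the wording: "at least" is inclusive, "more than"/"less than" are
#' strict.
#'
#' @param min_read_pairs minimum sequenced read-pairs (inclusive).
#' @param min_frac_mapped minimum mapped fraction (strict `>`).
#' @param max_frac_mito maximum mitochondrial fraction (strict `<`).
#' @param min_egfp_reads minimum eGFP-aligned reads (inclusive).
#' @param marker_genes interneuron marker genes; a missing gene counts as
#'   zero reads.
#' @param min_marker_reads raw reads required on at least one marker
#'   (inclusive).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_read_pairs = 5e6,
                          min_frac_mapped = 0.80,
                          max_frac_mito = 0.05,
                          min_egfp_reads = 1,
                          marker_genes = IN_HOUSEKEEPING,
                          min_marker_reads = 10) {
  if (length(marker_genes) == 0) {
    stop("marker_genes must be nonempty", call. = FALSE)
  }
  th <- list(min_read_pairs = min_read_pairs,
             min_frac_mapped = min_frac_mapped,
             max_frac_mito = max_frac_mito,
             min_egfp_reads = min_egfp_reads,
             marker_genes = marker_genes,
             min_marker_reads = min_marker_reads)
  num <- unlist(th[c("min_read_pairs", "min_frac_mapped", "max_frac_mito",
                     "min_egfp_reads", "min_marker_reads")])
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("qc thresholds must be nonnegative and finite", call. = FALSE)
  }
  class(th) <- "qc_thresholds"
  th
}

#' Apply per-cell quality control
#'
#' Evaluates the five QC criteria for every cell and reports, per cell,
#' the pass flag and the list of failed criteria, plus survivor counts
#' per developmental stage. A cell passes iff it satisfies all five
#' criteria. The marker-read criterion is evaluated on raw counts (QC
#' precedes normalization); a marker gene absent from the matrix
#' contributes zero reads.
#'
#' @param cells data.frame of per-cell metadata with columns `cell_id`,
#'   `stage`, `read_pairs`, `frac_mapped`, `frac_mito`, `egfp_reads`.
#' @param counts genes x cells raw count matrix; columns must match
#'   `cells$cell_id`.
#' @param thresholds a [qc_thresholds()] object.
#' @return data.frame of class `qc_report` with columns `cell_id`,
#'   `stage`, `pass`, `failed_criteria` (comma-separated, empty when
#'   passing), and attributes `summary` (survivors per stage) and
#'   `n_pass`.
#' @export
apply_qc <- function(cells, counts, thresholds = qc_thresholds()) {
  if (is.null(cells) || nrow(cells) == 0) {
    stop("empty cell list", call. = FALSE)
  }
  stopifnot(inherits(thresholds, "qc_thresholds"))
  req <- c("cell_id", "stage", "read_pairs", "frac_mapped", "frac_mito", "egfp_reads")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols) > 0) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(counts) != nrow(cells) || !all(cells$cell_id %in% colnames(counts))) {
    stop("counts/metadata mismatch: every cell needs a counts column",
         call. = FALSE)
  }
  counts <- counts[, cells$cell_id, drop = FALSE]

  marker_rows <- intersect(thresholds$marker_genes, rownames(counts))
  marker_ok <- if (length(marker_rows) == 0) {
    rep(FALSE, nrow(cells))
  } else {
    apply(counts[marker_rows, , drop = FALSE] >= thresholds$min_marker_reads,
          2, any)
  }

  crit <- cbind(
    min_read_pairs  = cells$read_pairs >= thresholds$min_read_pairs,
    min_frac_mapped = cells$frac_mapped > thresholds$min_frac_mapped,
    max_frac_mito   = cells$frac_mito < thresholds$max_frac_mito,
    min_egfp_reads  = cells$egfp_reads >= thresholds$min_egfp_reads,
    marker_reads    = unname(marker_ok)
  )
  failed <- apply(crit, 1, function(ok) paste(colnames(crit)[!ok], collapse = ","))
  report <- data.frame(
    cell_id = cells$cell_id,
    stage = cells$stage,
    pass = failed == "",
    failed_criteria = failed,
    stringsAsFactors = FALSE
  )
  surv <- table(factor(report$stage[report$pass], levels = unique(cells$stage)))
  attr(report, "summary") <- as.list(surv)
  attr(report, "n_pass") <- sum(report$pass)
  class(report) <- c("qc_report", "data.frame")
  report
}
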