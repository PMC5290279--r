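#' Shared-enrichment curve against a reference subtype family
#'
#' For each Z-score threshold on an incremental grid (default start 2.0,
#' step 0.1), takes the reference genes of the requested subtype family
#' with `z_score >= z` and reports the percentage of the query type's
#' enriched gene set found in that reference set:
#' `100 * |query intersect ref(z)| / |query|`. The denominator is the
#' fixed query set, so curves are comparable across families; gene
#' symbols are harmonized by case-insensitive exact match and unmatched
#' query symbols are reported via the `unmatched` attribute, never
#' dropped silently.
#'
#' @param query character vector, the query type's enriched genes
#'   (nonempty).
#' @param ref reference table with columns `gene`, `z_score`, `family`.
#' @param family which reference family to compare against.
#' @param z_start,z_step,z_max threshold grid; `z_max` defaults to the
#'   largest reference Z of the family (grid-aligned).
#' @return data.frame of class `shared_enrichment_curve` with columns
#'   `z`, `family`, `shared_percent`, `n_query`, `n_ref`; attribute
#'   `unmatched` lists query genes absent from the family's full gene
#'   list.
#' @export
shared_enrichment_curve <- function(query, ref, family,
                                    z_start = 2, z_step = 0.1, z_max = NULL) {
  if (length(query) == 0) stop("empty query gene set", call. = FALSE)
  stopifnot(all(c("gene", "z_score", "family") %in% names(ref)))
  fam <- ref[ref$family == family, , drop = FALSE]
  if (nrow(fam) == 0) {
    stop("no reference rows for family '", family, "'", call. = FALSE)
  }
  q <- unique(toupper(query))
  fam_genes <- toupper(fam$gene)
  if (is.null(z_max)) {
    z_max <- z_start + z_step * max(0, floor((max(fam$z_score) - z_start) / z_step))
  }
  if (z_max < z_start) z_max <- z_start
  grid <- seq(z_start, z_max, by = z_step)
  rows <- lapply(grid, function(z) {
    e_ref <- fam_genes[fam$z_score >= z]
    data.frame(z = z, family = family,
               shared_percent = 100 * length(intersect(q, e_ref)) / length(q),
               n_query = length(q), n_ref = length(e_ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "unmatched") <- query[!(toupper(query) %in% fam_genes)]
  class(out) <- c("shared_enrichment_curve", "data.frame")
  out
}
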