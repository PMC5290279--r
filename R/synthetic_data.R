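#' @importFrom stats plogis rnbinom rbinom rlnorm rpois runif rnorm rgamma
#'   median prcomp hclust cutree dist as.dist dnbinom optim sd var quantile
#'   p.adjust pnorm qnorm convolve t.test pt setNames aggregate approx
NULL

IN_HOUSEKEEPING <- c("Dlx1", "Dlx2", "Dlx5", "Dlx6", "Gad1", "Gad2")
QC_CRITERIA <- c("min_read_pairs", "min_frac_mapped", "max_frac_mito",
                 "min_egfp_reads", "marker_reads")

dropout_prob <- function(mu, midpoint, slope) {
  plogis(-slope * (log(mu) - log(midpoint)))
}

#' Generate a synthetic single-cell count matrix with known ground truth
#'
#' Simulates a gene x cell matrix of negative-binomial read counts with
#' planted cell types carrying marker genes at a known log2 fold change,
#' mean-dependent dropout (logistic Bernoulli masking in log NB mean), and
#' per-cell QC metadata consistent with the package's QC criteria except
#' for a planted fraction of cells that each violate exactly one named
#' criterion. The six interneuron housekeeping markers (Dlx1/2/5/6,
#' Gad1/2) are prepended to the gene list and highly expressed in every
#' cell, so only cells planted to fail the marker-read criterion fail it.
#'
#' Per-cell metadata records sequenced read-pairs (log-normal around the
#' nominal depth of 10 million), the fraction of read-pairs mapped, the
#' fraction of reads on the mitochondrial chromosome, eGFP-aligned reads,
#' and `mapped_reads`, the reads aligned to expressed genes — by
#' construction exactly the column sum of the count matrix, the
#' denominator of RPM normalization.
#'
#' @param params a [synthetic_params()] object.
#' @return a list of class `synthetic_counts` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x cells, with dimnames.}
#'     \item{cells}{data.frame of per-cell metadata: `cell_id`, `stage`,
#'       `read_pairs`, `frac_mapped`, `frac_mito`, `egfp_reads`,
#'       `mapped_reads`.}
#'     \item{truth}{ground truth: per-cell `type`, `stage`,
#'       `qc_should_fail`, `qc_fail_criterion`; `markers` (list mapping
#'       type to marker genes); `true_log2fc` (genes x types matrix, 0
#'       for non-markers).}
#'   }
#' @export
generate_counts <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  validate_synthetic_params(params)
  p <- params
  set.seed(p$seed)

  genes <- c(IN_HOUSEKEEPING, sprintf("Gene%04d", seq_len(p$n_genes)))
  n_genes_all <- length(genes)

  ## baseline NB means (count scale)
  base_mu <- numeric(n_genes_all)
  base_mu[seq_along(IN_HOUSEKEEPING)] <- 100
  base_mu[-seq_along(IN_HOUSEKEEPING)] <-
    exp(runif(p$n_genes, p$baseline_mean_log_range[1], p$baseline_mean_log_range[2]))

  ## disjoint marker sets, drawn from the non-housekeeping pool
  type_names <- paste0("type", seq_len(p$n_types))
  markers <- setNames(rep(list(character(0)), p$n_types), type_names)
  if (p$markers_per_type > 0) {
    marker_pool <- sample(genes[-seq_along(IN_HOUSEKEEPING)],
                          p$markers_per_type * p$n_types)
    markers <- setNames(split(marker_pool,
                              rep(seq_len(p$n_types), each = p$markers_per_type)),
                        type_names)
    base_mu[match(marker_pool, genes)] <-
      exp(runif(length(marker_pool), p$marker_mean_log_range[1], p$marker_mean_log_range[2]))
  }

  true_log2fc <- matrix(0, n_genes_all, p$n_types,
                        dimnames = list(genes, type_names))
  for (t in seq_len(p$n_types)) {
    true_log2fc[match(markers[[t]], genes), t] <- p$marker_log2fc
  }

  ## optional global stage effect on a random subset of genes
  stage_shift <- matrix(0, n_genes_all, p$n_stages)
  if (p$stage_shift_fraction > 0) {
    shifted <- sample(seq_len(n_genes_all),
                      round(p$stage_shift_fraction * n_genes_all))
    for (s in seq_len(p$n_stages)) {
      stage_shift[shifted, s] <- p$stage_shift_log2fc * (s - 1)
    }
  }

  n_cells <- p$cells_per_type_per_stage * p$n_types * p$n_stages
  cell_stage <- rep(p$stage_labels, each = p$cells_per_type_per_stage * p$n_types)
  cell_type <- rep(rep(seq_len(p$n_types), each = p$cells_per_type_per_stage),
                   times = p$n_stages)
  cell_id <- sprintf("%s_c%03d", cell_stage,
                     unlist(lapply(table(factor(cell_stage, levels = p$stage_labels)),
                                   seq_len), use.names = FALSE))

  counts <- matrix(0L, n_genes_all, n_cells, dimnames = list(genes, cell_id))
  for (i in seq_len(n_cells)) {
    mu_i <- base_mu * 2^(true_log2fc[, cell_type[i]] +
                         stage_shift[, match(cell_stage[i], p$stage_labels)])
    y <- rnbinom(n_genes_all, size = p$dispersion, mu = mu_i)
    drop <- rbinom(n_genes_all, 1L, dropout_prob(mu_i, p$dropout_midpoint, p$dropout_slope))
    y[drop == 1L] <- 0
    counts[, i] <- as.integer(y)
  }

  ## metadata consistent with QC pass
  read_pairs <- round(rlnorm(n_cells, meanlog = log(1e7), sdlog = 0.1))
  frac_mapped <- runif(n_cells, 0.85, 0.95)
  frac_mito <- runif(n_cells, 0.002, 0.04)
  egfp_reads <- rpois(n_cells, 50) + 1L

  ## plant QC failures: each failing cell violates exactly one criterion
  n_fail <- round(p$qc_fail_fraction * n_cells)
  qc_should_fail <- rep(FALSE, n_cells)
  qc_fail_criterion <- rep(NA_character_, n_cells)
  if (n_fail > 0) {
    fail_idx <- sample(n_cells, n_fail)
    crit <- rep_len(QC_CRITERIA, n_fail)
    qc_should_fail[fail_idx] <- TRUE
    qc_fail_criterion[fail_idx] <- crit
    for (j in seq_len(n_fail)) {
      i <- fail_idx[j]
      switch(crit[j],
        min_read_pairs = { read_pairs[i] <- round(runif(1, 1e6, 4.99e6)) },
        min_frac_mapped = { frac_mapped[i] <- runif(1, 0.5, 0.80) },
        max_frac_mito = { frac_mito[i] <- runif(1, 0.05, 0.20) },
        min_egfp_reads = { egfp_reads[i] <- 0L },
        marker_reads = {
          counts[IN_HOUSEKEEPING, i] <- as.integer(sample(0:5, length(IN_HOUSEKEEPING),
                                                          replace = TRUE))
        })
    }
  }

  cells <- data.frame(
    cell_id = cell_id,
    stage = cell_stage,
    read_pairs = read_pairs,
    frac_mapped = frac_mapped,
    frac_mito = frac_mito,
    egfp_reads = egfp_reads,
    mapped_reads = unname(colSums(counts)),
    stringsAsFactors = FALSE
  )

  truth <- list(
    type = setNames(paste0("type", cell_type), cell_id),
    stage = setNames(cell_stage, cell_id),
    qc_should_fail = setNames(qc_should_fail, cell_id),
    qc_fail_criterion = setNames(qc_fail_criterion, cell_id),
    markers = markers,
    true_log2fc = true_log2fc
  )

  structure(list(counts = counts, cells = cells, truth = truth),
            class = "synthetic_counts")
}

#' Generate a synthetic reference differential-expression table
#'
#' Builds a reference table of (gene, Z-score, subtype-family label) rows
#' in which a controlled subset of a query gene set appears with
#' prescribed Z-scores, emulating the published gray-matter interneuron
#' subtype tables used for shared-enrichment comparison. Background genes
#' carry synthetic identifiers and Gaussian Z-scores; query genes not
#' selected as shared do not appear in the table, so the intersection with
#' the query set is fully controlled.
#'
#' @param n_genes number of background reference genes.
#' @param query_genes character vector, the query gene set from which
#'   shared genes are drawn.
#' @param n_shared how many query genes to plant in the reference
#'   (`0 <= n_shared <= length(query_genes)`).
#' @param shared_z Z-scores given to the shared genes; recycled to
#'   `n_shared` (a vector allows, e.g., half below and half above a
#'   threshold).
#' @param family family label for every row (e.g. `"Reln-like"`).
#' @param background_z_mean,background_z_sd Gaussian parameters of the
#'   background Z-scores.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `z_score`, `family`.
#' @export
generate_reference_de <- function(n_genes, query_genes, n_shared,
                                  shared_z = 5, family = "Reln-like",
                                  background_z_mean = 0, background_z_sd = 1,
                                  seed = 1L) {
  if (n_shared > length(query_genes)) {
    stop("n_shared exceeds the size of the query gene set", call. = FALSE)
  }
  set.seed(seed)
  shared <- if (n_shared > 0) sample(query_genes, n_shared) else character(0)
  bg <- sprintf("Refg%05d", seq_len(n_genes))
  bg <- setdiff(bg, shared)
  data.frame(
    gene = c(shared, bg),
    z_score = c(rep_len(shared_z, n_shared),
                rnorm(length(bg), background_z_mean, background_z_sd)),
    family = family,
    stringsAsFactors = FALSE
  )
}

crw_track <- function(n_steps, dt, step_length_mean, kappa) {
  heading0 <- runif(1, -pi, pi)
  turns <- if (kappa == 0) {
    runif(n_steps - 1, -pi, pi)
  } else if (is.infinite(kappa)) {
    rep(0, n_steps - 1)
  } else {
    rnorm(n_steps - 1, 0, 1 / sqrt(kappa))
  }
  headings <- cumsum(c(heading0, turns))
  steps <- if (step_length_mean == 0) {
    rep(0, n_steps)
  } else {
    rgamma(n_steps, shape = 4, scale = step_length_mean / 4)
  }
  data.frame(
    t_min = dt * (0:n_steps),
    x_um = cumsum(c(0, steps * cos(headings))),
    y_um = cumsum(c(0, steps * sin(headings)))
  )
}

#' Generate synthetic migration tracks as correlated random walks
#'
#' Each track is a correlated random walk: per-frame turning angles are
#' Gaussian with variance `1/turning_concentration` (uniform on the circle
#' when the concentration is 0, straight-line in the infinite limit) and
#' per-frame step lengths are Gamma distributed around
#' `step_length_mean`. Higher turning concentration yields higher expected
#' directional persistence. Timestamps are multiples of `dt`.
#'
#' @param params a [track_params()] object, the shared base parameters.
#' @param groups optional named list of per-group parameter overrides,
#'   e.g. `list(PSB = list(turning_concentration = 5), CGE = list())`,
#'   emulating two graft conditions. When given, the result carries a
#'   `group` column and per-group track id prefixes.
#' @return data.frame with columns `track_id`, `t_min`, `x_um`, `y_um`
#'   (and `group` when `groups` is given).
#' @export
generate_tracks <- function(params = track_params(), groups = NULL) {
  stopifnot(inherits(params, "track_params"))
  if (!is.null(groups)) {
    if (is.null(names(groups)) || any(names(groups) == "")) {
      stop("groups must be a named list of parameter overrides", call. = FALSE)
    }
    out <- lapply(seq_along(groups), function(g) {
      pg <- params
      pg[names(groups[[g]])] <- groups[[g]]
      pg$seed <- params$seed + g - 1L
      tr <- generate_tracks(pg)
      tr$track_id <- paste0(names(groups)[g], "_", tr$track_id)
      tr$group <- names(groups)[g]
      tr
    })
    return(do.call(rbind, out))
  }
  set.seed(params$seed)
  tracks <- lapply(seq_len(params$n_tracks), function(i) {
    tr <- crw_track(params$n_steps, params$dt, params$step_length_mean,
                    params$turning_concentration)
    cbind(track_id = sprintf("T%03d", i), tr, stringsAsFactors = FALSE)
  })
  do.call(rbind, tracks)
}
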