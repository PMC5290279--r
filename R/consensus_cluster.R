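#' Clustering parameters for consensus typing
#'
#' Defaults follow the study design: cells are projected onto the top 10
#' principal components of log2(RPM + 1) expression, agglomerated with
#' Ward linkage on Euclidean distances, and the procedure is repeated 100
#' times on random 80% subsamples of the cells to measure co-clustering
#' stability. K defaults to the three robust interneuron types.
#'
#' @param k number of clusters to cut (>= 2).
#' @param n_components number of principal components (reduced
#'   automatically, with a warning, when it exceeds what the data
#'   support).
#' @param distance distance metric passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()];
#'   `"ward.D2"` is Ward's criterion on raw Euclidean distances.
#' @param n_runs number of resampling runs for the stability score.
#' @param sample_fraction fraction of cells drawn (without replacement)
#'   per run.
#' @param log_transform log2(x + 1)-transform expression before PCA.
#' @param scale_genes variance-scale genes before PCA (centering is
#'   always applied).
#' @param seed integer seed for the resampling.
#' @return an object of class `clustering_params`.
#' @export
clustering_params <- function(k = 3, n_components = 10,
                              distance = "euclidean", linkage = "ward.D2",
                              n_runs = 100, sample_fraction = 0.8,
                              log_transform = TRUE, scale_genes = FALSE,
                              seed = 1L) {
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must be in (0, 1]", call. = FALSE)
  }
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  structure(list(k = k, n_components = n_components, distance = distance,
                 linkage = linkage, n_runs = n_runs,
                 sample_fraction = sample_fraction,
                 log_transform = log_transform, scale_genes = scale_genes,
                 seed = seed),
            class = "clustering_params")
}

pca_scores <- function(expr, params) {
  x <- t(expr)                               # cells x genes
  if (params$log_transform) x <- log2(x + 1)
  n_comp <- params$n_components
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (n_comp > max_comp) {
    warning("n_components reduced from ", n_comp, " to ", max_comp,
            " (limited by data dimensions)", call. = FALSE)
    n_comp <- max_comp
  }
  pc <- prcomp(x, center = TRUE, scale. = params$scale_genes, rank. = n_comp)
  pc$x[, seq_len(n_comp), drop = FALSE]
}

#' PCA followed by hierarchical clustering
#'
#' Projects cells onto the top principal components of the
#' (log-transformed) expression of pre-selected genes, computes pairwise
#' distances, agglomerates, and cuts the tree into `k` clusters.
#' Deterministic given its input.
#'
#' @param expr genes x cells expression matrix (RPM of selected genes).
#' @param params a [clustering_params()] object.
#' @param k number of clusters; defaults to `params$k`.
#' @return integer cluster labels (1..k) named by cell.
#' @export
pca_hclust <- function(expr, params = clustering_params(), k = params$k) {
  if (ncol(expr) <= k) {
    stop("need more cells than clusters", call. = FALSE)
  }
  sc <- pca_scores(expr, params)
  hc <- hclust(dist(sc, method = params$distance), method = params$linkage)
  cutree(hc, k = k)
}

#' Resampled co-clustering stability matrix
#'
#' Repeats PCA + hierarchical clustering `n_runs` times on random
#' subsamples of `ceiling(sample_fraction * n)` cells drawn without
#' replacement (PCA recomputed on each subsample) and records, for every
#' pair of cells, the proportion of runs in which both were drawn and
#' assigned the same cluster, out of the runs in which both were drawn.
#' The diagonal is 1; pairs never co-sampled are flagged `NA`, never
#' silently zeroed.
#'
#' @param expr genes x cells expression matrix (RPM of selected genes).
#' @param params a [clustering_params()] object (uses `k`, `n_runs`,
#'   `sample_fraction`, `seed` and the PCA/linkage settings).
#' @return an object of class `stability_matrix`: list with `s` (cell x
#'   cell stability scores in [0,1], `NA`-flagged where undefined),
#'   `co_sampled` and `co_clustered` (pair counts), and `n_runs`.
#' @export
stability_matrix <- function(expr, params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"))
  n <- ncol(expr)
  cells <- colnames(expr)
  m <- ceiling(params$sample_fraction * n)
  if (m <= params$k) stop("subsample smaller than k", call. = FALSE)
  set.seed(params$seed)
  co_sampled <- matrix(0L, n, n, dimnames = list(cells, cells))
  co_clustered <- matrix(0L, n, n, dimnames = list(cells, cells))
  for (r in seq_len(params$n_runs)) {
    idx <- sort(sample.int(n, m))
    labels <- pca_hclust(expr[, idx, drop = FALSE], params)
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1L
    same <- outer(labels, labels, "==")
    co_clustered[idx, idx] <- co_clustered[idx, idx] + same
  }
  s <- ifelse(co_sampled > 0, co_clustered / co_sampled, NA_real_)
  diag(s) <- 1
  n_flagged <- sum(is.na(s[upper.tri(s)]))
  if (n_flagged > 0) {
    warning(n_flagged, " cell pair(s) never co-sampled; stability flagged NA",
            call. = FALSE)
  }
  structure(list(s = s, co_sampled = co_sampled, co_clustered = co_clustered,
                 n_runs = params$n_runs),
            class = "stability_matrix")
}

stability_dissimilarity <- function(s) {
  mat <- if (inherits(s, "stability_matrix")) s$s else s
  if (any(is.na(mat))) {
    ## flagged pairs imputed at the overall mean stability for tree building
    mat[is.na(mat)] <- mean(mat, na.rm = TRUE)
  }
  as.dist(1 - mat)
}

#' Consensus cluster assignment from a stability matrix
#'
#' Hierarchically clusters cells on the dissimilarity `1 - s` (average
#' linkage) and cuts into `k` clusters — the final robust assignment that
#' a stability heatmap displays. Also returns the leaf order for heatmap
#' display.
#'
#' @param s a [stability_matrix()] object (or a plain symmetric matrix of
#'   stability scores).
#' @param k number of consensus clusters.
#' @return an object of class `cluster_assignment`: list with `labels`
#'   (integer 1..k named by cell), `order` (heatmap leaf order), `k`,
#'   and `hclust` (the consensus tree).
#' @export
consensus_assign <- function(s, k) {
  mat <- if (inherits(s, "stability_matrix")) s$s else s
  n <- ncol(mat)
  if (k > n) stop("k exceeds the number of cells", call. = FALSE)
  d <- stability_dissimilarity(s)
  hc <- hclust(d, method = "average")
  if (max(hc$height) <= .Machine$double.eps) {
    warning("degenerate stability matrix: all cells perfectly co-cluster; ",
            "any k-partition has zero-height merges", call. = FALSE)
  }
  labels <- cutree(hc, k = k)
  structure(list(labels = labels, order = hc$order, k = k, hclust = hc),
            class = "cluster_assignment")
}

#' Suggest the number of consensus clusters
#'
#' Advisory heuristic: cuts the consensus tree at each k in `2..k_max`
#' and returns the k maximizing the mean silhouette width on the
#' dissimilarity `1 - s`. Absence of structure is flagged by the
#' proportion of ambiguous clustering (PAC): the fraction of
#' off-diagonal stability scores falling strictly between 0.1 and 0.9.
#' Resampled co-clustering of structureless data leaves most pair
#' scores at intermediate values (a silhouette on the consensus matrix
#' itself is blind to this, as forced cluster boundaries look crisp);
#' when more than half of all pair scores are ambiguous (PAC > 0.5) the
#' result carries `no_structure = TRUE`.
#'
#' @param s a [stability_matrix()] object or plain stability matrix.
#' @param k_max largest k considered (>= 2).
#' @return integer k with attributes `sil_width` (named mean silhouette
#'   per k), `pac` (proportion of ambiguous clustering) and
#'   `no_structure` (logical).
#' @export
suggest_k <- function(s, k_max = 6) {
  if (k_max < 2) stop("k_max must be >= 2", call. = FALSE)
  mat <- if (inherits(s, "stability_matrix")) s$s else s
  k_max <- min(k_max, ncol(mat) - 1L)
  d <- stability_dissimilarity(s)
  hc <- hclust(d, method = "average")
  dmat <- as.matrix(d)
  widths <- vapply(2:k_max, function(k) {
    sil <- cluster::silhouette(cutree(hc, k = k), dmatrix = dmat)
    mean(sil[, "sil_width"])
  }, numeric(1))
  names(widths) <- 2:k_max
  best <- as.integer(names(widths)[which.max(widths)])
  off_diag <- mat[upper.tri(mat)]
  pac <- mean(off_diag > 0.1 & off_diag < 0.9, na.rm = TRUE)
  structure(best, sil_width = widths, pac = pac, no_structure = pac > 0.5)
}
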