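#' t-SNE embedding of cells
#'
#' Two-dimensional t-SNE of cells on log2(RPM + 1) expression of selected
#' genes, computed on the top principal components and initialized from
#' the first two components (a deterministic, spectral-style
#' initialization that makes runs reproducible under a fixed seed).
#' Cells are canonicalized to a fixed internal order (sorted by
#' identifier) before embedding, so permuting the input columns does not
#' change any cell's coordinates.
#'
#' The main cross-stage embedding uses the conventional perplexity of 30;
#' subtype parcellation within one main type uses perplexity 4.
#'
#' @param expr genes x cells expression matrix (RPM of selected genes).
#' @param perplexity t-SNE perplexity; requires at least
#'   `3 * perplexity` cells.
#' @param n_iter gradient-descent iterations (>= 250).
#' @param n_pcs number of principal components fed to t-SNE.
#' @param log_transform log2(x + 1)-transform before PCA.
#' @param seed integer seed.
#' @return data.frame of class `embedding_result` with columns
#'   `cell_id`, `tsne1`, `tsne2` (rows in input cell order) and a
#'   `params` attribute echoing the settings.
#' @export
embed_cells <- function(expr, perplexity = 30, n_iter = 1000, n_pcs = 50,
                        log_transform = TRUE, seed = 1L) {
  n <- ncol(expr)
  if (perplexity >= n) {
    stop("perplexity must be smaller than the number of cells", call. = FALSE)
  }
  if (n < 3 * perplexity) {
    stop("need at least 3 * perplexity cells", call. = FALSE)
  }
  if (n_iter < 250) stop("n_iter must be >= 250", call. = FALSE)
  cells <- colnames(expr)
  ord <- order(cells)                         # canonical order
  x <- t(expr[, ord, drop = FALSE])
  if (log_transform) x <- log2(x + 1)
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = TRUE, rank. = max(n_pcs, 2L))
  scores <- pc$x
  init <- scores[, 1:2, drop = FALSE]
  init <- init / stats::sd(init[, 1]) * 1e-4   # standard small-norm init
  set.seed(seed)
  fit <- Rtsne::Rtsne(scores[, seq_len(n_pcs), drop = FALSE],
                      dims = 2, perplexity = perplexity,
                      max_iter = n_iter, Y_init = init,
                      pca = FALSE, check_duplicates = FALSE)
  coords <- fit$Y[match(cells, cells[ord]), , drop = FALSE]
  out <- data.frame(cell_id = cells, tsne1 = coords[, 1], tsne2 = coords[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(perplexity = perplexity, n_iter = n_iter,
                              n_pcs = n_pcs, seed = seed)
  class(out) <- c("embedding_result", "data.frame")
  out
}

#' Subtype clustering in t-SNE space
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' 2-D t-SNE coordinates of the cells of one main type, cut into `k_sub`
#' subtype labels — the parcellation step behind subtype marker
#' discovery.
#'
#' @param emb an [embed_cells()] result (or a data.frame with `cell_id`,
#'   `tsne1`, `tsne2`).
#' @param k_sub number of subtypes (>= 2).
#' @return integer subtype labels (1..k_sub) named by cell.
#' @export
subtype_clusters <- function(emb, k_sub) {
  if (k_sub < 2) stop("k_sub must be >= 2", call. = FALSE)
  if (k_sub > nrow(emb)) {
    stop("k_sub exceeds the number of cells", call. = FALSE)
  }
  coords <- as.matrix(emb[, c("tsne1", "tsne2")])
  d <- dist(coords)
  if (max(d) <= .Machine$double.eps) {
    warning("degenerate embedding: all points coincide; a single effective cluster",
            call. = FALSE)
  }
  hc <- hclust(d, method = "average")
  labels <- cutree(hc, k = k_sub)
  names(labels) <- emb$cell_id
  labels
}
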