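# shared fixtures and independent oracles used across test files

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small planted-type dataset for fast pipeline tests
small_sim <- function(seed = 1, ...) {
  args <- list(n_genes = 300, cells_per_type_per_stage = 15,
               markers_per_type = 25, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  generate_counts(do.call(synthetic_params, args))
}

# homogeneous population (no planted types)
null_sim <- function(seed = 1, n_cells = 90, n_genes = 500) {
  generate_counts(synthetic_params(
    n_genes = n_genes, cells_per_type_per_stage = n_cells, n_types = 1,
    n_stages = 1, stage_labels = "P2", markers_per_type = 0, seed = seed))
}

# brute-force agglomerative clustering with average linkage on a distance
# matrix: sequential merging of the closest pair until k clusters remain
naive_average_linkage <- function(dmat, k) {
  n <- nrow(dmat)
  members <- as.list(seq_len(n))
  while (length(members) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (j <= i) next
        d <- mean(dmat[members[[i]], members[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(members)) labels[members[[i]]] <- i
  labels
}

# loop-based RPM oracle
rpm_oracle <- function(counts, mapped) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      out[i, j] <- counts[i, j] / mapped[j] * 1e6
    }
  }
  out
}

# loop-based track metric oracle
track_metrics_oracle <- function(track) {
  path <- 0
  for (i in 2:nrow(track)) {
    path <- path + sqrt((track$x_um[i] - track$x_um[i - 1])^2 +
                        (track$y_um[i] - track$y_um[i - 1])^2)
  }
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
              (track$y_um[nrow(track)] - track$y_um[1])^2)
  dur <- (track$t_min[nrow(track)] - track$t_min[1]) / 60
  list(speed = path / dur, persistence = if (path == 0) 0 else net / path,
       path_length = path, net_displacement = net)
}

# Monte-Carlo oracle: expected persistence of an isotropic random walk
# with Gamma(shape = 4) step lengths
isotropic_persistence_oracle <- function(n_steps, n_walks = 10000, seed = 99) {
  set.seed(seed)
  vals <- numeric(n_walks)
  for (w in seq_len(n_walks)) {
    ang <- runif(n_steps, -pi, pi)
    len <- rgamma(n_steps, shape = 4, scale = 1 / 4)
    dx <- sum(len * cos(ang)); dy <- sum(len * sin(ang))
    vals[w] <- sqrt(dx^2 + dy^2) / sum(len)
  }
  mean(vals)
}

# minimal per-cell metadata passing all QC criteria
passing_cells <- function(n, stage = "P2") {
  data.frame(
    cell_id = sprintf("cell%03d", seq_len(n)),
    stage = stage,
    read_pairs = 8e6,
    frac_mapped = 0.9,
    frac_mito = 0.01,
    egfp_reads = 10,
    stringsAsFactors = FALSE
  )
}

# counts matrix whose marker rows satisfy the marker-read criterion
passing_counts <- function(cells, n_genes = 20) {
  genes <- c("Dlx1", "Dlx2", "Dlx5", "Dlx6", "Gad1", "Gad2",
             sprintf("g%03d", seq_len(n_genes)))
  m <- matrix(5L, length(genes), nrow(cells),
              dimnames = list(genes, cells$cell_id))
  m["Gad1", ] <- 50L
  m
}
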