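## Dropout-aware differential expression.
##
## Observation model per group: a count y for a gene with group mean mu is
## zero-inflated negative binomial — with probability pi(mu) the
## transcript drops out (y = 0); otherwise y ~ NB(size = theta, mu).
## pi is logistic in log mu: pi(mu) = plogis(a0 + a1 * log mu), so poorly
## expressed genes drop out more often. (a0, a1, theta) are fitted per
## group; fold changes are profiled on a log2 grid.

#' Fit the per-group dropout/overdispersion error model
#'
#' Estimates, for one group of cells: the NB size parameter `theta` by
#' method of moments on nonzero counts (median across genes); the
#' dropout logistic `(a0, a1)` by maximum likelihood on observed zero
#' fractions of genes binned by mean, in excess of the zeros the NB
#' itself predicts; and per-gene dropout-corrected group means `mu`
#' solving `mu * (1 - pi(mu)) = mean(y)`.
#'
#' @param counts genes x cells raw count matrix.
#' @param group_cells column names (or indices) of the group's cells
#'   (>= 5).
#' @param n_bins number of gene bins for the dropout fit.
#' @return an object of class `error_model`: list with `a0`, `a1`,
#'   `theta`, `mu` (named per-gene corrected means), `cells`.
#' @export
fit_error_model <- function(counts, group_cells, n_bins = 20) {
  y <- counts[, group_cells, drop = FALSE]
  if (ncol(y) < 5) stop("need at least 5 cells in the group", call. = FALSE)
  if (all(y == 0)) stop("degenerate model: group has no nonzero counts", call. = FALSE)
  n_cells <- ncol(y)

  nz_mean <- apply(y, 1, function(r) if (any(r > 0)) mean(r[r > 0]) else NA_real_)

  ## theta: method of moments on nonzero counts, per gene, correcting the
  ## zero-truncation of the moments; for a zero-truncated NB,
  ## E[Y^2|Y>0]/E[Y|Y>0] - 1 = mu (1 + 1/theta) and
  ## E[Y|Y>0] = mu / (1 - p0(mu, theta)); solved for theta by root
  ## finding, median over genes
  theta_g <- apply(y, 1, function(r) {
    rnz <- r[r > 0]
    if (length(rnz) < 5) return(NA_real_)
    m1 <- mean(rnz)
    q <- mean(rnz^2) / m1 - 1
    if (q <= 0) return(NA_real_)
    gap <- function(th) {
      mu <- q / (1 + 1 / th)
      p0 <- (th / (th + mu))^th
      mu / (1 - p0) - m1
    }
    lo <- gap(0.01); hi <- gap(1000)
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NA_real_)
    tryCatch(stats::uniroot(gap, c(0.01, 1000), tol = 1e-4)$root,
             error = function(e) NA_real_)
  })
  theta <- median(theta_g, na.rm = TRUE)
  if (!is.finite(theta)) theta <- 10        # near-Poisson fallback
  theta <- min(max(theta, 0.01), 1000)

  ## dropout logistic: excess zeros over NB expectation, genes binned by mean
  obs <- data.frame(lmu = log(nz_mean),
                    zeros = rowSums(y == 0),
                    nb0 = (theta / (theta + nz_mean))^theta)
  obs <- obs[is.finite(obs$lmu), , drop = FALSE]
  bins <- cut(obs$lmu, breaks = unique(quantile(obs$lmu, probs = seq(0, 1, length.out = n_bins + 1))),
              include.lowest = TRUE)
  bin_lmu <- tapply(obs$lmu, bins, mean)
  bin_nb0 <- tapply(obs$nb0, bins, mean)
  bin_zero <- tapply(obs$zeros, bins, sum)
  bin_n <- tapply(rep(n_cells, nrow(obs)), bins, sum)
  keep <- !is.na(bin_lmu)
  bin_lmu <- bin_lmu[keep]; bin_nb0 <- bin_nb0[keep]
  bin_zero <- bin_zero[keep]; bin_n <- bin_n[keep]

  negll <- function(par) {
    pi_b <- plogis(par[1] + par[2] * bin_lmu)
    q <- pmin(pmax(pi_b + (1 - pi_b) * bin_nb0, 1e-10), 1 - 1e-10)
    -sum(bin_zero * log(q) + (bin_n - bin_zero) * log(1 - q))
  }
  fit <- optim(c(0, -1), negll, method = "L-BFGS-B",
               lower = c(-20, -10), upper = c(20, 10))
  a0 <- fit$par[1]; a1 <- fit$par[2]

  ## dropout-corrected group means: mu * (1 - pi(mu)) = observed mean
  ybar <- rowMeans(y)
  mu <- ybar
  pos <- mu > 0
  for (it in 1:50) {
    pi_mu <- pmin(plogis(a0 + a1 * log(pmax(mu[pos], 1e-12))), 0.95)
    mu_new <- ybar[pos] / (1 - pi_mu)
    if (max(abs(mu_new - mu[pos]) / pmax(mu[pos], 1e-12)) < 1e-8) {
      mu[pos] <- mu_new
      break
    }
    mu[pos] <- mu_new
  }
  structure(list(a0 = a0, a1 = a1, theta = theta, mu = mu,
                 cells = colnames(y), n_cells = n_cells),
            class = "error_model")
}

#' Dropout probability implied by an error model
#' @param model an [fit_error_model()] result.
#' @param mu expression mean(s), count scale.
#' @return dropout probabilities in (0, 1).
#' @export
dropout_probability <- function(model, mu) {
  plogis(model$a0 + model$a1 * log(pmax(mu, 1e-12)))
}

## log-likelihood of one group's counts under the ZINB model, vectorized
## over a grid of candidate means m (one number per grid point)
zinb_grid_loglik <- function(y, m, theta, a0, a1) {
  n0 <- sum(y == 0)
  ynz <- y[y > 0]
  ll <- numeric(length(m))
  M <- zinb_cell_loglik(c(if (n0 > 0) 0L, ynz), m, theta, a0, a1)
  if (n0 > 0) {
    ll <- n0 * M[1, ]
    M <- M[-1, , drop = FALSE]
  }
  if (length(ynz) > 0) ll <- ll + colSums(M)
  ll
}

## per-count-value ZINB log-likelihood matrix: one row per value of `y`,
## one column per candidate mean in `m`
zinb_cell_loglik <- function(y, m, theta, a0, a1) {
  ## clamp away from 1 so a nonzero count at a vanishing mean stays a
  ## finite (if astronomically negative) log-likelihood
  pi_m <- pmin(plogis(a0 + a1 * log(m)), 1 - 1e-12)
  out <- matrix(NA_real_, length(y), length(m))
  z <- y == 0
  if (any(z)) {
    p0 <- log(pmax(pi_m + (1 - pi_m) * dnbinom(0, size = theta, mu = m), 1e-300))
    out[z, ] <- matrix(p0, sum(z), length(m), byrow = TRUE)
  }
  if (any(!z)) {
    ynz <- y[!z]
    dens <- dnbinom(rep(ynz, times = length(m)), size = theta,
                    mu = rep(m, each = length(ynz)), log = TRUE)
    out[!z, ] <- matrix(dens, length(ynz), length(m)) +
      matrix(log(1 - pi_m), length(ynz), length(m), byrow = TRUE)
  }
  out
}

grid_argmax <- function(ll, grid) {
  top <- which(ll == max(ll))
  top[which.min(abs(grid[top]))]            # ties resolved toward 0
}

#' Differential expression of one type against all other cells
#'
#' For every gene, each group's expression distribution is built by
#' evaluating the zero-inflated NB likelihood of the group's counts over
#' a grid of log2 means and aggregating it across bootstrap resamples of
#' the cells (which propagates cell-level heterogeneity that a single
#' product likelihood understates); the fold-change distribution f
#' (target over complement) is then the discrete cross-correlation of
#' the two normalized group curves under a flat log-scale prior — the
#' joint-posterior construction of dropout-aware single-cell DE. The MLE log2 fold change is the argmax of this curve
#' restricted to `[-grid_max, grid_max]` (ties resolved toward 0); the
#' Z-score is the signed standard-normal quantile of the fold-change
#' distribution's mass above zero — the confidence of over- or
#' under-expression expressed on the z scale, as a classical p-value
#' would be — so a fold that the data leave unidentified (e.g. a gene
#' undetected in either group) earns a wide distribution and a small Z
#' rather than spurious confidence. The
#' construction is exactly antisymmetric: swapping target and complement
#' negates both the MLE and the Z-score. Adjusted expressions are the
#' per-group posterior means on the RPM scale.
#'
#' @param counts genes x cells raw count matrix (all retained cells).
#' @param assignment a [consensus_assign()] result, or a named vector /
#'   factor of type labels per cell.
#' @param target_type the type label tested against the rest.
#' @param mapped_reads per-cell mapped-read totals used to put adjusted
#'   expressions on the RPM scale; defaults to column sums of `counts`.
#' @param grid_max,grid_step log2 fold-change grid `[-grid_max,
#'   grid_max]` by `grid_step`; the log2 expression grid spans
#'   `-grid_max` to the data maximum at the same step.
#' @param boot_resamples number of bootstrap resamples of cells used to
#'   build each group's expression distribution (the aggregate of
#'   resampled-cell posteriors); 0 uses the plain product likelihood
#'   over cells, which understates cell-level heterogeneity.
#' @param seed seed for the bootstrap resampling (the caller's RNG
#'   state is preserved); resamples are tied to the group's cell set,
#'   not to its role, so swapping target and complement reuses the same
#'   resamples and the antisymmetry is exact.
#' @param models optional list(target, rest) of precomputed
#'   [fit_error_model()] fits.
#' @param return_curves keep the per-gene fold-change distribution
#'   curves (as a `curves` attribute).
#' @return data.frame of class `de_result`: per gene `mle_log2fc`,
#'   `z_score`, `adj_expr_target`, `adj_expr_rest`, `p_value`, `fdr`
#'   (emitted for convenience, unused by enrichment selection), `flag`.
#' @export
de_test <- function(counts, assignment, target_type,
                    mapped_reads = NULL,
                    grid_max = 10, grid_step = 0.05,
                    boot_resamples = 150, seed = 1L,
                    models = NULL, return_curves = FALSE) {
  labels <- if (inherits(assignment, "cluster_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  if (is.null(names(labels))) {
    stopifnot(length(labels) == ncol(counts))
    names(labels) <- colnames(counts)
  }
  t_cells <- names(labels)[labels == target_type]
  c_cells <- setdiff(names(labels), t_cells)
  if (length(t_cells) < 5 || length(c_cells) < 5) {
    stop("need at least 5 cells in the target type and in the complement",
         call. = FALSE)
  }
  if (is.null(mapped_reads)) mapped_reads <- colSums(counts)
  if (is.null(names(mapped_reads))) names(mapped_reads) <- colnames(counts)

  if (is.null(models)) {
    models <- list(target = fit_error_model(counts, t_cells),
                   rest = fit_error_model(counts, c_cells))
  }
  mt <- models$target; mc <- models$rest
  rpm_t <- mean(1e6 / mapped_reads[t_cells])
  rpm_c <- mean(1e6 / mapped_reads[c_cells])

  ## log2 expression grid shared by both groups; its cross-correlation
  ## spans fold changes beyond [-grid_max, grid_max], then truncated
  lg_max <- max(grid_max, ceiling(log2(max(counts) + 1)) + 2)
  lgrid <- seq(-grid_max, lg_max, by = grid_step)
  mu_grid <- 2^lgrid
  L <- length(lgrid)
  f_full <- grid_step * seq.int(-(L - 1), L - 1)  # cross-correlation lags
  in_window <- abs(f_full) <= grid_max + grid_step / 2
  f_grid <- f_full[in_window]

  genes <- rownames(counts)
  n_genes <- length(genes)
  mle <- numeric(n_genes); zsc <- numeric(n_genes)
  adj_t <- numeric(n_genes); adj_c <- numeric(n_genes)
  flag <- character(n_genes)
  curves <- if (return_curves) matrix(NA_real_, n_genes, length(f_grid),
                                      dimnames = list(genes, NULL)) else NULL

  ## empirical prior over log2 expression magnitude, shared by both
  ## groups: kernel density of the genes' dropout-corrected means mixed
  ## with a uniform floor so no magnitude has zero support; anchors the
  ## posterior of a group in which a gene went undetected at plausible
  ## low expression instead of the grid boundary
  prior_sample <- log2(pmax(c(mt$mu, mc$mu), 2^lgrid[1]))
  dens <- stats::density(prior_sample, from = lgrid[1],
                         to = lgrid[length(lgrid)], n = length(lgrid))
  prior <- dens$y / sum(dens$y)
  prior <- 0.9 * prior + 0.1 / length(lgrid)
  log_prior <- log(prior)

  ## bootstrap cell weights per group, tied to the group's cell set so
  ## that the same group reuses the same resamples in any role
  boot_weights <- function(cells) {
    if (boot_resamples == 0) return(NULL)
    group_seed <- (abs(seed) + sum(utf8ToInt(paste(sort(cells), collapse = "")))) %%
      .Machine$integer.max
    set.seed(group_seed)
    n <- length(cells)
    t(stats::rmultinom(boot_resamples, size = n, prob = rep(1 / n, n)))
  }
  rng_state <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  Wt <- boot_weights(t_cells)
  Wc <- boot_weights(c_cells)
  if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv())

  group_posterior <- function(y, model, W) {
    if (is.null(W)) {
      ll <- zinb_grid_loglik(y, mu_grid, model$theta, model$a0, model$a1) +
        log_prior
      p <- exp(ll - max(ll))
      return(p / sum(p))
    }
    u <- unique(y)
    Mu <- zinb_cell_loglik(u, mu_grid, model$theta, model$a0, model$a1)
    A <- outer(y, u, "==") + 0                 # cells x unique values
    llb <- (W %*% A) %*% Mu                    # resamples x grid
    llb <- sweep(llb, 2, log_prior, "+")
    llb <- llb - llb[cbind(seq_len(nrow(llb)), max.col(llb, ties.method = "first"))]
    pb <- exp(llb)
    pb <- pb / rowSums(pb)
    colMeans(pb)
  }

  for (g in seq_len(n_genes)) {
    yt <- counts[g, t_cells]; yc <- counts[g, c_cells]
    if (sum(yt) + sum(yc) == 0) {
      flag[g] <- "uninformative"
      next
    }
    pt <- group_posterior(yt, mt, Wt)
    pc <- group_posterior(yc, mc, Wc)
    adj_t[g] <- sum(pt * mu_grid) * rpm_t
    adj_c[g] <- sum(pc * mu_grid) * rpm_c
    ## distribution of f = log2(mu_t) - log2(mu_c): cross-correlation
    pf <- convolve(pt, pc, conj = TRUE, type = "open")
    pf <- pmax(pf[in_window], 0)
    pf <- pf / sum(pf)
    if (return_curves) curves[g, ] <- pf
    i <- grid_argmax(pf, f_grid)
    mle[g] <- f_grid[i]
    ## confidence of over-/under-expression: signed normal quantile of
    ## the fold-distribution mass above zero (antisymmetric; calibrated
    ## under the null)
    p_pos <- sum(pf[f_grid > 0]) + 0.5 * sum(pf[f_grid == 0])
    zsc[g] <- qnorm(min(max(p_pos, 1e-12), 1 - 1e-12))
  }

  out <- data.frame(gene = genes, mle_log2fc = mle, z_score = zsc,
                    adj_expr_target = adj_t, adj_expr_rest = adj_c,
                    p_value = 2 * pnorm(-abs(zsc)),
                    flag = flag, stringsAsFactors = FALSE)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  attr(out, "target_type") <- target_type
  attr(out, "n_target") <- length(t_cells)
  attr(out, "n_rest") <- length(c_cells)
  attr(out, "grid") <- c(max = grid_max, step = grid_step)
  attr(out, "models") <- models
  if (return_curves) attr(out, "curves") <- curves
  class(out) <- c("de_result", "data.frame")
  out
}

#' Select type-enriched genes
#'
#' Applies the joint fold-change / confidence rule: a gene is
#' up-enriched when `mle_log2fc >= mle_threshold` and `z_score >=
#' z_threshold`, down-enriched when both fall at or below the negated
#' thresholds. Both comparisons are inclusive.
#'
#' @param de a [de_test()] result.
#' @param mle_threshold minimum |MLE log2 fold change| (default 2).
#' @param z_threshold minimum |Z-score| (default 2).
#' @return list with character vectors `up` and `down`.
#' @export
enriched_genes <- function(de, mle_threshold = 2, z_threshold = 2) {
  stopifnot(mle_threshold > 0, z_threshold > 0)
  list(
    up = de$gene[de$mle_log2fc >= mle_threshold & de$z_score >= z_threshold],
    down = de$gene[de$mle_log2fc <= -mle_threshold & de$z_score <= -z_threshold]
  )
}

#' Top-N table of type-enriched genes
#'
#' Ranks the up-enriched genes by Z-score (descending), breaking ties by
#' |MLE log2 fold change| (descending) then gene name, and truncates to
#' `n` rows — the table behind a top-50 marker heatmap. The matrix of
#' adjusted expressions is attached as attribute `heatmap`.
#'
#' @param de a [de_test()] result.
#' @param n table size (default 50).
#' @param mle_threshold,z_threshold enrichment rule thresholds.
#' @return data.frame of at most `n` rows, attribute `n_enriched` giving
#'   the enriched count before truncation.
#' @export
top_n_table <- function(de, n = 50, mle_threshold = 2, z_threshold = 2) {
  up <- de[de$mle_log2fc >= mle_threshold & de$z_score >= z_threshold, ,
           drop = FALSE]
  ord <- order(-up$z_score, -abs(up$mle_log2fc), up$gene)
  up <- up[ord, , drop = FALSE]
  n_enriched <- nrow(up)
  out <- utils::head(up, n)
  rownames(out) <- NULL
  attr(out, "n_enriched") <- n_enriched
  attr(out, "heatmap") <- as.matrix(
    `rownames<-`(out[, c("adj_expr_target", "adj_expr_rest")], out$gene))
  out
}

#' Time-course of a gene's representative expression in one type
#'
#' Extracts the model-based adjusted expression (RPM scale) of a gene in
#' the target type from per-stage DE tables — the trajectory of a
#' type-enriched gene across development. Missing stages are flagged,
#' never interpolated; a gene absent from a stage's table reports 0 with
#' flag `"absent"`.
#'
#' @param de_by_stage named list of [de_test()] results, one per stage
#'   (an `NULL` element marks a stage without a table).
#' @param gene gene identifier.
#' @return data.frame with columns `stage`, `adj_expr`, `flag`.
#' @export
timecourse_expression <- function(de_by_stage, gene) {
  stopifnot(length(de_by_stage) > 0, !is.null(names(de_by_stage)))
  rows <- lapply(names(de_by_stage), function(st) {
    de <- de_by_stage[[st]]
    if (is.null(de)) {
      return(data.frame(stage = st, adj_expr = NA_real_, flag = "missing_stage",
                        stringsAsFactors = FALSE))
    }
    i <- match(gene, de$gene)
    if (is.na(i)) {
      return(data.frame(stage = st, adj_expr = 0, flag = "absent",
                        stringsAsFactors = FALSE))
    }
    data.frame(stage = st, adj_expr = de$adj_expr_target[i],
               flag = if (de$flag[i] == "") "ok" else de$flag[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
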