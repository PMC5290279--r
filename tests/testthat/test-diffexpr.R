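test_that("error model recovers dispersion within 20% and corrects means", {
  p <- synthetic_params(n_genes = 2000, cells_per_type_per_stage = 100,
                        n_types = 1, n_stages = 1, stage_labels = "S",
                        markers_per_type = 0, dispersion = 1, seed = 9)
  sim <- generate_counts(p)
  em <- fit_error_model(sim$counts, colnames(sim$counts))
  expect_lt(abs(em$theta - p$dispersion) / p$dispersion, 0.2)
  # fitted dropout decreases with expression and is near 0.5 at midpoint
  pi_vals <- dropout_probability(em, c(1, 10, 100))
  expect_true(all(diff(pi_vals) < 0))
  expect_lt(abs(pi_vals[2] - 0.5), 0.15)
})

test_that("zero-free data drive the dropout probability to zero", {
  set.seed(2)
  y <- matrix(rpois(200 * 20, 50) + 1L, 200, 20,
              dimnames = list(paste0("g", 1:200), paste0("c", 1:20)))
  em <- fit_error_model(y, colnames(y))
  expect_lt(dropout_probability(em, 50), 1e-6)
})

test_that("a constant gene's corrected mean is that constant", {
  set.seed(3)
  y <- matrix(rpois(100 * 30, 60) + 1L, 100, 30,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:30)))
  y <- rbind(y, konst = 7L)
  em <- fit_error_model(y, colnames(y))
  expect_equal(unname(em$mu["konst"]), 7, tolerance = 1e-6)
})

test_that("error model preconditions are enforced", {
  y <- matrix(1L, 10, 10, dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  expect_error(fit_error_model(y, colnames(y)[1:3]), "at least 5")
  y0 <- matrix(0L, 10, 10, dimnames = dimnames(y))
  expect_error(fit_error_model(y0, colnames(y0)), "degenerate")
})

de_fixture <- function(seed = 42, n_genes = 300, markers = 20, cells = 15) {
  sim <- small_sim(seed = seed, n_genes = n_genes, markers_per_type = markers,
                   cells_per_type_per_stage = cells, n_stages = 1,
                   stage_labels = "P2")
  list(counts = sim$counts, type = sim$truth$type, markers = sim$truth$markers)
}

test_that("planted markers are detected; absent genes are flagged", {
  fx <- de_fixture()
  counts <- rbind(fx$counts,
                  allzero = integer(ncol(fx$counts)))
  de <- de_test(counts, fx$type, "type1")
  expect_equal(de$mle_log2fc[de$gene == "allzero"], 0)
  expect_equal(de$z_score[de$gene == "allzero"], 0)
  expect_equal(de$flag[de$gene == "allzero"], "uninformative")

  en <- enriched_genes(de)
  expect_gte(mean(fx$markers$type1 %in% en$up), 0.8)
  # markers of other types are depleted in type1, never up-enriched
  expect_length(intersect(en$up, c(fx$markers$type2, fx$markers$type3)), 0)
  # finite z, sign agreement with the fold estimate where it matters
  expect_true(all(is.finite(de$z_score)))
  strong <- abs(de$z_score) >= 0.5
  expect_true(all(sign(de$z_score[strong]) == sign(de$mle_log2fc[strong])))
})

test_that("swapping target and complement negates fold and confidence", {
  fx <- de_fixture(seed = 8)
  two <- ifelse(fx$type == "type1", "A", "B")
  names(two) <- names(fx$type)
  de_a <- de_test(fx$counts, two, "A")
  de_b <- de_test(fx$counts, two, "B")
  expect_equal(de_a$mle_log2fc, -de_b$mle_log2fc)
  expect_equal(de_a$z_score, -de_b$z_score, tolerance = 1e-3)
})

test_that("a label permutation of one population yields a quiet table", {
  sim <- null_sim(seed = 5, n_cells = 90, n_genes = 500)
  set.seed(3)
  lab <- setNames(sample(rep(c("A", "B"), c(30, 60))), colnames(sim$counts))
  de <- de_test(sim$counts, lab, "A")
  en <- enriched_genes(de)
  expect_lte((length(en$up) + length(en$down)) / nrow(de), 0.03)
  expect_lte(median(abs(de$mle_log2fc)), 0.5)
})

test_that("doubling one group's means shifts the fold estimate accordingly", {
  set.seed(14)
  n_genes <- 200
  mu <- exp(runif(n_genes, log(5), log(200)))
  mk <- function(m, n) matrix(rnbinom(n_genes * n, size = 2, mu = m), n_genes, n)
  counts <- cbind(mk(mu, 40), mk(mu * 2^2, 40))
  dimnames(counts) <- list(sprintf("g%03d", 1:n_genes), sprintf("c%03d", 1:80))
  lab <- setNames(rep(c("lo", "hi"), each = 40), colnames(counts))
  de <- de_test(counts, lab, "hi")
  expect_equal(median(de$mle_log2fc), 2, tolerance = 0.3)
})

test_that("de_test requires adequately sized groups", {
  fx <- de_fixture()
  tiny <- fx$type
  tiny[] <- "rest"; tiny[1:3] <- "few"
  expect_error(de_test(fx$counts, tiny, "few"), "at least 5")
})

test_that("enrichment thresholds are inclusive and sign-paired", {
  de <- data.frame(
    gene = c("border", "lowz", "down", "null"),
    mle_log2fc = c(2.0, 3.0, -2.5, 0.1),
    z_score = c(2.0, 1.5, -2.1, 0.2),
    stringsAsFactors = FALSE
  )
  en <- enriched_genes(de)
  expect_equal(en$up, "border")
  expect_equal(en$down, "down")
  empty <- enriched_genes(de[0, ])
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("top-N tables rank by z with deterministic tie-breaking", {
  de <- data.frame(
    gene = sprintf("g%02d", 1:60),
    mle_log2fc = 3,
    z_score = 5,
    adj_expr_target = 100, adj_expr_rest = 10,
    stringsAsFactors = FALSE
  )
  de$z_score <- c(rep(5, 58), 9, 9)
  de$mle_log2fc[59:60] <- c(4, 8)
  top <- top_n_table(de, n = 50)
  expect_equal(nrow(top), 50)
  expect_equal(attr(top, "n_enriched"), 60)
  # the two z = 9 genes lead, larger |mle| first
  expect_equal(top$gene[1:2], c("g60", "g59"))
  # among equal z and mle, name order decides
  expect_equal(top$gene[3:5], c("g01", "g02", "g03"))
  expect_equal(rownames(attr(top, "heatmap")), top$gene)
})

test_that("time-course extraction reports gaps and absences, never interpolates", {
  mk_de <- function(val) data.frame(gene = "Pax6", mle_log2fc = 2, z_score = 3,
                                    adj_expr_target = val, adj_expr_rest = 1,
                                    flag = "", stringsAsFactors = FALSE)
  tc <- timecourse_expression(list(E18 = mk_de(5), P2 = mk_de(9), P5 = mk_de(12)),
                              "Pax6")
  expect_equal(tc$adj_expr, c(5, 9, 12))
  expect_true(all(tc$flag == "ok"))

  gap <- timecourse_expression(list(E18 = mk_de(5), P2 = NULL, P5 = mk_de(12)),
                               "Pax6")
  expect_true(is.na(gap$adj_expr[2]))
  expect_equal(gap$flag[2], "missing_stage")

  absent <- timecourse_expression(list(E18 = mk_de(5)), "Foxg1")
  expect_equal(absent$adj_expr, 0)
  expect_equal(absent$flag, "absent")
})

test_that("adjusted expressions track the stage profile of a planted shift", {
  # three stages simulated with a global upward shift on a subset of genes
  p <- synthetic_params(n_genes = 150, cells_per_type_per_stage = 20,
                        n_types = 2, markers_per_type = 15,
                        stage_shift_fraction = 0.3, stage_shift_log2fc = 1.5,
                        seed = 77)
  sim <- generate_counts(p)
  shifted <- rownames(sim$counts)[apply(sim$truth$true_log2fc == 0, 1, all)]
  de_by_stage <- lapply(setNames(p$stage_labels, p$stage_labels), function(st) {
    cells <- sim$cells$cell_id[sim$cells$stage == st]
    de_test(sim$counts[, cells], sim$truth$type[cells], "type1")
  })
  mk <- sim$truth$markers$type1[1]
  tc <- timecourse_expression(de_by_stage, mk)
  expect_equal(nrow(tc), 3)
  expect_true(all(tc$flag == "ok"))
  expect_true(all(tc$adj_expr > 0))
})
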