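test_that("fixed seed gives bit-identical data with self-consistent metadata", {
  a <- small_sim(seed = 7, qc_fail_fraction = 0.1)
  b <- small_sim(seed = 7, qc_fail_fraction = 0.1)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)

  expect_true(all(a$counts >= 0))
  expect_true(is.integer(a$counts))
  expect_equal(unname(colSums(a$counts)), a$cells$mapped_reads)

  mk <- a$truth$markers
  expect_equal(anyDuplicated(unlist(mk)), 0)
  # non-markers carry zero true fold change
  nonmark <- setdiff(rownames(a$counts), unlist(mk))
  expect_true(all(a$truth$true_log2fc[nonmark, ] == 0))
})

test_that("without planted signal, per-gene means do not differ by type", {
  sim <- small_sim(seed = 3, marker_log2fc = 0, n_genes = 200,
                   cells_per_type_per_stage = 60, n_stages = 1,
                   stage_labels = "P2")
  type <- sim$truth$type
  t1 <- names(type)[type == "type1"]; t2 <- names(type)[type == "type2"]
  m1 <- rowMeans(sim$counts[, t1]); m2 <- rowMeans(sim$counts[, t2])
  se <- sqrt(apply(sim$counts[, t1], 1, var) / length(t1) +
             apply(sim$counts[, t2], 1, var) / length(t2))
  z <- abs(m1 - m2) / pmax(se, 1e-12)
  # 3-sigma criterion per gene; allow the expected few Gaussian outliers
  expect_gt(mean(z < 3), 0.97)
})

test_that("flat dropout at the median matches brute-force Bernoulli masking", {
  p <- synthetic_params(n_genes = 2000, cells_per_type_per_stage = 200,
                        n_types = 1, n_stages = 1, stage_labels = "S",
                        markers_per_type = 0, dropout_slope = 0, seed = 5)
  sim <- generate_counts(p)
  observed_zero <- mean(sim$counts == 0)

  # oracle: same NB mean distribution, dropout replaced by an independent
  # fair-coin mask
  set.seed(123)
  mu <- exp(runif(2000, p$baseline_mean_log_range[1], p$baseline_mean_log_range[2]))
  y <- matrix(rnbinom(2000 * 200, size = p$dispersion, mu = mu), 2000, 200)
  y[matrix(rbinom(2000 * 200, 1, 0.5), 2000, 200) == 1] <- 0L
  oracle_zero <- mean(y == 0)
  expect_lt(abs(observed_zero - oracle_zero), 0.01)
})

test_that("planted QC failures hit the requested count, one criterion each", {
  sim <- generate_counts(synthetic_params(
    n_genes = 50, cells_per_type_per_stage = 100, n_types = 1, n_stages = 1,
    stage_labels = "P2", markers_per_type = 0, qc_fail_fraction = 0.1, seed = 2))
  expect_equal(sum(sim$truth$qc_should_fail), 10)
  rep <- apply_qc(sim$cells, sim$counts)
  failing <- rep[!rep$pass, ]
  expect_equal(sort(failing$cell_id),
               sort(names(which(sim$truth$qc_should_fail))))
  # each planted failure violates exactly the named criterion
  planted <- sim$truth$qc_fail_criterion[failing$cell_id]
  expect_equal(unname(failing$failed_criteria), unname(planted))
})

test_that("parameter validation rejects malformed settings", {
  expect_error(synthetic_params(n_genes = -5), "n_genes")
  expect_error(synthetic_params(n_genes = 10.5), "n_genes")
  expect_error(synthetic_params(qc_fail_fraction = 1.2), "qc_fail_fraction")
  expect_error(synthetic_params(n_types = 0), "n_types")
  expect_error(synthetic_params(dispersion = 0), "dispersion")
  expect_error(synthetic_params(n_genes = 10, markers_per_type = 10, n_types = 3),
               "marker sets")
  expect_error(track_params(n_steps = 1), "n_steps")
  expect_error(track_params(dt = 0), "dt")
})

test_that("reference tables control the planted overlap exactly", {
  q <- sprintf("Q%02d", 1:40)

  none <- generate_reference_de(300, q, 0, seed = 1)
  expect_length(intersect(toupper(none$gene), toupper(q)), 0)

  all_in <- generate_reference_de(300, q, 40, shared_z = 5, seed = 1)
  cur <- shared_enrichment_curve(q, all_in, "Reln-like", z_max = 4)
  expect_true(all(cur$shared_percent == 100))

  # half the shared genes below the threshold, half above: exactly 50%
  half <- generate_reference_de(300, q, 40, shared_z = rep(c(1, 3), 20), seed = 1)
  cur2 <- shared_enrichment_curve(q, half, "Reln-like", z_max = 2)
  expect_equal(cur2$shared_percent[cur2$z == 2], 50)

  expect_error(generate_reference_de(300, q, 41), "n_shared")
})

test_that("track generator obeys its limiting regimes", {
  # near-infinite turning concentration: straight lines
  straight <- generate_tracks(track_params(n_tracks = 10, n_steps = 20,
                                           turning_concentration = 1e9, seed = 1))
  met <- tracks_metrics(straight, burn_in_min = 0)
  expect_true(all(met$persistence > 0.999))

  # zero step length: zero speed
  still <- generate_tracks(track_params(n_tracks = 5, n_steps = 10,
                                        step_length_mean = 0, seed = 1))
  met0 <- tracks_metrics(still, burn_in_min = 0)
  expect_true(all(met0$speed == 0))
  expect_true(all(met0$stationary))

  # isotropic turning: mean persistence matches the Monte-Carlo oracle
  iso <- generate_tracks(track_params(n_tracks = 300, n_steps = 20,
                                      turning_concentration = 0, seed = 4))
  met_iso <- tracks_metrics(iso, burn_in_min = 0)
  oracle <- isotropic_persistence_oracle(n_steps = 20)
  expect_lt(abs(mean(met_iso$persistence) - oracle), 0.02)
})

test_that("grouped tracks carry group labels and parameter overrides", {
  tr <- generate_tracks(track_params(n_tracks = 5, n_steps = 12, seed = 3),
                        groups = list(PSB = list(turning_concentration = 1e9),
                                      CGE = list(turning_concentration = 0)))
  expect_setequal(unique(tr$group), c("PSB", "CGE"))
  met <- tracks_metrics(tr, burn_in_min = 0)
  expect_true(all(met$persistence[met$group == "PSB"] > 0.999))
  expect_true(mean(met$persistence[met$group == "CGE"]) < 0.9)
})
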