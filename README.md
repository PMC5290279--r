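# scintype

Consensus typing, type-enriched gene discovery and migration metrics for
developing Htr3a-GFP+ cortical interneurons profiled by full-length
single-cell RNA-seq.

Caudal ganglionic eminence-derived cortical interneurons are
transcriptionally diverse, and that diversity emerges across late embryonic
and early postnatal development (E18, P2, P5). `scintype` implements the
complete typing workflow for such data as tested, reusable R functions:

* **Quality control** — a cell is kept iff read-pairs ≥ 5×10⁶, mapped
  fraction > 0.80, mitochondrial fraction < 0.05, eGFP reads ≥ 1, and at
  least one interneuron marker (*Dlx1/2/5/6*, *Gad1/2*) has ≥ 10 raw reads.
* **Normalization & selection** — RPM = count · 10⁶ / mapped reads; genes
  kept when expressed above 10 RPM in more than 5% of cells (both strict).
* **Consensus clustering** — PCA (top 10 components of log₂(RPM+1)) +
  Ward hierarchical clustering, repeated 100× on random 80% subsamples;
  the stability score *s(i,j)* is the proportion of co-sampled runs in
  which cells *i, j* co-cluster; the final assignment cuts the average-
  linkage tree of 1 − *s* at *k* (default 3). `suggest_k()` advises on *k*
  and flags structureless data via the proportion of ambiguous clustering.
* **Embeddings** — seeded, order-canonical t-SNE (perplexity 30 across
  stages; 4 for within-type subtype parcellation, followed by average-
  linkage clustering in the embedding plane).
* **Dropout-aware differential expression** — per-group zero-inflated
  negative binomial model (dropout probability logistic in log mean);
  each group's expression posterior is aggregated over 150 bootstrap
  resamples of cells under an empirical magnitude prior, and the fold-
  change distribution is the cross-correlation of the two. Reported per
  gene: MLE log₂ fold change (grid argmax on [−10, 10], step 0.05), a
  Z-score (signed normal quantile of the mass above zero), and adjusted
  expressions (posterior means, RPM scale). Type-enriched genes satisfy
  MLE ≥ 2 and Z ≥ 2 (or both ≤ −2), inclusively.
* **Cross-dataset comparison** — percentage of a query type's enriched
  genes shared with reference subtype families (*Reln*-like, *Vip*-like)
  at incremental Z thresholds (step 0.1).
* **Migration metrics** — after discarding the first 60 min of each
  time-lapse track (frames every 10 min): speed = path length / duration
  (µm/h) and directional persistence = net displacement / path length,
  compared between graft groups by unpaired Student's t-test.
* **Synthetic data** — a first-class generator of count matrices with
  planted types/markers/dropout and QC failures, reference DE tables with
  controlled overlap, and correlated-random-walk migration tracks, so the
  whole pipeline is testable with known ground truth.

## Worked example

```r
library(scintype)

sim <- generate_counts(synthetic_params(qc_fail_fraction = 0.1, seed = 42))
qc  <- apply_qc(sim$cells, sim$counts)
unlist(attr(qc, "summary"))
#> E18  P2  P5
#>  65  67  71

keep <- qc$cell_id[qc$pass & qc$stage == "P2"]
rpm  <- to_rpm(sim$counts[, keep],
               sim$cells$mapped_reads[match(keep, sim$cells$cell_id)])
expr <- rpm[select_genes(rpm), ]          # 1695 genes x 67 cells

sm <- stability_matrix(expr, clustering_params(k = 3, seed = 7))
suggest_k(sm)                             # 3 (PAC 0.112: strong structure)
ca <- consensus_assign(sm, 3)
table(ca$labels, sim$truth$type[names(ca$labels)])
#>     type1 type2 type3
#>   1    20     0     0
#>   2     0    25     0
#>   3     0     0    22

de  <- de_test(sim$counts[, keep], ca$labels, 1)
top_n_table(de, n = 5)[, c("gene", "mle_log2fc", "z_score")]
#>       gene mle_log2fc z_score
#> 1 Gene0205       3.70    7.03
#> 2 Gene0383       3.55    7.03
#> 3 Gene0504       3.55    7.03
#> 4 Gene0963       3.50    7.03
#> 5 Gene0688       3.45    7.03
```

The 10% of cells planted to fail QC are exactly the ones rejected; the
three planted types at P2 are recovered without error; and the top
type-1-enriched genes are all planted type-1 markers (true log₂ fold
change 3, estimated ≈ 3.5 after dropout correction on 67 cells).

For migration:

```r
tracks <- generate_tracks(track_params(n_tracks = 50, seed = 1),
                          groups = list(PSB = list(turning_concentration = 5),
                                        CGE = list(turning_concentration = 0.5)))
met <- tracks_metrics(tracks, burn_in_min = 60)
compare_groups(met[met$group == "PSB", ], met[met$group == "CGE", ])
```

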