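---
title: "Consensus typing of developing cortical interneurons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus typing of developing cortical interneurons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scintype)
```

# The problem

Caudal ganglionic eminence (CGE)-derived cortical interneurons labeled by an
Htr3a-GFP reporter are transcriptionally heterogeneous, and their diversity
unfolds across late embryonic and early postnatal development (E18, P2, P5).
`scintype` packages, as reusable and tested functions, the computational
workflow for typing such cells from full-length single-cell RNA-seq:

1. per-cell quality control on five criteria,
2. reads-per-million (RPM) normalization and expressed-gene selection,
3. PCA + hierarchical clustering with a resampling co-clustering stability
   score and a consensus assignment into robust cell types,
4. t-SNE embeddings for cross-stage visualization and within-type subtype
   parcellation,
5. dropout-aware differential expression producing MLE log2 fold changes and
   Z-scores, with a threshold rule for type-enriched genes,
6. shared-enrichment comparison of a type's enriched genes against reference
   subtype tables over incremental Z thresholds, and
7. migration speed and directional persistence from time-lapse tracks of
   grafted cells, with a two-group comparison.

Every stage is exercisable end-to-end on synthetic data with known ground
truth; the generator is itself part of the package's tested surface.

# Quality control

A cell is retained iff it satisfies all of: at least 5 million sequenced
read-pairs; more than 80% of read-pairs mapped; less than 5% of reads on the
mitochondrial chromosome; at least one eGFP-aligned read; and at least ten raw
reads on at least one canonical interneuron marker (Dlx1, Dlx2, Dlx5, Dlx6,
Gad1, Gad2). Inequality strictness follows the wording literally: "at least"
is inclusive, "more than" and "less than" are strict, so a cell at exactly
4,999,999 read-pairs or exactly 5% mitochondrial reads fails. The marker-read
criterion is evaluated on raw counts because QC precedes normalization.

# Normalization and gene selection

RPM is `count * 1e6 / mapped_reads`, with `mapped_reads` the reads aligned to
expressed genes (so each cell's RPM values sum to one million under the
package's default). Clustering input is restricted to genes expressed above
10 RPM in more than 5% of cells — both inequalities strict, which the
boundary-case unit tests pin down. Selection is computed per analysis subset
(per stage for within-stage clustering; pooled for the cross-stage
embedding). Downstream clustering operates on `log2(RPM + 1)`; log
stabilization is the standard choice for expression distances and is exposed
as the `log_transform` flag.

# Consensus clustering

Cells are projected onto the top `n_components` principal components
(default 10; genes centered, not variance-scaled — both choices exposed) and
agglomerated with Ward linkage (`ward.D2`, the Ward criterion for raw
Euclidean distances) before cutting at `k`. Robustness is assessed by
repeating the whole procedure (PCA included) on `n_runs = 100` random
subsamples of 80% of the cells drawn without replacement, and scoring each
cell pair by the proportion of runs in which both were drawn *and*
co-assigned. The denominator is the number of runs in which the pair was
co-sampled — the co-clustering proportion is only observable then — and
never-co-sampled pairs are flagged `NA`, not zeroed. The consensus
assignment hierarchically clusters `1 - s` (average linkage) and cuts at
`k`; its leaf order is the heatmap display order. The default `k = 3`
reflects the three robust interneuron types this workflow was built around.

`suggest_k` is advisory: it maximizes the mean silhouette of the consensus
tree cut over `k = 2..k_max`. Because a silhouette computed on the consensus
matrix itself is self-referential (forced cluster boundaries look crisp even
on noise — the well-known consensus-clustering overfitting artifact),
absence of structure is flagged by the proportion of ambiguous clustering
(PAC): the fraction of pair scores strictly between 0.1 and 0.9. On
structureless data most pair scores are intermediate (PAC above 0.95 in our
null simulations) while planted-type data concentrate near 0 and 1 (PAC
below 0.15); the flag threshold 0.5 — "more ambiguous than not" — sits far
from both regimes.

Tie-breaking in agglomeration follows `hclust`'s deterministic ordering, so
identical inputs give identical trees.

# Embeddings

The cross-stage map uses t-SNE at the conventional perplexity 30; subtype
parcellation within one main type uses perplexity 4 and then agglomerates
(Euclidean, average linkage) in the 2-D embedding space. "Spectral"-style
determinism is obtained by initializing t-SNE from the first two principal
components scaled to a small norm; together with an internal canonical cell
order this makes coordinates reproducible under a fixed seed and invariant
to input column permutations. The subtype tree is cut at an explicit
`k_sub` (the original workflow cut its tree manually by inspection; an
explicit parameter plus the `suggest_k` heuristic replaces that
irreproducible step).

# Dropout-aware differential expression

The observation model per group is zero-inflated negative binomial: with
probability `pi(mu)` a transcript drops out (observed 0), otherwise the
count is NB with mean `mu` and size `theta`. `pi` is logistic in `log mu` —
poorly expressed genes drop out more — with parameters `(a0, a1)` fitted per
group from the excess of observed zeros over what the NB alone predicts,
on genes binned by expression. `theta` is a method-of-moments estimate on
nonzero counts whose moment equations are corrected for the truncation at
zero (the naive nonzero-count MoM overestimates `theta` substantially);
the median across genes is used.

For a target type versus all remaining cells, each group's expression
distribution over a log2-mean grid (step 0.05) is the aggregate of the
group's ZINB likelihood across 150 bootstrap resamples of its cells,
multiplied by an empirical prior over expression magnitude (kernel density
of the genes' dropout-corrected means, mixed 9:1 with a uniform floor).
Both ingredients matter for calibration:

* the bootstrap aggregation propagates cell-level heterogeneity that a
  single product likelihood understates;
* the magnitude prior anchors the posterior of a group in which a gene went
  undetected at plausible low expression, instead of letting the fold
  estimate run to the grid boundary with spurious confidence.

The fold-change distribution is the discrete cross-correlation of the two
group curves, so swapping target and complement mirrors it exactly: the MLE
(grid argmax, ties resolved toward 0, restricted to log2 fold changes in
[-10, 10]) and Z negate under group exchange. The Z-score is the signed
standard-normal quantile of the distribution's mass above zero — the
confidence of over- or under-expression expressed on the z scale, as a
classical p-value would be. Under label permutations of a homogeneous
population, the joint rule "MLE >= 2 and Z >= 2 (or both <= -2)" passes
about 0.2% of genes in our simulations, while planted log2 fold change 3
markers at 30-versus-60 cells are detected with ~99% power.

Enrichment thresholds are inclusive (`MLE >= 2`, `Z >= 2`, both in log2 /
z units). Top-N tables rank up-enriched genes by Z descending, ties by
|MLE| then gene name. No multiple-testing correction enters the selection
rule; a BH-adjusted column is emitted for convenience only. Adjusted
expressions are per-group posterior means on the RPM scale, and the
time-course helper extracts them per stage for one gene and type, flagging
(never interpolating) missing stages.

# Cross-dataset shared enrichment

Given a query type's enriched gene set and a reference table of
(gene, Z, subtype family), the shared-enrichment curve reports, for each
threshold on an incremental grid (start 2.0, step 0.1),
`100 * |query ∩ {family genes with Z >= z}| / |query|`. The denominator is
the fixed query set, which makes curves comparable across families (the
alternative intersection-over-union reading of "percentage of shared
enriched genes" is noted but not the default). Symbols are harmonized by
case-insensitive exact match; unmatched query symbols are reported, never
silently dropped. The reference set shrinks with the threshold, so the
curve is non-increasing by construction.

# Migration metrics

Tracks are time-stamped 2-D positions sampled every 10 minutes. The first
60 minutes are removed (settling of the slice in the chamber) and times
re-zeroed; gaps of at most two missing frames are bridged linearly, longer
gaps are an error. Speed is total path length divided by the track's
observed duration after burn-in (micrometers per hour); directional
persistence is net displacement over path length, in [0, 1]. The group
comparison reports means with standard errors and a two-sided unpaired
Student's t-test, pooled-variance by default (Welch available by flag).

# The synthetic-data generator

The generator emulates the study design: `n_types = 3` planted types at
`n_stages = 3` stages (E18/P2/P5), 25 cells per type per stage, 2,000 genes
with 50 disjoint markers per type at log2 fold change 3. Counts are NB with
gene means drawn log-uniform between 0.5 and 100 counts (size
`dispersion = 1`), markers between 10 and 100 (real type markers are
decently expressed); dropout is Bernoulli masking with probability logistic
in the log NB mean, 50% at 10 counts, slope 1. These magnitudes are
conventional choices, not values fitted to the study's data (which reports
none); they produce zero fractions and on/off marker patterns typical of
microfluidic full-length single-cell libraries. Sequenced read-pair totals
are log-normal around the nominal depth of 10 million; `mapped_reads` is
defined as the column sum of the count matrix, making RPM totals exactly
one million. A requested fraction of cells violates exactly one named QC
criterion each. Migration tracks are correlated random walks (Gaussian
turning with variance `1/turning_concentration`, Gamma step lengths, 10-min
frames); higher concentration gives straighter walks.

What the generator does *not* emulate: gene-gene correlation structure,
batch/chip effects, library-size-dependent detection differences between
cells, continuous (non-discrete) lineage variation, and UMI or read-level
noise. Passing tests on these simulations therefore demonstrates the
correctness and calibration of the algorithms under the stated model, not
robustness to every artifact of real data.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the pipeline at the study's
design scale (2,000 genes, 75 cells per stage; 20-seed null batteries at
500–1,000 genes; 50 power simulations at 150 genes and 30-versus-60 cells;
20-seed migration power at 50 tracks per group) — sizes chosen to estimate
rates with useful precision while keeping a full run in minutes on one
core. Fold grids span [-10, 10] log2 units at step 0.05; the expression
grid extends to the data maximum plus two log2 units. Degenerate inputs
(all-zero genes, zero mapped reads, perfectly co-clustering cells,
stationary tracks, never-co-sampled pairs) are flagged or raised as named
errors rather than silently coerced.

# Known limitations

* The DE module emulates the *decision rule and output contract* of
  dropout-aware single-cell DE (MLE fold change, Z, adjusted expression);
  it does not reproduce any external tool's exact numbers.
* Consensus clustering assumes a meaningful discrete partition; gradual
  continua will be split arbitrarily (the PAC flag offers partial
  protection).
* The per-group error model is shared across cells; chips or batches with
  heterogeneous capture efficiency violate this.
* Shared-enrichment comparison takes reference DE tables as inputs; it does
  not reprocess external datasets.
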