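---
title: "Methods: models, parameters and design choices in ilcmirror"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ilcmirror}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ilcmirror` compares the transcriptomes of six sorted human lymphocyte
subsets — three circulating innate lymphoid cell populations (ILC1, ILC2 and
the c-Kit+ CRTH2− precursor ILCP) and their adaptive "mirror" CD4 T helper
subsets (Th1, Th2, Th17) — from a gene-level read-count matrix. This
vignette documents the statistical machinery, its assumptions, the defaults
and why they were chosen, and the design decisions taken where the problem
left the design genuinely open.

## Count model and normalization

Counts are modelled as negative binomial, `Var = μ + φμ²`. Genes expressed
below 1 count per million (cpm, computed on raw library sizes) in every
sample are removed before anything else; the filter is boundary-inclusive
(`cpm ≥ min_cpm` in `≥ min_samples` samples, defaults 1 and 1) and is
applied *before* the scaling factors are computed, so the factors are not
driven by the all-zero tail.

Between-sample composition bias is corrected with TMM scaling factors
(trimmed mean of gene-wise log2 abundance ratios against a reference sample,
30% trim on M-values, 5% on A-values, inverse delta-method variance
weights, factors rescaled to geometric mean 1). `tmm_factors()` delegates to
the edgeR implementation of the method; the test suite checks it against an
independently coded step-by-step reference at 1e-6.

Expression is analysed on the log2-cpm scale,
`log2((count + 0.5) / (lib × factor + 1) × 1e6)`; the pseudo-count keeps
zeros finite and caps the scale-invariance of the transform (doubling all
counts and library sizes changes log-cpm appreciably only where counts are
comparable to 0.5). Each observation receives a voom precision weight: the
sqrt residual standard deviation from an initial gene-wise fit is smoothed
against mean log-count by lowess (span 0.5) and the predicted standard
deviation enters as `w = sd^-4`. Weights are computed once, under the full
six-group design, and reused for every contrast — the alternative
(re-estimating the trend per comparison) re-fits the same trend on subsets
of the same samples and makes contrasts incomparable across comparisons.

## Differential expression

Designs are group-means parameterizations (one indicator column per subset,
or per lineage for the total-ILC vs total-Th comparison); contrasts such as
`ILC2 − Th2` are tested per gene with the empirical-Bayes moderated t:
residual variances `s²_g` (residual df `d_g`) are shrunk toward a prior
`(d0, s0²)` estimated by moment matching on the log variances,
`s̃²_g = (d0·s0² + d_g·s²_g)/(d0 + d_g)`, and the t-statistic gains `d0`
degrees of freedom. Two numerical conventions: an infinite prior-df estimate
is capped at 1e7 (and `prior_df = Inf` is honoured exactly as the fully
pooled statistic), and the unscaled contrast variance is computed as
`Σ c_j² u²_gj`, which is exact for group-means designs because their
disjoint indicator columns keep `X'WX` diagonal under any weights.
`prior_df = 0` reproduces the ordinary t exactly, which the tests exploit
against a per-gene weighted least-squares oracle.

Two open points were resolved as follows. Donors are not modelled as a
blocking factor: the generator's donor effects are small (0.1 on log2) and a
donor term would cost a third of the residual degrees of freedom at n = 3;
the unblocked fit is slightly conservative because donor variance inflates
the residual. The total-ILC vs total-Th comparison is fitted as its own
two-group model on the same normalized matrix rather than as an averaged
contrast of the six-group fit, so its residual variance is estimated at the
lineage level, matching how a two-population comparison would normally be
run.

Multiple testing uses Benjamini–Hochberg throughout (`bh_adjust()` is a
validated wrapper over the standard step-up implementation). Sub-tables —
e.g. the lncRNA tables selected by annotation biotype — keep the
genome-wide adjusted p-values rather than re-adjusting within the subset,
because the long-noncoding analysis is a read-out of the global DE tables,
not a separate family of tests.

## Gene-set enrichment

The enrichment procedure is implemented from scratch. Genes are ranked by
decreasing moderated t (ties broken lexicographically by gene id so the
ranking is reproducible). For a set S of size `N_S` in a universe of `N`,
the running sum adds `|t_i|^P / Σ_S |t|^P` at members and subtracts
`1/(N − N_S)` at non-members; `ES_up` is the maximum of the walk and
`ES_down` the minimum (the endpoints pin both to `[0, 1]` and `[-1, 0]`).
The default weight exponent is `P = 1`. The implementation evaluates the
walk in closed form at the member positions (the sum is piecewise linear
between hits, so the extrema occur at hits or just before them); the test
suite proves exact equivalence with the exhaustive walk on all subsets of
all short lists.

The null distribution redraws the member *labels*: `n_permutations`
(default 1000) uniform draws of `N_S` genes without replacement.
`NES = ES / mean(null ES)` and the p-value is the proportion of null scores
at least as extreme, both computed per direction — the up-score is compared
with null up-scores and the down-score with null down-scores, since the two
directions are scored separately. Three numerical choices:

- p-values use the add-one estimator `(1 + extreme)/(1 + n)` so a
  permutation p is never exactly zero; the raw proportion is available
  (`add_one = FALSE`) for literal replication.
- one null distribution is computed per set *size* and shared by all
  same-size sets in a run: under label permutation the null depends on the
  set only through its size, so this is exact by exchangeability and gives a
  large speed-up (disable with `shared_null = FALSE`).
- BH adjustment spans all (set, direction) tests of a run.

A consequence worth knowing: with 1000 permutations the smallest attainable
p is 1/1001, so in a family of `m` tests a set can only be BH-significant at
0.05 if at least ≈ m/50 tests sit at that floor. With the default 500-set
collection (1000 tests) and ~10 planted sets per comparison, planted sets
are detected at the permutation resolution but cannot clear the family-wise
adjustment; the acceptance script therefore reports both the raw-p detection
rate and the adjusted-p recovery rate.

## Signatures, spider matrices, clustering, PCA

The signature of subset S is the set of genes with adjusted p < 0.05 *and*
positive estimate in S-vs-T for **all five** T ≠ S. This conjunction makes
signatures provably disjoint (asserted at run time). The spider matrix entry
(signature, subset) is the mean log2 normalized cpm of the signature's genes
over the subset's samples; on planted data each row peaks at its own subset.
The significance-conjunction reading of "overexpressed in each subset
compared to all others" is one of two defensible readings (the other being
fold-change ranking); it uses the pipeline's global significance threshold
and is exposed through `alpha`.

Heatmap matrices are row z-scores with the sample (n−1) standard deviation;
constant rows map to 0 instead of NaN. Row order comes from complete-linkage
agglomeration on Euclidean distances (deterministic; ties resolve by row
index). PCA takes the `n_top = 500` most variable genes on the log-cpm
scale, centers genes without unit-scaling (variance-based selection argues
for keeping the variance structure; a `scale.` flag is provided), and
reports per-component and cumulative variance fractions plus squared-loading
contributions.

## The synthetic-data generator

`simulate_counts()` emulates the study design: 6 subsets × 3 donors (18
libraries), gene baselines log2-uniform over `[1, 9]` rescaled to an
expected library size of 2e6 reads, gene-wise dispersions
`φ ~ Gamma(shape 2, mean 0.1)` (mid-range for sorted-cell bulk RNA-seq),
log-normal library-size factors (sd 0.15 on the log scale), gene-by-donor
log2 effects of sd 0.1, and a `de_fraction = 0.15` of genes carrying a
planted effect of ±2 log2 units in one randomly chosen subset; 15% of genes
are labelled "lncRNA". The default de_fraction was set together with the
default enriched-set sizes (8–12 members at 90% purity) so that the
expected per-subset pool of planted up-genes (~25) always supports building
the enriched sets — a construction constraint, not a statistical one.
Desk-scale runs use 2000 genes; the generator scales to the ~20,000 genes a
real post-filter matrix would contain, at proportional cost.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: lineage-wide expression programs (effects are
subset-specific, so the total-ILC vs total-Th comparison sees only diluted
one-sixth effects and finds few genes at the defaults), correlated gene
modules, GC/length biases, sample outliers and batch structure beyond the
donor term, and any real annotation. Planted gene sets are random draws, not
curated pathways.

## Pipeline reproducibility and problem sizes

`run_pipeline()` fans a single seed out to the stage seeds by fixed offsets
(simulation +101, gene sets +202, GSEA +303), writes every intermediate
table with 15-significant-digit formatting, and records md5 hashes of all
outputs in `manifest.json`; two runs with the same configuration are
byte-identical (the only timestamped file, `run.log`, is excluded from the
manifest). The test suite and the acceptance script run the default
configuration — 2000 genes, 18 samples, 500 gene sets, 1000 permutations —
which completes in about a minute on one core; power, calibration and
false-discovery properties are checked over 10–20 simulation seeds at that
scale.

## Known limitations

- Donor pairing is ignored by design; with strongly donor-structured real
  data a blocking factor or duplicate-correlation approach would be needed.
- The contrast-variance shortcut assumes group-means designs; arbitrary
  design matrices would need the full unscaled covariance.
- Permutation resolution bounds adjusted GSEA significance (see above);
  raising `n_permutations` is the remedy when many sets are tested.
- Signature sizes depend strongly on power at n = 3 per subset: genes with
  low baseline expression rarely pass the all-five conjunction.
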