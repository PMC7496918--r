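# ilcmirror

Bulk RNA-seq comparison of human circulating innate lymphoid cell (ILC) and
CD4 T helper subsets, packaged as a reusable, fully testable pipeline.

Helper ILCs are often described as the innate "mirror" of CD4 Th cells —
ILC1 vs Th1, ILC2 vs Th2, and the circulating c-Kit+ CRTH2− ILC precursor
(ILCP) vs Th17. `ilcmirror` implements the complete computational route from
a gene-level count matrix (six sorted subsets × donors) to the analyses that
probe this mirror hypothesis:

- **Filtering and normalization** — genes kept at ≥ 1 count per million (cpm)
  in ≥ 1 sample; between-sample scaling factors by the trimmed mean of
  M-values (TMM); log2-cpm with voom precision weights
  `w = predicted_sd^-4` from the fitted mean–variance trend.
- **Differential expression** — gene-wise weighted linear models under a
  group-means design, empirical-Bayes moderated t-statistics
  `t_g = c'β̂_g / (s̃_g √(c'(X'WX)⁻¹c))` with
  `s̃²_g = (d0·s0² + d_g·s²_g)/(d0 + d_g)`, two-sided p-values on `d0 + d_g`
  degrees of freedom, Benjamini–Hochberg adjustment. Comparisons: total ILC
  vs total Th (2-group model) and all 15 subset pairs.
- **Gene-set enrichment** — a weighted running-sum score over the ranked
  moderated-t list (weight `|t|^P`, default `P = 1`; miss penalty
  `1/(N − N_S)`), with separate up/down enrichment scores, a gene-label
  permutation null (default 1000 randomizations), `NES = ES / mean(null ES)`
  per direction, directional permutation p-values, BH across all
  (set, direction) tests, and Venn partitions of sets shared across the
  three mirror comparisons.
- **Signatures and ordination** — per-subset signatures (genes up-regulated
  vs all five other subsets at adjusted p < 0.05), spider-chart matrices of
  mean log2 normalized cpm, row z-score matrices with complete-linkage
  clustering order, PCA on the top 500 most variable genes, and lncRNA
  sub-tables read out of the genome-wide adjustment by annotation biotype.
- **Synthetic data with ground truth** — a negative-binomial generator
  (`Var = μ + φμ²`, gene-wise `φ ~ Gamma`) emulating the 6-subset × 3-donor
  design with planted subset effects, library-size spread, donor effects,
  biotype labels and planted-enriched gene sets, so every stage is
  verifiable without access to sorted-cell sequencing data.

Standard building blocks (TMM, voom, gene-wise weighted least squares,
EB variance shrinkage, BH) are delegated to edgeR/limma/stats; the
enrichment procedure, signature logic and orchestration are implemented
here and all of it is cross-checked in the test suite against independent
step-by-step reference implementations.

## Worked example

```r
library(ilcmirror)

sim    <- simulate_counts(sim_config(n_genes = 2000, seed = 42))
counts <- filter_low_expression(sim$counts)          # >= 1 cpm in >= 1 sample
design <- build_design(sim$samples, "subset")
norm   <- log_cpm_and_weights(counts, tmm_factors(counts), design)
fit    <- fit_models(norm, design)
fit
#> gene_fit: 2000 genes, groups: ILC1, ILC2, ILCP, Th1, Th2, Th17
#>   residual df: 12; EB prior: d0 = 4.919, s02 = 0.8313

tab <- test_contrast(fit, c(ILC2 = 1, Th2 = -1))
sum(tab$adj_p < 0.05)                                # 90 DE genes, 49 up in ILC2
head(tab[order(tab$p), ], 3)
#>      gene_id log2fc      t        p    adj_p
#> 1402 G001402  -2.08 -10.04 1.53e-08 2.75e-05
#> 839  G000839   2.18   9.61 2.87e-08 2.75e-05
#> 1728 G001728   2.09   9.14 5.94e-08 2.75e-05

ranked <- rank_genes(tab)
sets <- simulate_genesets(rownames(counts), sim$truth, n_null_sets = 20,
                          n_enriched_sets = 2, size_range = c(20, 50),
                          enriched_size_range = c(8, 12), seed = 1,
                          subsets = "ILC2")
res <- gsea_run(ranked, sets, gsea_config(n_permutations = 1000, seed = 2))
head(res[order(res$p), ], 4)
#>                     set size direction     es  nes        p  adj_p
#> 41 ENRICHED_UP_ILC2_001    8        up  0.974 3.22 0.000999 0.0220
#> 43 ENRICHED_UP_ILC2_002   12        up  0.971 3.51 0.000999 0.0220
#> 40         NULL_SET_020   26      down -0.576 2.52 0.003996 0.0586
#> 17         NULL_SET_009   33        up  0.514 2.11 0.019980 0.2198
```

The moderated t recovers the planted |log2FC| = 2 effects (estimates near
±2), and the two gene sets planted from ILC2-up genes top the enrichment
table at the permutation resolution (p = 1/1001) while random sets do not.

The whole analysis is also available as one call —
`run_pipeline(pipeline_config(seed = 1), "outdir")` — which writes every
intermediate table, a `manifest.json` with seeds and file hashes (two runs
with the same configuration are byte-identical), and a plain-text
`report.txt` with the DE count matrix, Venn regions, NES dot-matrix,
signature sizes, spider matrix and lncRNA counts. A thin CLI wrapper lives
at `inst/cli/ilcmirror.R` (`simulate`, `run`, `report` subcommands).

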