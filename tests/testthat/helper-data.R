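# Shared fixture builders. All data is generated in code under fixed seeds.

# Small synthetic study, normalized and fitted under the subset design.
quick_study <- function(n_genes = 600, seed = 1, de_fraction = 0.1,
                        effect_size_log2 = 2, mean_lib_size = 5e5, ...) {
  sim <- simulate_counts(sim_config(n_genes = n_genes, seed = seed,
                                    de_fraction = de_fraction,
                                    effect_size_log2 = effect_size_log2,
                                    mean_lib_size = mean_lib_size, ...))
  filtered <- filter_low_expression(sim$counts)
  tmm <- tmm_factors(filtered)
  design <- build_design(sim$samples, "subset")
  norm <- log_cpm_and_weights(filtered, tmm, design)
  fit <- fit_models(norm, design)
  list(sim = sim, filtered = filtered, norm = norm, design = design, fit = fit)
}

# All 15 unordered pairwise contrast tables from a subset fit.
all_pairwise <- function(fit) {
  groups <- colnames(coef(fit))
  out <- list()
  for (pr in utils::combn(groups, 2, simplify = FALSE)) {
    out[[paste(pr[1], pr[2], sep = "_vs_")]] <-
      test_contrast(fit, stats::setNames(c(1, -1), pr))
  }
  out
}

# A deterministic ranked list (named, sorted decreasing) for GSEA tests.
toy_ranked <- function(n = 50, seed = 1) {
  set.seed(seed)
  t <- rnorm(n)
  names(t) <- sprintf("G%03d", seq_len(n))
  t[order(-t, names(t))]
}

# Hand-built contrast table with chosen significance pattern.
fake_contrast <- function(gene_id, log2fc, adj_p, p = adj_p) {
  tb <- data.frame(gene_id = gene_id, log2fc = log2fc,
                   t = log2fc * 10, p = p, adj_p = adj_p,
                   stringsAsFactors = FALSE)
  class(tb) <- c("contrast_table", "data.frame")
  tb
}
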