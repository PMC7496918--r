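make_pairwise_tables <- function(genes, high_in) {
  # high_in: named character vector gene -> subset where it is overexpressed
  subsets <- c("ILC1", "ILC2", "ILCP", "Th1", "Th2", "Th17")
  out <- list()
  for (pr in utils::combn(subsets, 2, simplify = FALSE)) {
    lfc <- numeric(length(genes))
    adj <- rep(0.9, length(genes))
    for (i in seq_along(genes)) {
      s <- high_in[genes[i]]
      if (is.na(s)) next
      if (s == pr[1]) { lfc[i] <- 3; adj[i] <- 0.001 }
      if (s == pr[2]) { lfc[i] <- -3; adj[i] <- 0.001 }
    }
    out[[paste(pr[1], pr[2], sep = "_vs_")]] <- fake_contrast(genes, lfc, adj)
  }
  out
}

test_that("signatures apply the all-five conjunction rule", {
  genes <- sprintf("G%02d", 1:20)
  high <- stats::setNames(rep(NA_character_, 20), genes)
  high[1:10] <- "ILC2"
  high[11:12] <- "Th17"
  tabs <- make_pairwise_tables(genes, high)
  sig <- subset_signatures(tabs)
  expect_setequal(sig$members$ILC2, genes[1:10])
  expect_setequal(sig$members$Th17, genes[11:12])
  expect_length(sig$members$ILC1, 0)

  # a gene up vs 4 subsets but flat vs the 5th is excluded
  tabs2 <- tabs
  tb <- tabs2[["ILC2_vs_Th2"]]
  tb$adj_p[tb$gene_id == "G01"] <- 0.5
  tabs2[["ILC2_vs_Th2"]] <- tb
  sig2 <- subset_signatures(tabs2)
  expect_false("G01" %in% sig2$members$ILC2)
  expect_setequal(sig2$members$ILC2, genes[2:10])

  # no significant genes anywhere -> six empty signatures
  none <- make_pairwise_tables(genes, stats::setNames(rep(NA_character_, 20), genes))
  expect_equal(sum(lengths(subset_signatures(none)$members)), 0)

  expect_error(subset_signatures(tabs[-1]), "missing pairwise")
})

test_that("spider values average signature expression per subset", {
  sim <- simulate_counts(sim_config(n_genes = 30, seed = 1))
  norm <- list(log_cpm = matrix(2, 30, 18,
                                dimnames = list(sprintf("G%06d", 1:30),
                                                sim$samples$sample_id)))
  sig <- structure(list(members = list(ILC1 = "G000001", ILC2 = character(0),
                                       ILCP = character(0), Th1 = character(0),
                                       Th2 = character(0), Th17 = character(0)),
                        alpha = 0.05), class = "signature_set")
  sp <- spider_values(sig, norm, sim$samples)
  expect_equal(unname(sp["ILC1", ]), rep(2, 6))
  expect_true(all(is.na(sp["ILC2", ])))
})

test_that("planted subset-specific genes dominate their spider row", {
  st <- quick_study(n_genes = 800, seed = 12, de_fraction = 0.25,
                    effect_size_log2 = 3)
  tabs <- all_pairwise(st$fit)
  sig <- subset_signatures(tabs)
  sp <- spider_values(sig, st$norm, st$sim$samples)
  for (s in rownames(sp)) {
    if (!length(sig$members[[s]])) next
    expect_equal(names(which.max(sp[s, ])), s)
  }
  # planted up-genes recovered into the right signature only
  truth <- st$sim$truth
  eff <- as.matrix(truth[grep("^effect_", names(truth))])
  colnames(eff) <- sub("^effect_", "", colnames(eff))
  for (s in colnames(eff)) {
    planted_up <- truth$gene_id[eff[, s] > 0]
    for (other in setdiff(colnames(eff), s)) {
      expect_length(intersect(planted_up, sig$members[[other]]), 0)
    }
  }
})

test_that("row z-scores center and scale with the sample sd convention", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- row_zscores(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_lt(max(abs(rowMeans(z))), 1e-10)
})

test_that("complete-linkage ordering recovers planted clusters and the oracle heights", {
  x <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
             c(5, 5), c(5.1, 5), c(5, 5.1))
  rownames(x) <- paste0("r", 1:6)
  ord <- cluster_order(x)
  expect_setequal(ord, 1:6)
  hc <- stats::hclust(stats::dist(x), method = "complete")
  expect_setequal(stats::cutree(hc, 2)[1:3], 1)
  expect_setequal(stats::cutree(hc, 2)[4:6], 2)
  expect_equal(sort(hc$height), oracle_complete_linkage_heights(x),
               tolerance = 1e-12)
  expect_error(cluster_order(x[1, , drop = FALSE]), ">= 2 rows")
})

test_that("PCA on top-variable genes reports SVD-consistent variance fractions", {
  st <- quick_study(n_genes = 500, seed = 13)
  pca <- pca_top_variable(st$norm, n_top = 100)
  expect_equal(sum(pca$var_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(pca$var_fraction) <= 1e-12))
  expect_true(all(pca$var_fraction >= 0))
  expect_length(pca$genes, 100)

  # gene-order invariance
  norm2 <- st$norm
  perm <- sample(nrow(norm2$log_cpm))
  norm2$log_cpm <- norm2$log_cpm[perm, ]
  pca2 <- pca_top_variable(norm2, n_top = 100)
  expect_equal(pca2$var_fraction, pca$var_fraction, tolerance = 1e-8)
  expect_setequal(pca2$genes, pca$genes)
  expect_error(pca_top_variable(st$norm, n_top = 1), ">= 2")
})

test_that("a dominant two-group structure separates on PC1", {
  set.seed(14)
  y <- matrix(rnorm(300 * 12, sd = 0.3), 300, 12)
  y[1:150, 1:6] <- y[1:150, 1:6] + 3
  dimnames(y) <- list(sprintf("G%03d", 1:300), sprintf("S%02d", 1:12))
  pca <- pca_top_variable(list(log_cpm = y), n_top = 200)
  pc1 <- pca$scores[, 1]
  grp <- rep(c(1, 2), each = 6)
  sil <- vapply(seq_along(pc1), function(i) {
    a <- mean(abs(pc1[i] - pc1[grp == grp[i]][-which(which(grp == grp[i]) == i)]))
    b <- mean(abs(pc1[i] - pc1[grp != grp[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
})

test_that("biotype restriction reads sub-tables out of the global adjustment", {
  genes <- sprintf("G%02d", 1:10)
  ann <- data.frame(gene_id = genes, symbol = genes,
                    biotype = rep(c("lncRNA", "protein_coding"), 5),
                    stringsAsFactors = FALSE)
  tb <- fake_contrast(genes, rnorm(10), seq(0.01, 0.1, length.out = 10))
  lnc <- biotype_subset(tb, ann, "lncRNA")
  expect_equal(lnc$gene_id, genes[c(TRUE, FALSE)])
  # adjusted p untouched (no re-computation on the subset)
  expect_equal(lnc$adj_p, tb$adj_p[c(TRUE, FALSE)])

  # union over labels restores the full table
  pc <- biotype_subset(tb, ann, "protein_coding")
  expect_setequal(c(lnc$gene_id, pc$gene_id), genes)

  # recognized class absent from the annotation -> empty table
  ann2 <- ann; ann2$biotype <- "protein_coding"
  expect_equal(nrow(biotype_subset(tb, ann2, "lncRNA")), 0)
  expect_error(biotype_subset(tb, ann2, "miRNA"), "protein_coding")

  ann3 <- ann[1:8, ]
  expect_warning(biotype_subset(tb, ann3, "lncRNA"), "dropped")
})

test_that("qPCR relative expression follows the 2^-deltaCt formula", {
  expect_equal(qpcr_delta_ct(c(25, 25, 25), c(20, 20, 20)), 0.03125)
  expect_equal(qpcr_delta_ct(c(24, 25, 26), c(22, 23, 24)), 0.25)
  expect_equal(qpcr_delta_ct(c(30, 30, 30), c(30, 30, 30)), 1)
  one_less <- qpcr_delta_ct(c(24, 24, 24), c(20, 20, 20))
  expect_equal(qpcr_delta_ct(c(23, 23, 23), c(20, 20, 20)) / one_less, 2)
  expect_error(qpcr_delta_ct(c(50, 25, 25), c(20, 20, 20)), "\\(0, 45\\)")
  expect_error(qpcr_delta_ct(c(25, NA, 25), c(20, 20, 20)), "complete")
})
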