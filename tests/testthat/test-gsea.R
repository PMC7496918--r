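test_that("the running-sum score matches hand-computed walks", {
  ranked <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  es <- enrichment_score(ranked, c("g1", "g5"), P = 1)
  # hits add 3/5 then 2/5; misses subtract 1/3
  expect_equal(unname(es["es_up"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(es["es_down"]), -0.4, tolerance = 1e-12)
  expect_equal(es, oracle_es(ranked, c("g1", "g5"), P = 1), tolerance = 1e-12)

  # single top hit with all |t| equal reaches ES = 1 at position 1
  flat <- c(a = 1, b = 1, c = 1, d = 1)
  expect_equal(unname(enrichment_score(flat, "a")["es_up"]), 1)

  expect_error(enrichment_score(ranked, "nope"), "empty intersection")
  expect_error(enrichment_score(ranked, names(ranked)), "entire ranked universe")
})

test_that("P = 0 reduces to the one-sided Kolmogorov-Smirnov statistic on ranks", {
  ranked <- toy_ranked(40, seed = 2)
  members <- sample(names(ranked), 12)
  es <- enrichment_score(ranked, members, P = 0)
  pos <- which(names(ranked) %in% members)
  non <- setdiff(seq_along(ranked), pos)
  f_mem <- vapply(seq_along(ranked), function(x) mean(pos <= x), numeric(1))
  f_non <- vapply(seq_along(ranked), function(x) mean(non <= x), numeric(1))
  expect_equal(unname(es["es_up"]), max(0, f_mem - f_non), tolerance = 1e-12)
  expect_equal(unname(es["es_down"]), min(0, f_mem - f_non), tolerance = 1e-12)
})

test_that("reversing the ranked list swaps the two enrichment directions", {
  ranked <- toy_ranked(30, seed = 3)
  members <- sample(names(ranked), 8)
  fwd <- enrichment_score(ranked, members, P = 1)
  flipped <- rev(-ranked)
  bwd <- enrichment_score(flipped, members, P = 1)
  expect_equal(unname(fwd["es_up"]), -unname(bwd["es_down"]), tolerance = 1e-12)
  expect_equal(unname(fwd["es_down"]), -unname(bwd["es_up"]), tolerance = 1e-12)
})

test_that("the permutation null is reproducible with the expected sign structure", {
  ranked <- toy_ranked(60, seed = 4)
  a <- permutation_null(ranked, 10, n = 200, seed = 9)
  b <- permutation_null(ranked, 10, n = 200, seed = 9)
  expect_identical(a, b)
  expect_gt(mean(a[, "es_up"]), 0)
  expect_lt(mean(a[, "es_down"]), 0)
  expect_true(all(a[, "es_up"] >= 0 & a[, "es_up"] <= 1))
  expect_true(all(a[, "es_down"] <= 0 & a[, "es_down"] >= -1))

  # with set_size = N - 1 only the excluded gene varies
  deg <- permutation_null(ranked, 59, n = 300, seed = 1)
  expect_lte(length(unique(deg[, "es_up"])), 60)

  expect_error(permutation_null(ranked, 60, n = 10, seed = 1), "set_size")
})

test_that("NES and permutation p follow their definitions", {
  null <- rep(0.4, 1000)
  res <- nes_and_pvalue(0.4, null, "up")
  expect_equal(res$nes, 1)
  expect_equal(res$p, 1)

  set.seed(5)
  null2 <- runif(1000, 0, 0.5)
  res2 <- nes_and_pvalue(0.9, null2, "up")
  expect_equal(res2$nes, 0.9 / mean(null2))
  expect_equal(res2$p, 1 / 1001)
  # raw-proportion estimator available for literal replication
  expect_equal(nes_and_pvalue(0.9, null2, "up", add_one = FALSE)$p, 0)

  expect_error(nes_and_pvalue(0.5, rep(0, 10), "up"), "degenerate")
})

test_that("gsea_run is deterministic and treats duplicate sets identically", {
  ranked <- toy_ranked(80, seed = 6)
  sets <- list(A = names(ranked)[c(1, 3, 5, 7)],
               B = sample(names(ranked), 10),
               A2 = names(ranked)[c(1, 3, 5, 7)],
               GONE = c("x1", "x2"))
  cfg <- gsea_config(n_permutations = 100, seed = 2)
  expect_warning(r1 <- gsea_run(ranked, sets, cfg), "skipped")
  expect_warning(r2 <- gsea_run(ranked, sets, cfg), "skipped")
  expect_identical(r1, r2)
  expect_false("GONE" %in% r1$set)
  a <- r1[r1$set == "A", c("es", "nes", "p")]
  a2 <- r1[r1$set == "A2", c("es", "nes", "p")]
  rownames(a) <- rownames(a2) <- NULL
  expect_identical(a, a2)
  expect_true(all(r1$adj_p >= r1$p))
  expect_true(all(r1$es[r1$direction == "up"] >= 0))
  expect_true(all(r1$es[r1$direction == "down"] <= 0))

  expect_error(suppressWarnings(gsea_run(ranked, list(Z = "zz"), cfg)),
               "no usable")
})

test_that("Venn partition of shared enriched sets matches brute-force set arithmetic", {
  fake <- function(sig_sets, all_sets) {
    data.frame(set = all_sets, size = 10, direction = "up",
               es = 0.5, nes = 2,
               p = ifelse(all_sets %in% sig_sets, 0.001, 0.8),
               adj_p = ifelse(all_sets %in% sig_sets, 0.01, 0.9),
               stringsAsFactors = FALSE)
  }
  universe <- sprintf("S%02d", 1:12)
  same <- fake(universe[1:5], universe)
  tri <- shared_enriched_sets(list(a = same, b = same, c = same))
  expect_equal(tri$n[tri$region == "a & b & c"], 5)
  expect_equal(sum(tri$n), 5)

  disj <- shared_enriched_sets(list(a = fake(universe[1:3], universe),
                                    b = fake(universe[4:6], universe)))
  expect_equal(disj$n[disj$region == "a & b"], 0)
  expect_equal(disj$n[disj$region == "a"], 3)

  set.seed(7)
  sigs <- lapply(1:3, function(i) sample(universe, 6))
  names(sigs) <- c("x", "y", "z")
  res <- shared_enriched_sets(lapply(sigs, fake, all_sets = universe))
  for (s in universe) {
    inset <- names(sigs)[vapply(sigs, function(v) s %in% v, logical(1))]
    if (!length(inset)) next
    region <- paste(inset, collapse = " & ")
    expect_match(res$sets[res$region == region], s, fixed = TRUE)
  }
  expect_equal(sum(res$n), length(unique(unlist(sigs))))
})

test_that("ranked lists order by decreasing t with lexicographic tie-break", {
  tb <- fake_contrast(c("B", "A", "C"), c(1, 2, 1), c(0.5, 0.5, 0.5))
  tb$t <- c(5, 5, 1)
  r <- rank_genes(tb)
  expect_equal(names(r), c("A", "B", "C"))
  expect_true(!is.unsorted(rev(r)))
})
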