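test_that("design matrices take the group-means form", {
  sim <- simulate_counts(sim_config(n_genes = 10, seed = 1))
  d6 <- build_design(sim$samples, "subset")
  expect_equal(dim(d6), c(18L, 6L))
  expect_equal(unname(colSums(d6)), rep(3, 6))
  expect_true(all(rowSums(d6) == 1))

  d2 <- build_design(sim$samples, "lineage")
  expect_equal(dim(d2), c(18L, 2L))
  expect_equal(unname(colSums(d2)), c(9, 9))

  smp <- sim$samples[sim$samples$subset != "ILC1", ]
  expect_equal(ncol(build_design(smp, "subset")), 5L)
})

test_that("unweighted fits reproduce group means (OLS identity)", {
  sim <- simulate_counts(sim_config(n_genes = 50, seed = 2))
  design <- build_design(sim$samples, "lineage")
  y <- matrix(rnorm(50 * 18), 50, 18,
              dimnames = list(sprintf("G%02d", 1:50), sim$samples$sample_id))
  norm <- list(log_cpm = y, weights = matrix(1, 50, 18))
  fit <- fit_models(norm, design)
  ilc_cols <- sim$samples$sample_id[sim$samples$subset %in% c("ILC1", "ILC2", "ILCP")]
  expect_equal(unname(coef(fit)[, "ILC"]),
               unname(rowMeans(y[, ilc_cols])), tolerance = 1e-10)
})

test_that("moderated t reduces to the ordinary and fully pooled statistics in its limits", {
  st <- quick_study(n_genes = 200, seed = 3)
  ctr <- c(ILC2 = 1, Th2 = -1)
  w <- stats::setNames(numeric(6), colnames(coef(st$fit)))
  w[names(ctr)] <- ctr

  tab0 <- test_contrast(st$fit, ctr, prior_df = 0)
  ref <- oracle_ordinary_t(st$norm$log_cpm, st$norm$weights, st$design, w)
  expect_equal(tab0$t, unname(ref[, "t"]), tolerance = 1e-8)
  expect_equal(tab0$p, unname(ref[, "p"]), tolerance = 1e-8)

  s02 <- st$fit$s02
  tab_inf <- test_contrast(st$fit, ctr, prior_df = Inf, prior_var = s02)
  v <- drop(st$fit$stdev_unscaled^2 %*% w^2)
  expect_equal(tab_inf$t, unname(tab0$log2fc / sqrt(s02 * v)), tolerance = 1e-8)
})

test_that("constant residual variances need no shrinkage", {
  s2 <- rep(0.5, 300)
  eb <- estimate_eb_prior(s2, df = 10)
  expect_equal(eb$df_prior, 1e7)
  expect_equal(unname(eb$var_post), s2, tolerance = 1e-6)
})

test_that("shrunk variances are less dispersed than raw ones", {
  st <- quick_study(n_genes = 400, seed = 4)
  expect_lte(var(st$fit$s2_post), var(st$fit$sigma2))
  expect_true(all(st$fit$s2_post >= pmin(st$fit$sigma2, st$fit$s02) - 1e-12))
  expect_true(all(st$fit$s2_post <= pmax(st$fit$sigma2, st$fit$s02) + 1e-12))
})

test_that("BH adjustment matches the step-up formula and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("moderated p-values are calibrated under the null", {
  sim <- simulate_counts(sim_config(n_genes = 5000, seed = 6, de_fraction = 0))
  counts <- filter_low_expression(sim$counts)
  design <- build_design(sim$samples, "lineage")
  norm <- log_cpm_and_weights(counts, tmm_factors(counts), design)
  fit <- fit_models(norm, design)
  tab <- test_contrast(fit, c(ILC = 1, Th = -1))
  frac <- mean(tab$p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
  ks <- suppressWarnings(stats::ks.test(tab$p, "punif"))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("DE summaries count signed discoveries and respect sign symmetry", {
  st <- quick_study(n_genes = 300, seed = 7, de_fraction = 0.2)
  fwd <- test_contrast(st$fit, c(ILC2 = 1, Th2 = -1))
  rev <- test_contrast(st$fit, c(ILC2 = -1, Th2 = 1))
  s <- de_summary(list(ILC2_vs_Th2 = fwd, Th2_vs_ILC2 = rev))
  expect_equal(s$counts$n_up[1], s$counts$n_down[2])
  expect_equal(s$counts$n_down[1], s$counts$n_up[2])

  none <- fake_contrast(c("A", "B"), c(1, -1), c(0.9, 0.9))
  s0 <- de_summary(list(x = none))
  expect_equal(unlist(s0$counts[, c("n_up", "n_down")], use.names = FALSE), c(0, 0))

  other <- fake_contrast(c("A", "C"), c(1, -1), c(0.9, 0.9))
  expect_error(de_summary(list(x = none, y = other)), "universe")
})

test_that("DE counts recover a planted two-group truth", {
  # 2000 genes, 100 up + 50 down at a strong effect, Gaussian errors
  set.seed(8)
  n <- 2000
  samples <- data.frame(
    sample_id = sprintf("%s_D%d", rep(c("ILC2", "Th2"), each = 9), 1:9),
    subset = rep(c("ILC2", "Th2"), each = 9),
    donor = paste0("D", rep(1:9, 2)), stringsAsFactors = FALSE)
  design <- build_design(samples, "subset")
  mu <- matrix(0, n, 18)
  mu[1:100, 1:9] <- 2
  mu[101:150, 1:9] <- -2
  y <- mu + matrix(rnorm(n * 18, sd = 0.7), n, 18)
  dimnames(y) <- list(sprintf("G%04d", 1:n), samples$sample_id)
  fit <- fit_models(list(log_cpm = y, weights = matrix(1, n, 18)), design)
  tab <- test_contrast(fit, c(ILC2 = 1, Th2 = -1))
  s <- de_summary(list(ILC2_vs_Th2 = tab))
  expect_lte(abs(s$counts$n_up - 100), 15)
  expect_lte(abs(s$counts$n_down - 50), 15)
})
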