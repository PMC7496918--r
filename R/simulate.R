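#' Configuration for the synthetic RNA-seq study generator
#'
#' Builds the parameter set for [simulate_counts()]. The defaults emulate the
#' design of the sorted-cell study the pipeline targets: 6 cell subsets
#' (ILC1, ILC2, ILCP, Th1, Th2, Th17) sampled from 3 healthy donors, gene-wise
#' negative-binomial counts with `Var = mu + phi * mu^2`, unequal library
#' sizes, small donor effects, and a configurable fraction of genes with a
#' planted subset-specific log2 effect.
#'
#' @param n_genes number of genes to simulate.
#' @param n_subsets number of cell subsets (2..6, taken in order from
#'   ILC1, ILC2, ILCP, Th1, Th2, Th17).
#' @param n_donors donors per subset (>= 2); one library per subset x donor.
#' @param baseline_log2_range range of per-gene baseline abundance on the log2
#'   scale; baselines are drawn uniformly on this range and rescaled so the
#'   expected library size equals `mean_lib_size`.
#' @param dispersion mean negative-binomial dispersion phi (0 gives Poisson).
#' @param dispersion_shape shape of the gamma distribution for gene-wise phi.
#' @param de_fraction fraction of genes given a planted subset effect.
#' @param effect_size_log2 absolute planted log2 fold change.
#' @param donor_sd_log2 sd (log2) of gene-by-donor effects shared by all
#'   libraries of one donor; kept small so default fits need no blocking.
#' @param libsize_log_sd sd of the log-normal library-size factors.
#' @param mean_lib_size expected library size (reads per sample).
#' @param lncrna_fraction fraction of genes labelled with biotype "lncRNA"
#'   (remaining genes are "protein_coding").
#' @param seed integer seed; all generator output is reproducible from it.
#' @return A list of class `sim_config`.
#' @seealso [simulate_counts()], [simulate_genesets()]
#' @export
sim_config <- function(n_genes = 2000,
                       n_subsets = 6,
                       n_donors = 3,
                       baseline_log2_range = c(1, 9),
                       dispersion = 0.1,
                       dispersion_shape = 2,
                       de_fraction = 0.15,
                       effect_size_log2 = 2,
                       donor_sd_log2 = 0.1,
                       libsize_log_sd = 0.15,
                       mean_lib_size = 2e6,
                       lncrna_fraction = 0.15,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_subsets = as.integer(n_subsets),
              n_donors = as.integer(n_donors),
              baseline_log2_range = as.numeric(baseline_log2_range),
              dispersion = dispersion, dispersion_shape = dispersion_shape,
              de_fraction = de_fraction, effect_size_log2 = effect_size_log2,
              donor_sd_log2 = donor_sd_log2, libsize_log_sd = libsize_log_sd,
              mean_lib_size = mean_lib_size, lncrna_fraction = lncrna_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stop_ilc("n_genes must be >= 1")
  if (cfg$n_subsets < 2 || cfg$n_subsets > length(ALL_SUBSETS)) {
    stop_ilc("n_subsets must be between 2 and %d", length(ALL_SUBSETS))
  }
  if (cfg$n_donors < 2) stop_ilc("n_donors must be >= 2")
  for (fr in c("de_fraction", "lncrna_fraction")) {
    if (cfg[[fr]] < 0 || cfg[[fr]] > 1) stop_ilc("%s must lie in [0, 1]", fr)
  }
  if (cfg$dispersion < 0) stop_ilc("dispersion must be >= 0")
  if (cfg$dispersion_shape <= 0) stop_ilc("dispersion_shape must be > 0")
  if (cfg$libsize_log_sd < 0 || cfg$donor_sd_log2 < 0) {
    stop_ilc("variance parameters must be >= 0")
  }
  if (length(cfg$baseline_log2_range) != 2 ||
      diff(cfg$baseline_log2_range) < 0) {
    stop_ilc("baseline_log2_range must be an increasing pair")
  }
  invisible(cfg)
}

#' Simulate a sorted-subset RNA-seq count matrix with known ground truth
#'
#' Draws gene-level counts for `n_subsets x n_donors` libraries from a
#' negative-binomial model: `counts[g, s] ~ NB(mu, size = 1/phi_g)` with
#' `mu = baseline_g * 2^(effect[g, subset(s)] + donor_dev[g, donor(s)]) *
#' lib_factor_s`. A `de_fraction` of genes carries a planted effect of
#' `+/- effect_size_log2` in one randomly chosen subset; the truth table
#' records every planted effect and each gene's biotype.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements
#'   `counts` (integer matrix, genes x samples),
#'   `samples` (data.frame: sample_id, subset, donor),
#'   `annotation` (data.frame: gene_id, symbol, biotype),
#'   `truth` (data.frame: gene_id, biotype, is_de, de_subset, and one
#'    `effect_<subset>` column of true log2 effects per subset), and
#'   `lib_factors` (the drawn library-size factors).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, {
    subsets <- ALL_SUBSETS[seq_len(config$n_subsets)]
    donors <- paste0("D", seq_len(config$n_donors))
    samples <- data.frame(
      sample_id = as.vector(outer(subsets, donors, paste, sep = "_")),
      subset = rep(subsets, times = config$n_donors),
      donor = rep(donors, each = config$n_subsets),
      stringsAsFactors = FALSE)

    n <- config$n_genes
    gene_id <- sprintf("G%06d", seq_len(n))
    symbol <- sprintf("SYM%06d", seq_len(n))
    biotype <- ifelse(stats::runif(n) < config$lncrna_fraction,
                      "lncRNA", "protein_coding")

    baseline <- 2^stats::runif(n, config$baseline_log2_range[1],
                               config$baseline_log2_range[2])
    # rescale so an average library totals mean_lib_size reads
    baseline <- baseline * config$mean_lib_size / sum(baseline)

    effect <- matrix(0, n, config$n_subsets, dimnames = list(gene_id, subsets))
    n_de <- round(config$de_fraction * n)
    de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
    de_subset <- rep(NA_character_, n)
    if (n_de > 0) {
      sub_pick <- sample(subsets, n_de, replace = TRUE)
      sign_pick <- sample(c(-1, 1), n_de, replace = TRUE)
      de_subset[de_idx] <- sub_pick
      effect[cbind(de_idx, match(sub_pick, subsets))] <-
        sign_pick * config$effect_size_log2
    }

    phi <- if (config$dispersion > 0) {
      stats::rgamma(n, shape = config$dispersion_shape,
                    scale = config$dispersion / config$dispersion_shape)
    } else rep(0, n)

    donor_dev <- if (config$donor_sd_log2 > 0) {
      matrix(stats::rnorm(n * config$n_donors, 0, config$donor_sd_log2),
             n, config$n_donors, dimnames = list(gene_id, donors))
    } else matrix(0, n, config$n_donors, dimnames = list(gene_id, donors))

    lib_factor <- exp(stats::rnorm(nrow(samples), 0, config$libsize_log_sd))
    names(lib_factor) <- samples$sample_id

    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(gene_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- baseline *
        2^(effect[, samples$subset[j]] + donor_dev[, samples$donor[j]]) *
        lib_factor[j]
      counts[, j] <- if (config$dispersion > 0) {
        as.integer(stats::rnbinom(n, mu = mu, size = 1 / phi))
      } else {
        as.integer(stats::rpois(n, lambda = mu))
      }
    }

    truth <- data.frame(gene_id = gene_id, symbol = symbol, biotype = biotype,
                        is_de = seq_len(n) %in% de_idx,
                        de_subset = de_subset, stringsAsFactors = FALSE)
    eff_df <- as.data.frame(effect)
    names(eff_df) <- paste0("effect_", subsets)
    truth <- cbind(truth, eff_df)
    rownames(truth) <- NULL

    annotation <- truth[, c("gene_id", "symbol", "biotype")]

    list(counts = counts, samples = samples, annotation = annotation,
         truth = truth, lib_factors = lib_factor)
  })
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Null sets are uniform draws from the gene universe. Enriched sets are drawn
#' predominantly (`purity` of members) from genes whose true planted effect in
#' a chosen subset has the requested sign, so a downstream contrast against
#' that subset should score them as enriched.
#'
#' @param genes character vector, the gene universe.
#' @param truth truth table from [simulate_counts()].
#' @param n_null_sets,n_enriched_sets numbers of sets of each kind.
#' @param size_range inclusive range of null-set sizes.
#' @param enriched_size_range inclusive range of enriched-set sizes (defaults
#'   to `size_range`); must stay within the planted same-sign gene pool.
#' @param seed integer seed.
#' @param subsets subsets targeted by enriched sets (recycled); defaults to
#'   every subset that has planted up-regulated genes.
#' @param direction "up" or "down": sign of the planted effects members are
#'   drawn from.
#' @param purity fraction of each enriched set drawn from same-sign effect
#'   genes (>= 0.8 to keep the planted signal unambiguous).
#' @return A named list of gene-id vectors of class `geneset_collection`, with
#'   attribute `info`: a data.frame (name, description, enriched, subset,
#'   direction).
#' @export
simulate_genesets <- function(genes, truth, n_null_sets = 10,
                              n_enriched_sets = 0, size_range = c(20, 200),
                              seed = 1L, subsets = NULL, direction = "up",
                              purity = 0.9, enriched_size_range = size_range) {
  for (sr in list(size_range, enriched_size_range)) {
    if (sr[1] < 2 || sr[2] > length(genes)) {
      stop_ilc("set sizes must lie within [2, %d]", length(genes))
    }
    if (sr[1] > sr[2]) stop_ilc("size range must be increasing")
  }
  if (purity < 0.8 || purity > 1) stop_ilc("purity must lie in [0.8, 1]")
  direction <- match.arg(direction, c("up", "down"))
  sgn <- if (direction == "up") 1 else -1

  eff_cols <- grep("^effect_", names(truth), value = TRUE)
  eff <- as.matrix(truth[match(genes, truth$gene_id), eff_cols, drop = FALSE])
  colnames(eff) <- sub("^effect_", "", eff_cols)
  if (n_enriched_sets > 0) {
    if (is.null(subsets)) {
      subsets <- colnames(eff)[colSums(sgn * eff > 0) > 0]
      if (!length(subsets)) {
        stop_ilc("no genes with %s-regulated planted effects to enrich from",
                 direction)
      }
    }
    subsets <- rep_len(subsets, n_enriched_sets)
  }

  with_seed(seed, {
    n_total <- n_null_sets + n_enriched_sets
    sets <- vector("list", n_total)
    info <- data.frame(name = character(n_total), description = character(n_total),
                       enriched = logical(n_total), subset = NA_character_,
                       direction = NA_character_, stringsAsFactors = FALSE)
    sizes <- c(
      if (n_null_sets > 0) {
        sample(seq(size_range[1], size_range[2]), n_null_sets, replace = TRUE)
      },
      if (n_enriched_sets > 0) {
        sample(seq(enriched_size_range[1], enriched_size_range[2]),
               n_enriched_sets, replace = TRUE)
      })
    for (i in seq_len(n_total)) {
      k <- sizes[i]
      if (i <= n_null_sets) {
        members <- sample(genes, k)
        info$name[i] <- sprintf("NULL_SET_%03d", i)
        info$description[i] <- "random gene set"
      } else {
        sub <- subsets[i - n_null_sets]
        pool <- genes[sgn * eff[, sub] > 0]
        n_core <- ceiling(purity * k)
        if (length(pool) < n_core) {
          stop_ilc("subset %s has only %d %s-regulated genes; cannot build an enriched set of size %d",
                   sub, length(pool), direction, k)
        }
        core <- sample(pool, n_core)
        filler <- sample(setdiff(genes, core), k - n_core)
        members <- c(core, filler)
        info$name[i] <- sprintf("ENRICHED_%s_%s_%03d", toupper(direction), sub,
                                i - n_null_sets)
        info$description[i] <- sprintf("planted %s-enriched in %s", direction, sub)
        info$enriched[i] <- TRUE
        info$subset[i] <- sub
        info$direction[i] <- direction
      }
      sets[[i]] <- sort(members)
    }
    names(sets) <- info$name
    structure(sets, info = info, class = "geneset_collection")
  })
}
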