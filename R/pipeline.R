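# End-to-end orchestration: simulate-or-load -> filter -> normalize -> fit ->
# contrasts -> GSEA -> signatures -> PCA -> lncRNA -> report.

#' Pipeline configuration
#'
#' Either point `counts`/`metadata`/`annotation` (and optionally `genesets`)
#' at input files, or leave them NULL to run on synthetic data drawn from
#' `sim`. One global `seed` fans out to the stage seeds by fixed offsets
#' (simulation +101, gene-set simulation +202, GSEA +303) so each stage is
#' independently reproducible.
#'
#' @param counts,metadata,annotation,genesets input file paths (TSV / GMT),
#'   or NULL to simulate.
#' @param sim list of [sim_config()] overrides for the synthetic run.
#' @param sim_genesets list: `n_null_sets`, `n_enriched_sets`, `size_range`
#'   for [simulate_genesets()] when `genesets` is NULL.
#' @param alpha BH-adjusted significance threshold used throughout.
#' @param min_cpm,min_samples expression-filter thresholds.
#' @param n_top genes used for the PCA.
#' @param gsea list of [gsea_config()] overrides.
#' @param lncrna_biotype annotation label of the long-noncoding class.
#' @param seed global integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, annotation = NULL,
                            genesets = NULL, sim = list(),
                            sim_genesets = list(), alpha = 0.05,
                            min_cpm = 1, min_samples = 1, n_top = 500,
                            gsea = list(), lncrna_biotype = "lncRNA",
                            seed = 1L) {
  seed <- as.integer(seed)
  sim$seed <- seed + 101L
  sim_cfg <- do.call(sim_config, sim)
  gs_defaults <- list(n_null_sets = 470, n_enriched_sets = 30,
                      size_range = c(20, 200), enriched_size_range = c(8, 12))
  sim_genesets <- utils::modifyList(gs_defaults, sim_genesets)
  gsea$seed <- seed + 303L
  gsea_cfg <- do.call(gsea_config, gsea)
  if (alpha <= 0 || alpha >= 1) stop_ilc("alpha must lie in (0, 1)")
  structure(list(counts = counts, metadata = metadata, annotation = annotation,
                 genesets = genesets, sim = sim_cfg,
                 sim_genesets = sim_genesets, alpha = alpha,
                 min_cpm = min_cpm, min_samples = min_samples, n_top = n_top,
                 gsea = gsea_cfg, lncrna_biotype = lncrna_biotype,
                 seed = seed),
            class = "pipeline_config")
}

run_stage <- function(name, log_con, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    msg <- sprintf("stage '%s' failed: %s", name, conditionMessage(e))
    if (!is.null(log_con)) writeLines(msg, log_con)
    stop(msg, call. = FALSE)
  })
  msg <- sprintf("[%s] stage '%s' done in %.1fs",
                 format(Sys.time(), "%H:%M:%S"), name,
                 proc.time()[["elapsed"]] - t0)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
  res
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writes all intermediate and final tables
#' under `outdir`, and returns (and writes) a run manifest recording the
#' package version, seeds, input hashes, per-stage row counts, and the md5
#' of every output table. Re-running with the same configuration reproduces
#' byte-identical tables and manifest.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "pipeline_config")) {
    stop_ilc("config must come from pipeline_config()")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stages <- list()
  simulated <- is.null(config$counts)

  inputs <- run_stage("inputs", log_con, {
    if (simulated) {
      sim <- simulate_counts(config$sim)
      sets <- if (is.null(config$genesets)) {
        simulate_genesets(rownames(sim$counts), sim$truth,
                          n_null_sets = config$sim_genesets$n_null_sets,
                          n_enriched_sets = config$sim_genesets$n_enriched_sets,
                          size_range = config$sim_genesets$size_range,
                          enriched_size_range = config$sim_genesets$enriched_size_range,
                          seed = config$seed + 202L,
                          subsets = intersect(ILC_SUBSETS, sim$samples$subset))
      } else read_gmt(config$genesets)
      write_counts(sim$counts, file.path(outdir, "counts.tsv"))
      write_metadata(sim$samples, file.path(outdir, "metadata.tsv"))
      write_annotation(sim$annotation, file.path(outdir, "annotation.tsv"))
      write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
      write_gmt(sets, file.path(outdir, "genesets.gmt"))
      list(counts = sim$counts, samples = sim$samples,
           annotation = sim$annotation, sets = sets, truth = sim$truth)
    } else {
      counts <- read_counts(config$counts)
      samples <- read_metadata(config$metadata, counts)
      annotation <- read_annotation(config$annotation)
      sets <- if (!is.null(config$genesets)) read_gmt(config$genesets) else NULL
      list(counts = counts, samples = samples, annotation = annotation,
           sets = sets, truth = NULL)
    }
  })
  stages$n_genes_input <- nrow(inputs$counts)
  stages$n_samples <- ncol(inputs$counts)

  filtered <- run_stage("filter", log_con, {
    filter_low_expression(inputs$counts, config$min_cpm, config$min_samples)
  })
  stages$n_genes_retained <- nrow(filtered)
  write_counts(filtered, file.path(outdir, "filtered_counts.tsv"))

  norm <- run_stage("normalize", log_con, {
    tmm <- tmm_factors(filtered)
    design <- build_design(inputs$samples, "subset")
    log_cpm_and_weights(filtered, tmm, design)
  })
  write_tsv(data.frame(sample_id = colnames(filtered),
                       lib_size = norm$lib_sizes, tmm_factor = norm$tmm_factors),
            file.path(outdir, "tmm_factors.tsv"))
  write_tsv(data.frame(gene_id = rownames(norm$log_cpm), norm$log_cpm,
                       check.names = FALSE),
            file.path(outdir, "log_cpm.tsv"))

  subsets <- ALL_SUBSETS[ALL_SUBSETS %in% inputs$samples$subset]
  fits <- run_stage("fit", log_con, {
    subset_design <- build_design(inputs$samples, "subset")
    lineage_design <- build_design(inputs$samples, "lineage")
    list(subset = fit_models(norm, subset_design),
         lineage = fit_models(norm, lineage_design))
  })

  contrasts <- run_stage("contrasts", log_con, {
    tabs <- list()
    tabs[["total_ILC_vs_Th"]] <-
      test_contrast(fits$lineage, c(ILC = 1, Th = -1))
    for (pr in utils::combn(subsets, 2, simplify = FALSE)) {
      nm <- paste(pr[1L], pr[2L], sep = "_vs_")
      ctr <- stats::setNames(c(1, -1), pr)
      tabs[[nm]] <- test_contrast(fits$subset, ctr)
    }
    tabs
  })
  for (nm in names(contrasts)) {
    write_contrast_table(contrasts[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))
  }
  mirror_names <- vapply(MIRROR_PAIRS, function(p) paste(p, collapse = "_vs_"),
                         character(1))
  mirror_names <- mirror_names[mirror_names %in% names(contrasts)]
  desum <- de_summary(contrasts[names(contrasts) != "total_ILC_vs_Th"],
                      alpha = config$alpha)
  write_tsv(desum$counts, file.path(outdir, "de_summary.tsv"))
  if (!is.null(desum$up_matrix)) {
    write_tsv(data.frame(subset = rownames(desum$up_matrix), desum$up_matrix,
                         check.names = FALSE),
              file.path(outdir, "de_up_matrix.tsv"))
    write_tsv(data.frame(subset = rownames(desum$down_matrix), desum$down_matrix,
                         check.names = FALSE),
              file.path(outdir, "de_down_matrix.tsv"))
  }
  stages$n_de_total <- sum(contrasts$total_ILC_vs_Th$adj_p < config$alpha)

  gsea_tabs <- NULL
  if (!is.null(inputs$sets)) {
    gsea_tabs <- run_stage("gsea", log_con, {
      comparisons <- c("total_ILC_vs_Th", mirror_names)
      out <- list()
      for (nm in comparisons) {
        ranked <- rank_genes(contrasts[[nm]])
        out[[nm]] <- gsea_run(ranked, inputs$sets, config$gsea)
      }
      out
    })
    for (nm in names(gsea_tabs)) {
      write_gsea_table(gsea_tabs[[nm]], file.path(outdir, paste0("gsea_", nm, ".tsv")))
    }
    if (length(mirror_names) >= 2) {
      venn <- shared_enriched_sets(gsea_tabs[mirror_names], alpha = config$alpha)
      write_tsv(venn, file.path(outdir, "venn_regions.tsv"))
    }
    stages$n_gsea_sets <- length(inputs$sets)
  }

  sigs <- run_stage("signatures", log_con, {
    pairwise <- contrasts[names(contrasts) != "total_ILC_vs_Th"]
    subset_signatures(pairwise, alpha = config$alpha, subsets = subsets)
  })
  spider <- spider_values(sigs, norm, inputs$samples)
  sig_df <- data.frame(
    subset = rep(names(sigs$members), lengths(sigs$members)),
    gene_id = unlist(sigs$members, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(sig_df, file.path(outdir, "signatures.tsv"))
  write_tsv(data.frame(signature = rownames(spider), spider, check.names = FALSE),
            file.path(outdir, "spider.tsv"))
  stages$signature_sizes <- as.list(lengths(sigs$members))

  pca <- run_stage("pca", log_con, {
    pca_top_variable(norm, n_top = config$n_top)
  })
  write_tsv(data.frame(component = seq_along(pca$var_fraction),
                       var_fraction = pca$var_fraction, cum_var = pca$cum_var),
            file.path(outdir, "pca_variance.tsv"))
  write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores,
                       check.names = FALSE),
            file.path(outdir, "pca_scores.tsv"))

  if (config$lncrna_biotype %in% inputs$annotation$biotype) {
    lnc <- run_stage("lncrna", log_con, {
      out <- list()
      for (nm in mirror_names) {
        out[[nm]] <- biotype_subset(contrasts[[nm]], inputs$annotation,
                                    config$lncrna_biotype)
      }
      out
    })
    for (nm in names(lnc)) {
      write_contrast_table(lnc[[nm]], file.path(outdir, paste0("lncrna_", nm, ".tsv")))
    }
    stages$n_lncrna_de <- as.list(stats::setNames(
      vapply(lnc, function(tb) sum(tb$adj_p < config$alpha), numeric(1)),
      names(lnc)))
  }

  manifest <- run_stage("manifest", log_con, {
    files <- sort(setdiff(list.files(outdir), c("run.log", "manifest.json",
                                                "report.txt")))
    hashes <- as.list(tools::md5sum(file.path(outdir, files)))
    names(hashes) <- files
    m <- list(package = "ilcmirror",
              version = as.character(utils::packageVersion("ilcmirror")),
              seed = config$seed,
              stage_seeds = list(simulation = config$seed + 101L,
                                 genesets = config$seed + 202L,
                                 gsea = config$seed + 303L),
              alpha = config$alpha,
              simulated_inputs = simulated,
              stages = stages,
              files = hashes)
    jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })
  make_report(outdir)
  invisible(manifest)
}

#' Assemble the numeric report of a completed run
#'
#' Reads the tables a [run_pipeline()] run wrote under `outdir` and composes
#' the numeric companions of the study's displays: the pairwise
#' differential-expression count matrix, Venn region counts of shared
#' up-enriched sets, the NES x adjusted-p dot matrix per comparison,
#' signature sizes with the spider matrix, and per-comparison lncRNA counts.
#' Regenerating the report from the same directory is idempotent.
#'
#' @param outdir directory of a completed run.
#' @return The report as a list, invisibly; also written to `report.txt`.
#' @export
make_report <- function(outdir) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_ilc("incomplete run: no manifest at %s", manifest_path)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  grab <- function(name) {
    p <- file.path(outdir, name)
    if (file.exists(p)) utils::read.delim(p, check.names = FALSE,
                                          stringsAsFactors = FALSE) else NULL
  }
  report <- list(seed = manifest$seed, stages = manifest$stages)
  lines <- c("ilcmirror run report",
             sprintf("seed: %s", manifest$seed),
             sprintf("genes retained after cpm filter: %s",
                     manifest$stages$n_genes_retained), "")

  de <- grab("de_summary.tsv")
  if (!is.null(de)) {
    report$de_counts <- de
    lines <- c(lines, "Differentially expressed genes per comparison (up / down):",
               sprintf("  %-16s %5d / %d", de$comparison, de$n_up, de$n_down), "")
  }
  up <- grab("de_up_matrix.tsv")
  if (!is.null(up)) {
    report$up_matrix <- up
    lines <- c(lines, "Pairwise up-regulated gene counts (column subset vs row subset):",
               utils::capture.output(print(up, row.names = FALSE)), "")
  }
  venn <- grab("venn_regions.tsv")
  if (!is.null(venn)) {
    report$venn <- venn
    lines <- c(lines, "Shared up-enriched gene sets across mirror comparisons:",
               sprintf("  %-40s %d", venn$region, venn$n), "")
  }
  gsea_files <- list.files(outdir, pattern = "^gsea_.*\\.tsv$")
  if (length(gsea_files)) {
    dots <- list()
    for (f in gsea_files) {
      g <- grab(f)
      nm <- sub("^gsea_(.*)\\.tsv$", "\\1", f)
      gup <- g[g$direction == "up", c("set", "nes", "adj_p")]
      names(gup) <- c("set", paste0("nes_", nm), paste0("adj_p_", nm))
      dots[[nm]] <- gup
      lines <- c(lines, sprintf("GSEA %s: %d / %d sets up-enriched at adj_p < %s",
                                nm, sum(g$adj_p < manifest$alpha & g$direction == "up"),
                                length(unique(g$set)), format(manifest$alpha)))
    }
    dot <- Reduce(function(a, b) merge(a, b, by = "set", all = TRUE), dots)
    dot <- dot[order(dot$set), , drop = FALSE]
    write_tsv(dot, file.path(outdir, "nes_dot_matrix.tsv"))
    report$nes_dot_matrix <- dot
    lines <- c(lines, "")
  }
  sig <- grab("signatures.tsv")
  spider <- grab("spider.tsv")
  if (!is.null(sig)) {
    sizes <- table(factor(sig$subset, levels = unique(sig$subset)))
    report$signature_sizes <- as.list(sizes)
    lines <- c(lines, "Signature sizes (genes up vs all other subsets):",
               sprintf("  %-5s %d", names(sizes), as.integer(sizes)), "")
  }
  if (!is.null(spider)) {
    report$spider <- spider
    lines <- c(lines, "Spider matrix (mean log2 normalized cpm of each signature per subset):",
               utils::capture.output(print(spider, row.names = FALSE)), "")
  }
  pca <- grab("pca_variance.tsv")
  if (!is.null(pca)) {
    report$pca_variance <- pca
    k <- min(3, nrow(pca))
    lines <- c(lines,
               sprintf("PCA: PC1 explains %.1f%%; first %d PCs %.1f%% of variance",
                       100 * pca$var_fraction[1], k, 100 * pca$cum_var[k]), "")
  }
  lnc_files <- list.files(outdir, pattern = "^lncrna_.*\\.tsv$")
  if (length(lnc_files)) {
    ln <- vapply(lnc_files, function(f) {
      tb <- grab(f)
      sum(tb$adj_p < manifest$alpha)
    }, numeric(1))
    names(ln) <- sub("^lncrna_(.*)\\.tsv$", "\\1", lnc_files)
    report$lncrna_de <- as.list(ln)
    lines <- c(lines, "Differentially expressed lncRNAs per mirror comparison:",
               sprintf("  %-16s %d", names(ln), ln), "")
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(report)
}
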