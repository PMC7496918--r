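# Subset signatures and spider summaries, heatmap z-score matrices with
# clustering order, PCA on top-variable genes, and biotype sub-tables.

#' Per-subset gene signatures
#'
#' A gene belongs to the signature of subset S iff it is overexpressed in S
#' relative to every other subset: `adj_p < alpha` and estimate > 0 (oriented
#' S minus T) in all five pairwise comparisons. By this conjunction the six
#' signatures are necessarily disjoint (asserted).
#'
#' @param pairwise named list of contrast tables covering all 15 unordered
#'   subset pairs, names `"A_vs_B"` with the estimate oriented A minus B
#'   (the reversed orientation is derived by sign flip). Ordered duplicates
#'   are allowed.
#' @param alpha adjusted-p threshold.
#' @param subsets subset labels to build signatures for.
#' @return Object of class `signature_set`: list with `members` (named list
#'   of gene-id vectors) and `alpha`.
#' @export
subset_signatures <- function(pairwise, alpha = 0.05, subsets = ALL_SUBSETS) {
  if (is.null(names(pairwise))) stop_ilc("pairwise must be a named list")
  parsed <- strsplit(names(pairwise), "_vs_", fixed = TRUE)
  directed <- new.env(parent = emptyenv())
  for (i in seq_along(parsed)) {
    pr <- parsed[[i]]
    if (length(pr) != 2 || !all(pr %in% subsets)) {
      stop_ilc("cannot parse comparison name '%s' (expected '<subset>_vs_<subset>')",
               names(pairwise)[i])
    }
    tb <- pairwise[[i]]
    assign(paste(pr[1L], pr[2L], sep = "|"), tb, envir = directed)
    rev_tb <- tb
    rev_tb$log2fc <- -rev_tb$log2fc
    rev_tb$t <- -rev_tb$t
    assign(paste(pr[2L], pr[1L], sep = "|"), rev_tb, envir = directed)
  }
  members <- stats::setNames(vector("list", length(subsets)), subsets)
  for (s in subsets) {
    keep <- NULL
    for (t in setdiff(subsets, s)) {
      key <- paste(s, t, sep = "|")
      if (!exists(key, envir = directed)) {
        stop_ilc("missing pairwise comparison %s vs %s", s, t)
      }
      tb <- get(key, envir = directed)
      hit <- tb$gene_id[tb$adj_p < alpha & tb$log2fc > 0]
      keep <- if (is.null(keep)) hit else intersect(keep, hit)
    }
    members[[s]] <- sort(keep)
  }
  overlap <- unlist(members)
  if (anyDuplicated(overlap)) {
    stop_ilc("internal error: signatures are not disjoint (gene '%s')",
             overlap[duplicated(overlap)][1L])
  }
  structure(list(members = members, alpha = alpha), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("signature_set (genes up vs all other subsets, adj_p <",
      format(x$alpha), "):\n")
  for (s in names(sizes)) cat(sprintf("  %-5s %d genes\n", s, sizes[s]))
  invisible(x)
}

#' Spider-chart matrix of signature expression
#'
#' Entry (signature, subset) is the mean log2 normalized cpm over the
#' signature's genes and the subset's samples — the radial coordinates of
#' the spider chart. Empty signatures yield a row of NA.
#'
#' @param signatures a `signature_set`.
#' @param norm a `normalized_matrix`.
#' @param samples sample table aligned to `norm`'s columns.
#' @return Numeric matrix, signatures x subsets.
#' @export
spider_values <- function(signatures, norm, samples) {
  samples <- align_samples(samples, norm$log_cpm)
  subsets <- names(signatures$members)
  out <- matrix(NA_real_, length(subsets), length(subsets),
                dimnames = list(signature = subsets, subset = subsets))
  for (sig in subsets) {
    genes <- intersect(signatures$members[[sig]], rownames(norm$log_cpm))
    if (!length(genes)) next
    for (s in subsets) {
      cols <- samples$sample_id[samples$subset == s]
      out[sig, s] <- mean(norm$log_cpm[genes, cols, drop = FALSE])
    }
  }
  out
}

#' Row z-scores
#'
#' Centers and scales each row to mean 0 and unit sample (n-1) standard
#' deviation; constant rows map to 0.
#'
#' @param m numeric matrix.
#' @return Matrix of the same shape.
#' @export
row_zscores <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop_ilc("m must be a numeric matrix")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Hierarchical clustering row order for heatmaps
#'
#' Complete-linkage agglomeration on Euclidean distances between rows;
#' returns the leaf order. Deterministic for fixed input (stats::hclust ties
#' resolve by row index).
#'
#' @param zmatrix numeric matrix (>= 2 rows), typically from [row_zscores()].
#' @return Integer row permutation.
#' @export
cluster_order <- function(zmatrix) {
  if (nrow(zmatrix) < 2) stop_ilc("clustering needs >= 2 rows")
  stats::hclust(stats::dist(zmatrix, method = "euclidean"),
                method = "complete")$order
}

#' PCA on the top-variable genes
#'
#' Selects the `n_top` genes with highest log2-cpm variance across all
#' samples, centers each gene (no unit scaling by default), and performs PCA
#' by SVD over samples.
#'
#' @param norm a `normalized_matrix` (or list with a `log_cpm` matrix).
#' @param n_top number of genes to keep (>= 2; capped at the gene count).
#' @param scale. also scale genes to unit variance before the SVD.
#' @param n_loadings number of top contributing genes reported per component.
#' @return Object of class `pca_summary`: `scores` (samples x components),
#'   `var_fraction`, `cum_var`, `genes` (the selected genes),
#'   `contributions` (list per component: named vector of squared-loading
#'   fractions for the top genes).
#' @export
pca_top_variable <- function(norm, n_top = 500, scale. = FALSE,
                             n_loadings = 50) {
  x <- norm$log_cpm
  if (is.null(x)) stop_ilc("norm must carry a log_cpm matrix")
  if (n_top < 2) stop_ilc("n_top must be >= 2")
  n_top <- min(n_top, nrow(x))
  v <- apply(x, 1, stats::var)
  top <- order(-v, seq_along(v))[seq_len(n_top)]
  sel <- x[top, , drop = FALSE]
  pr <- stats::prcomp(t(sel), center = TRUE, scale. = scale.)
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  contributions <- lapply(seq_len(ncol(pr$rotation)), function(j) {
    contr <- pr$rotation[, j]^2
    sort(contr, decreasing = TRUE)[seq_len(min(n_loadings, length(contr)))]
  })
  names(contributions) <- colnames(pr$x)
  structure(list(scores = pr$x, var_fraction = var_frac,
                 cum_var = cumsum(var_frac), genes = rownames(sel),
                 contributions = contributions),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  k <- min(5, length(x$var_fraction))
  cat(sprintf("pca_summary: %d samples, %d genes\n",
              nrow(x$scores), length(x$genes)))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  cat(sprintf("  cumulative over %d PCs: %.1f%%\n", k, 100 * x$cum_var[k]))
  invisible(x)
}

#' Restrict a contrast table to one annotation biotype
#'
#' Rows are restricted to genes carrying the requested biotype. Adjusted
#' p-values are NOT recomputed: the sub-table is read out of the genome-wide
#' BH adjustment, as when lncRNAs are extracted from a global DE table.
#'
#' @param table a contrast table.
#' @param annotation annotation data.frame (gene_id, symbol, biotype).
#' @param biotype biotype label to keep (default "lncRNA").
#' @return The restricted contrast table.
#' @export
biotype_subset <- function(table, annotation, biotype = "lncRNA") {
  available <- unique(annotation$biotype)
  # "lncRNA" is always a recognized class: absent from the annotation it
  # selects an empty table rather than raising an unknown-label error
  if (!biotype %in% c(available, "lncRNA")) {
    stop_ilc("unknown biotype '%s'; available: %s", biotype,
             paste(sort(available), collapse = ", "))
  }
  idx <- match(table$gene_id, annotation$gene_id)
  if (anyNA(idx)) {
    warning(sprintf("%d gene(s) missing from the annotation were dropped",
                    sum(is.na(idx))), call. = FALSE)
  }
  keep <- !is.na(idx) & annotation$biotype[idx] == biotype
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative qPCR expression by the 2^-deltaCt method
#'
#' `2^-(mean(ct_target) - mean(ct_reference))`: expression of a target gene
#' relative to a housekeeping reference, from replicate cycle-threshold
#' measurements.
#'
#' @param ct_target,ct_reference replicate Ct values (typically triplicates),
#'   each in (0, 45), no missing values.
#' @return Relative expression (one number).
#' @export
qpcr_delta_ct <- function(ct_target, ct_reference) {
  for (ct in list(target = ct_target, reference = ct_reference)) {
    if (!length(ct) || anyNA(ct)) stop_ilc("Ct replicates must be complete")
    if (any(ct <= 0 | ct >= 45)) stop_ilc("Ct values must lie in (0, 45)")
  }
  2^-(mean(ct_target) - mean(ct_reference))
}
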