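# Filtering, TMM scaling factors, log2-cpm and voom precision weights.

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / colsum[s] * 1e6`, using raw library sizes
#' (no TMM rescaling) — the scale on which the expression filter is defined.
#'
#' @param counts integer matrix, genes x samples.
#' @return Numeric matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  check_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop_ilc("zero library size for sample '%s'", colnames(counts)[lib == 0][1L])
  }
  t(t(counts) / lib) * 1e6
}

#' Filter genes by minimum expression
#'
#' Retains genes expressed at `>= min_cpm` counts per million in at least
#' `min_samples` samples (boundary inclusive); the defaults reproduce the
#' "at least 1 cpm in at least 1 sample" rule. Gene order is preserved.
#'
#' @param counts integer matrix, genes x samples.
#' @param min_cpm cpm threshold (inclusive).
#' @param min_samples minimum number of samples meeting the threshold.
#' @return The filtered count matrix (possibly with zero rows).
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 1) {
  cpm <- compute_cpm(counts)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Per-sample scaling factors from the trimmed mean of M-values: gene-wise
#' log2 abundance ratios against a reference sample are trimmed (30% on M,
#' 5% on A) and averaged with inverse delta-method variance weights; genes
#' with a zero count in either sample are excluded. Factors are rescaled to
#' geometric mean 1. Computation is delegated to the edgeR implementation of
#' the method.
#'
#' @param counts integer matrix, genes x samples (>= 2 samples), ideally
#'   already expression-filtered.
#' @return Numeric vector of factors, one per sample, named by sample.
#' @export
tmm_factors <- function(counts) {
  check_count_matrix(counts)
  if (ncol(counts) < 2) stop_ilc("TMM needs at least 2 samples")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' Log2-cpm transformation with voom precision weights
#'
#' Computes `log2((count + 0.5) / (lib_size * tmm_factor + 1) * 1e6)` and the
#' voom observation weights: gene-wise means and residual standard deviations
#' under `design` are fitted, the sqrt-sd vs mean log-count trend is smoothed
#' by lowess (span 0.5), and each observation receives weight
#' `predicted_sd^-4`. Delegated to the limma voom implementation.
#'
#' @param counts filtered integer count matrix.
#' @param tmm TMM factors from [tmm_factors()] (geometric mean 1).
#' @param design design matrix from [build_design()]; the weights are fitted
#'   once under this design.
#' @return An object of class `normalized_matrix`: list with `log_cpm`,
#'   `weights` (same shape), `tmm_factors`, `lib_sizes`.
#' @export
log_cpm_and_weights <- function(counts, tmm, design) {
  check_count_matrix(counts)
  if (length(tmm) != ncol(counts) || any(tmm <= 0)) {
    stop_ilc("tmm must hold one positive factor per sample")
  }
  if (nrow(design) != ncol(counts)) {
    stop_ilc("design rows (%d) must match samples (%d)", nrow(design), ncol(counts))
  }
  if (nrow(design) - qr(design)$rank < 1) {
    stop_ilc("design leaves zero residual degrees of freedom")
  }
  lib <- colSums(counts)
  v <- limma::voom(counts, design = design, lib.size = lib * tmm)
  out <- list(log_cpm = v$E, weights = v$weights,
              tmm_factors = tmm, lib_sizes = lib)
  dimnames(out$weights) <- dimnames(out$log_cpm)
  class(out) <- "normalized_matrix"
  out
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (log2 cpm + voom weights)\n",
              nrow(x$log_cpm), ncol(x$log_cpm)))
  cat(sprintf("  TMM factors: %s\n",
              paste(sprintf("%.3f", x$tmm_factors), collapse = " ")))
  invisible(x)
}
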