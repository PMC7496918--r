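# Gene-wise weighted linear models, empirical-Bayes moderated t contrasts,
# and Benjamini-Hochberg adjustment: the differential-expression engine.

D0_CAP <- 1e7  # prior df treated as "infinite" beyond this

#' Build a group-means design matrix
#'
#' One indicator column per group, no intercept. `grouping = "subset"` uses
#' the six cell-subset labels; `grouping = "lineage"` collapses
#' ILC1/ILC2/ILCP to "ILC" and Th1/Th2/Th17 to "Th" for the total-ILC vs
#' total-Th comparison.
#'
#' @param samples sample table (sample_id, subset, donor).
#' @param grouping `"subset"` or `"lineage"`.
#' @return Design matrix, samples x groups, with group column names.
#' @export
build_design <- function(samples, grouping = c("subset", "lineage")) {
  grouping <- match.arg(grouping)
  check_samples(samples)
  g <- as.character(samples$subset)
  if (grouping == "lineage") {
    g <- ifelse(g %in% ILC_SUBSETS, "ILC", "Th")
    levels <- c("ILC", "Th")
  } else {
    levels <- ALL_SUBSETS[ALL_SUBSETS %in% g]
  }
  counts <- table(factor(g, levels = levels))
  if (any(counts == 0)) {
    stop_ilc("group(s) with zero samples: %s",
             paste(names(counts)[counts == 0], collapse = ", "))
  }
  f <- factor(g, levels = levels)
  design <- stats::model.matrix(~ 0 + f)
  colnames(design) <- levels
  rownames(design) <- samples$sample_id
  if (qr(design)$rank < ncol(design)) stop_ilc("design is not of full rank")
  design
}

#' Fit gene-wise weighted linear models with EB variance shrinkage
#'
#' Fits each gene by weighted least squares under the voom weights, then
#' shrinks the gene-wise residual variances `s2_g` toward a common prior:
#' hyperparameters `(d0, s02)` are estimated by moment matching of
#' `log(s2_g)` against the scaled-F distribution they imply, and the
#' posterior variance is `s2_post = (d0*s02 + df*s2) / (d0 + df)`. The WLS
#' fits and the hyperparameter estimation are delegated to the limma
#' implementations (lmFit, squeezeVar).
#'
#' @param norm a `normalized_matrix` from [log_cpm_and_weights()], or any list
#'   with `log_cpm` and `weights` matrices.
#' @param design group-means design from [build_design()].
#' @return Object of class `gene_fit`: coefficients (genes x groups),
#'   stdev_unscaled, sigma2, df_residual, d0 (prior df, capped at 1e7),
#'   s02 (prior variance), s2_post, design.
#' @export
fit_models <- function(norm, design) {
  if (!is.list(norm) || is.null(norm$log_cpm) || is.null(norm$weights)) {
    stop_ilc("norm must carry log_cpm and weights matrices")
  }
  if (qr(design)$rank < ncol(design)) stop_ilc("design is rank-deficient")
  df_resid <- nrow(design) - ncol(design)
  if (df_resid < 1) stop_ilc("no residual degrees of freedom")
  fit <- limma::lmFit(norm$log_cpm, design, weights = norm$weights)
  eb <- estimate_eb_prior(fit$sigma^2, fit$df.residual)
  out <- list(coefficients = fit$coefficients,
              stdev_unscaled = fit$stdev.unscaled,
              sigma2 = fit$sigma^2,
              df_residual = fit$df.residual,
              d0 = eb$df_prior, s02 = eb$var_prior,
              s2_post = eb$var_post,
              design = design)
  class(out) <- "gene_fit"
  out
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Moment-matching estimate of the prior degrees of freedom `d0` and prior
#' variance `s02` from an ensemble of gene-wise residual variances, plus the
#' per-gene posterior (shrunk) variances. Wraps limma's squeezeVar; an
#' infinite prior df estimate is capped at `1e7`.
#'
#' @param s2 gene-wise residual variances.
#' @param df residual degrees of freedom (scalar or per gene).
#' @return List: `df_prior`, `var_prior`, `var_post`.
#' @export
estimate_eb_prior <- function(s2, df) {
  sq <- limma::squeezeVar(s2, df)
  d0 <- sq$df.prior
  if (length(d0) > 1) d0 <- d0[1L]
  d0 <- min(d0, D0_CAP)
  df_full <- rep_len(df, length(s2))
  var_post <- (d0 * sq$var.prior + df_full * s2) / (d0 + df_full)
  list(df_prior = d0, var_prior = sq$var.prior, var_post = var_post)
}

#' Moderated t-test of a contrast
#'
#' For contrast weights `w` over the design's group coefficients, computes the
#' estimate `w'beta_g`, the moderated t
#' `t_g = estimate / (s_post_g * sqrt(v_g))` with
#' `s2_post = (d0*s02 + df*s2_g)/(d0 + df)`, a two-sided p-value on
#' `d0 + df` degrees of freedom, and BH-adjusted p-values over all genes.
#' `v_g = sum(w^2 * stdev_unscaled^2)` — exact for the group-means designs
#' built by [build_design()], whose indicator columns keep `X'WX` diagonal.
#' `prior_df = 0` gives the ordinary t-statistic; `prior_df = Inf` the fully
#' pooled statistic with variance `s02`.
#'
#' @param fit a `gene_fit`.
#' @param contrast numeric contrast vector (length = number of groups, not all
#'   zero), or a named vector using group names.
#' @param prior_df,prior_var override the fit's EB hyperparameters (defaults:
#'   the estimated `d0`, `s02`).
#' @return A `contrast_table` data.frame: gene_id, log2fc, t, p, adj_p.
#' @export
test_contrast <- function(fit, contrast, prior_df = fit$d0,
                          prior_var = fit$s02) {
  if (!inherits(fit, "gene_fit")) stop_ilc("fit must be a gene_fit object")
  groups <- colnames(fit$coefficients)
  if (!is.null(names(contrast))) {
    w <- stats::setNames(numeric(length(groups)), groups)
    unknown <- setdiff(names(contrast), groups)
    if (length(unknown)) {
      stop_ilc("unknown group(s) in contrast: %s", paste(unknown, collapse = ", "))
    }
    w[names(contrast)] <- contrast
    contrast <- w
  }
  if (length(contrast) != length(groups)) {
    stop_ilc("contrast length (%d) must match number of groups (%d)",
             length(contrast), length(groups))
  }
  if (all(contrast == 0)) stop_ilc("contrast must not be all zero")
  if (prior_df < 0) stop_ilc("prior_df must be >= 0")

  est <- drop(fit$coefficients %*% contrast)
  v_unscaled <- drop(fit$stdev_unscaled^2 %*% contrast^2)
  df <- fit$df_residual
  d0 <- prior_df
  s2_post <- if (d0 == 0) {
    fit$sigma2
  } else if (is.infinite(d0)) {
    rep_len(prior_var, length(fit$sigma2))
  } else {
    (d0 * prior_var + df * fit$sigma2) / (d0 + df)
  }
  tstat <- est / sqrt(s2_post * v_unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = df + d0)
  out <- data.frame(gene_id = rownames(fit$coefficients),
                    log2fc = est, t = tstat, p = p,
                    adj_p = bh_adjust(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment
#' `adj_p(i) = min over j with rank >= rank(i) of min(1, m * p(j) / rank(j))`,
#' computed by `stats::p.adjust(method = "BH")` after range validation.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop_ilc("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Summarize differential-expression counts across comparisons
#'
#' For each named contrast table, counts genes with `adj_p < alpha` split by
#' the sign of the estimate. When the names follow the `"A_vs_B"` convention
#' over the six subsets, the paired-triangle pairwise layout is also emitted:
#' `up_matrix[T, S]` counts genes up-regulated in subset S relative to subset
#' T (read column-wise), and `down_matrix` the mirror.
#'
#' @param tables named list of contrast tables over one shared gene universe.
#' @param alpha adjusted-p threshold.
#' @return List with `counts` (data.frame: comparison, n_up, n_down) and,
#'   when derivable, `up_matrix` / `down_matrix`.
#' @export
de_summary <- function(tables, alpha = 0.05) {
  if (!length(tables) || is.null(names(tables))) {
    stop_ilc("tables must be a named list of contrast tables")
  }
  universe <- sort(tables[[1L]]$gene_id)
  for (nm in names(tables)) {
    if (!identical(sort(tables[[nm]]$gene_id), universe)) {
      stop_ilc("contrast table '%s' has a different gene universe", nm)
    }
  }
  counts <- data.frame(
    comparison = names(tables),
    n_up = vapply(tables, function(tb) {
      sum(tb$adj_p < alpha & tb$log2fc > 0)
    }, numeric(1)),
    n_down = vapply(tables, function(tb) {
      sum(tb$adj_p < alpha & tb$log2fc < 0)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  out <- list(counts = counts, alpha = alpha)
  pairs <- strsplit(names(tables), "_vs_", fixed = TRUE)
  ok <- vapply(pairs, function(p) {
    length(p) == 2 && all(p %in% ALL_SUBSETS)
  }, logical(1))
  if (any(ok)) {
    subs <- ALL_SUBSETS[ALL_SUBSETS %in% unlist(pairs[ok])]
    up <- matrix(NA_real_, length(subs), length(subs),
                 dimnames = list(subs, subs))
    down <- up
    for (i in which(ok)) {
      s <- pairs[[i]][1L]; t <- pairs[[i]][2L]
      up[t, s] <- counts$n_up[i]
      down[t, s] <- counts$n_down[i]
      # the reversed comparison swaps up and down
      up[s, t] <- counts$n_down[i]
      down[s, t] <- counts$n_up[i]
    }
    out$up_matrix <- up
    out$down_matrix <- down
  }
  out
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("gene_fit: %d genes, groups: %s\n",
              nrow(x$coefficients), paste(colnames(x$coefficients), collapse = ", ")))
  cat(sprintf("  residual df: %s; EB prior: d0 = %.4g, s02 = %.4g\n",
              paste(unique(x$df_residual), collapse = "/"), x$d0, x$s02))
  invisible(x)
}

#' @export
summary.gene_fit <- function(object, ...) {
  cat(sprintf("Gene-wise weighted linear model fit on %d genes\n",
              nrow(object$coefficients)))
  cat(sprintf("Groups (%d): %s\n", ncol(object$coefficients),
              paste(colnames(object$coefficients), collapse = ", ")))
  cat(sprintf("Residual df per gene: %s\n",
              paste(unique(object$df_residual), collapse = "/")))
  cat(sprintf("EB variance prior: d0 = %.4g, s02 = %.4g\n", object$d0, object$s02))
  cat("Residual variance quartiles (raw vs shrunk):\n")
  q <- rbind(raw = stats::quantile(object$sigma2),
             shrunk = stats::quantile(object$s2_post))
  print(signif(q, 4))
  invisible(object)
}

#' @export
coef.gene_fit <- function(object, ...) object$coefficients
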