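# Gene-set enrichment with a weighted running-sum score and a gene-label
# permutation null: the score walks the ranked gene list, adding
# |t_i|^P / sum_members(|t|^P) at members and subtracting 1/(N - N_S) at
# non-members; ES_up is the maximum of the running sum, ES_down the minimum.
# The null redraws the member labels uniformly from the ranked universe, the
# NES divides the observed ES by the mean same-direction null ES, and the
# permutation p-value is the proportion of null scores at least as extreme.

#' Rank genes by moderated t-statistic
#'
#' Orders a contrast table by decreasing t, breaking ties by gene id
#' (lexicographic) so the ranking is reproducible.
#'
#' @param table a `contrast_table` from [test_contrast()].
#' @return Named numeric vector of t-statistics, sorted for [gsea_run()].
#' @export
rank_genes <- function(table) {
  if (!all(c("gene_id", "t") %in% names(table))) {
    stop_ilc("table must have gene_id and t columns")
  }
  if (anyDuplicated(table$gene_id)) stop_ilc("duplicate gene ids in table")
  ord <- order(-table$t, table$gene_id, method = "radix")
  stats::setNames(table$t[ord], table$gene_id[ord])
}

check_ranked <- function(ranked) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked))) {
    stop_ilc("ranked list must be named with unique gene ids")
  }
  if (anyNA(ranked)) stop_ilc("ranked list contains missing t values")
  if (is.unsorted(rev(ranked))) stop_ilc("ranked list must be sorted by decreasing t")
  invisible(ranked)
}

# ES pair from member positions in the ranked list. `aw` = |t|^P over the
# whole list. O(k): the running sum is piecewise linear between hits, so the
# maximum is attained at a hit and the minimum just before a hit (or at the
# endpoints, where the sum is 0).
es_from_positions <- function(aw, pos, N) {
  pos <- sort.int(pos)
  k <- length(pos)
  w <- aw[pos]
  sw <- sum(w)
  W <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  miss <- (pos - seq_len(k)) / (N - k)
  c(es_up = max(0, W - miss), es_down = min(0, c(0, W[-k]) - miss))
}

#' Weighted running-sum enrichment score
#'
#' @param ranked named t-statistic vector from [rank_genes()].
#' @param geneset character vector of member gene ids; must intersect the
#'   ranked universe and must not equal it (the miss penalty `1/(N - N_S)`
#'   would be undefined).
#' @param P weight exponent on `|t|` (P = 0 reduces to the classic
#'   Kolmogorov-Smirnov statistic on member ranks; P = 1 weights each hit by
#'   the magnitude of its t-statistic).
#' @return Named vector `c(es_up, es_down)` with `es_up` in \[0, 1\] and
#'   `es_down` in \[-1, 0\].
#' @export
enrichment_score <- function(ranked, geneset, P = 1) {
  check_ranked(ranked)
  if (P < 0) stop_ilc("P must be >= 0")
  pos <- which(names(ranked) %in% geneset)
  N <- length(ranked)
  if (!length(pos)) stop_ilc("gene set has empty intersection with the ranked universe")
  if (length(pos) == N) {
    stop_ilc("gene set covers the entire ranked universe; miss penalty undefined")
  }
  es_from_positions(abs(ranked)^P, pos, N)
}

#' Gene-label permutation null for the enrichment score
#'
#' Draws `n` member sets of `set_size` genes uniformly without replacement
#' from the ranked universe and computes the ES pair for each.
#'
#' @param ranked named t-statistic vector from [rank_genes()].
#' @param set_size number of members per draw (`1 <= set_size < N`).
#' @param P weight exponent.
#' @param n number of permutations.
#' @param seed integer seed; draws are reproducible.
#' @return `n` x 2 matrix with columns `es_up`, `es_down`.
#' @export
permutation_null <- function(ranked, set_size, P = 1, n = 1000, seed = 1L) {
  check_ranked(ranked)
  N <- length(ranked)
  if (set_size < 1 || set_size >= N) {
    stop_ilc("set_size must lie in [1, %d]", N - 1)
  }
  if (n < 1) stop_ilc("n must be >= 1")
  aw <- abs(ranked)^P
  with_seed(seed, {
    out <- matrix(0, n, 2, dimnames = list(NULL, c("es_up", "es_down")))
    for (i in seq_len(n)) {
      out[i, ] <- es_from_positions(aw, sample.int(N, set_size), N)
    }
    out
  })
}

#' Normalized enrichment score and permutation p-value
#'
#' `NES = ES / mean(null ES of the same direction)`; the p-value is the
#' proportion of null scores at least as extreme as the observed one
#' (higher for the up direction, lower for down). By default the add-one
#' estimator `(1 + extreme) / (1 + n)` is used so p is never exactly 0; set
#' `add_one = FALSE` for the raw proportion.
#'
#' @param observed observed ES (one number, sign matching `direction`).
#' @param null null ES sample: the matrix from [permutation_null()] or a
#'   numeric vector of same-direction null scores.
#' @param direction `"up"` or `"down"`.
#' @param add_one logical; use the permutation-inclusive p estimator.
#' @return List with `nes` and `p`.
#' @export
nes_and_pvalue <- function(observed, null, direction = c("up", "down"),
                           add_one = TRUE) {
  direction <- match.arg(direction)
  if (is.matrix(null)) {
    null <- null[, if (direction == "up") "es_up" else "es_down"]
  }
  if (!length(null)) stop_ilc("null sample is empty")
  m <- mean(null)
  if (!is.finite(m) || m == 0) {
    stop_ilc("degenerate null: mean %s ES is zero", direction)
  }
  extreme <- if (direction == "up") sum(null >= observed) else sum(null <= observed)
  p <- if (add_one) (1 + extreme) / (1 + length(null)) else extreme / length(null)
  list(nes = observed / m, p = p)
}

#' GSEA configuration
#'
#' @param weight_exponent exponent P on `|t|` in the running sum.
#' @param n_permutations gene-label randomizations per set size.
#' @param seed integer seed for the permutation draws.
#' @param alpha significance threshold on BH-adjusted permutation p-values.
#' @param shared_null reuse one null distribution per set size within a run
#'   (identical in law by exchangeability of the uniform draws; large
#'   speedup).
#' @param add_one use the add-one permutation p estimator (see
#'   [nes_and_pvalue()]).
#' @return List of class `gsea_config`.
#' @export
gsea_config <- function(weight_exponent = 1, n_permutations = 1000, seed = 1L,
                        alpha = 0.05, shared_null = TRUE, add_one = TRUE) {
  if (weight_exponent < 0) stop_ilc("weight_exponent must be >= 0")
  if (n_permutations < 1) stop_ilc("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_ilc("alpha must lie in (0, 1)")
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alpha = alpha,
                 shared_null = isTRUE(shared_null),
                 add_one = isTRUE(add_one)),
            class = "gsea_config")
}

#' Run GSEA over a gene-set collection
#'
#' Each set is intersected with the ranked universe (sets left empty are
#' skipped with a warning); for every retained set an ES is computed for the
#' up and down directions separately, normalized against the gene-label
#' permutation null for its size, and assigned a directional permutation
#' p-value. BH adjustment is applied across all (set, direction) tests in
#' the run.
#'
#' @param ranked named t-statistic vector from [rank_genes()].
#' @param sets a `geneset_collection` (named list of gene-id vectors).
#' @param config a [gsea_config()].
#' @return data.frame of class `gsea_result`: set, size, direction, es, nes,
#'   p, adj_p — two rows (up, down) per usable set.
#' @export
gsea_run <- function(ranked, sets, config = gsea_config()) {
  check_ranked(ranked)
  if (!length(sets) || is.null(names(sets))) {
    stop_ilc("sets must be a non-empty named list")
  }
  P <- config$weight_exponent
  universe <- names(ranked)
  members <- lapply(sets, function(s) intersect(universe, s))
  sizes <- lengths(members)
  empty <- sizes == 0
  if (any(empty)) {
    warning(sprintf("%d gene set(s) had no genes in the ranked universe and were skipped",
                    sum(empty)), call. = FALSE)
    members <- members[!empty]
    sizes <- sizes[!empty]
  }
  if (!length(members)) stop_ilc("no usable gene sets after universe intersection")

  aw <- abs(ranked)^P
  N <- length(ranked)
  nulls <- if (config$shared_null) {
    u <- sort(unique(sizes))
    stats::setNames(lapply(u, function(k) {
      permutation_null(ranked, k, P = P, n = config$n_permutations,
                       seed = config$seed + k)
    }), as.character(u))
  } else NULL

  rows <- vector("list", length(members))
  for (i in seq_along(members)) {
    pos <- which(universe %in% members[[i]])
    if (length(pos) == N) {
      stop_ilc("gene set '%s' covers the entire ranked universe", names(members)[i])
    }
    es <- es_from_positions(aw, pos, N)
    null <- if (config$shared_null) nulls[[as.character(sizes[i])]] else {
      permutation_null(ranked, sizes[i], P = P, n = config$n_permutations,
                       seed = config$seed + i)
    }
    up <- nes_and_pvalue(es[["es_up"]], null, "up", add_one = config$add_one)
    dn <- nes_and_pvalue(es[["es_down"]], null, "down", add_one = config$add_one)
    rows[[i]] <- data.frame(
      set = names(members)[i], size = unname(sizes[i]),
      direction = c("up", "down"),
      es = c(es[["es_up"]], es[["es_down"]]),
      nes = c(up$nes, dn$nes), p = c(up$p, dn$p),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Venn partition of significantly up-enriched sets across comparisons
#'
#' For two or more GSEA result tables, finds the gene sets significantly
#' enriched in up-regulated genes (`direction == "up"`, `adj_p < alpha`,
#' `NES > 0`) in each comparison and partitions their union by the exact
#' combination of comparisons each set is significant in.
#'
#' @param results named list (>= 2) of `gsea_result` tables.
#' @param alpha adjusted-p threshold.
#' @return data.frame: `region` (comparison names joined by `&`), `n`, and
#'   `sets` (comma-separated set names); one row per non-empty combination,
#'   including empty regions with n = 0.
#' @export
shared_enriched_sets <- function(results, alpha = 0.05) {
  if (length(results) < 2 || is.null(names(results))) {
    stop_ilc("results must be a named list of >= 2 GSEA tables")
  }
  sig <- lapply(results, function(r) {
    unique(r$set[r$direction == "up" & r$adj_p < alpha & r$nes > 0])
  })
  all_sets <- sort(unique(unlist(sig)))
  nms <- names(results)
  key <- vapply(all_sets, function(s) {
    paste(nms[vapply(sig, function(x) s %in% x, logical(1))], collapse = " & ")
  }, character(1))
  combos <- unlist(lapply(seq_along(nms), function(k) {
    apply(utils::combn(nms, k), 2, paste, collapse = " & ")
  }))
  out <- data.frame(region = combos,
                    n = vapply(combos, function(cb) sum(key == cb), numeric(1)),
                    sets = vapply(combos, function(cb) {
                      paste(all_sets[key == cb], collapse = ",")
                    }, character(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
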