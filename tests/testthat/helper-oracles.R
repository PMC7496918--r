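# Independent reference implementations used as oracles. These are written
# directly from the definitions of each procedure and deliberately share no
# code with the package internals.

# Running-sum enrichment score by explicit walk over the ranked list.
oracle_es <- function(ranked, geneset, P = 1) {
  N <- length(ranked)
  is_member <- names(ranked) %in% geneset
  k <- sum(is_member)
  stopifnot(k > 0, k < N)
  w <- abs(ranked)^P
  denom <- sum(w[is_member])
  running <- 0
  es_up <- 0
  es_down <- 0
  for (i in seq_len(N)) {
    running <- running + if (is_member[i]) {
      if (denom > 0) w[i] / denom else 1 / k
    } else {
      -1 / (N - k)
    }
    es_up <- max(es_up, running)
    es_down <- min(es_down, running)
  }
  c(es_up = es_up, es_down = es_down)
}

# Step-by-step TMM factors, coded from the published definition: M/A values
# against a reference sample (upper-quartile cpm closest to the mean), 30%
# trim on M and 5% on A, inverse delta-method variance weights, factors
# rescaled to geometric mean 1.
oracle_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    unname(stats::quantile(counts[, j] / lib[j], 0.75))
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  one_factor <- function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    keep <- obs > 0 & rf > 0
    obs <- obs[keep]; rf <- rf[keep]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (rf / nR))
    A <- 0.5 * log2((obs / nO) * (rf / nR))
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Benjamini-Hochberg step-up, direct evaluation of
# adj_p(i) = min_{j : p_j >= p_i} min(1, m * p_j / rank_j).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# Ordinary (unmoderated) contrast t per gene by explicit weighted LS.
oracle_ordinary_t <- function(y, w, design, contrast) {
  n_gene <- nrow(y)
  out <- matrix(NA_real_, n_gene, 3,
                dimnames = list(rownames(y), c("est", "t", "p")))
  df <- nrow(design) - ncol(design)
  for (g in seq_len(n_gene)) {
    wg <- w[g, ]
    xtx <- crossprod(design * wg, design)
    beta <- solve(xtx, crossprod(design * wg, y[g, ]))
    resid <- y[g, ] - design %*% beta
    s2 <- sum(wg * resid^2) / df
    v <- drop(t(contrast) %*% solve(xtx) %*% contrast)
    est <- drop(crossprod(contrast, beta))
    tval <- est / sqrt(s2 * v)
    out[g, ] <- c(est, tval, 2 * stats::pt(-abs(tval), df))
  }
  out
}

# Naive complete-linkage agglomeration; returns sorted merge heights.
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}
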