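# Internal helpers shared across modules.

ILC_SUBSETS <- c("ILC1", "ILC2", "ILCP")
TH_SUBSETS <- c("Th1", "Th2", "Th17")
ALL_SUBSETS <- c(ILC_SUBSETS, TH_SUBSETS)
MIRROR_PAIRS <- list(c("ILC1", "Th1"), c("ILC2", "Th2"), c("ILCP", "Th17"))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

stop_ilc <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_count_matrix <- function(counts, what = "count matrix") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_ilc("%s must be a numeric matrix", what)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_ilc("%s must carry gene (row) and sample (column) identifiers", what)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop_ilc("duplicate gene identifier in %s: '%s'", what, dup)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1L]
    stop_ilc("duplicate sample identifier in %s: '%s'", what, dup)
  }
  if (anyNA(counts)) stop_ilc("%s contains missing values", what)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop_ilc("negative count for gene '%s', sample '%s'",
             rownames(counts)[bad[1L]], colnames(counts)[bad[2L]])
  }
  invisible(counts)
}

check_samples <- function(samples, counts = NULL) {
  need <- c("sample_id", "subset", "donor")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop_ilc("sample table must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_ilc("duplicate sample_id in metadata: '%s'",
             samples$sample_id[duplicated(samples$sample_id)][1L])
  }
  bad <- setdiff(unique(as.character(samples$subset)), ALL_SUBSETS)
  if (length(bad)) {
    stop_ilc("unknown subset label(s): %s (allowed: %s)",
             paste(bad, collapse = ", "), paste(ALL_SUBSETS, collapse = ", "))
  }
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), samples$sample_id)
    if (length(missing)) {
      stop_ilc("metadata missing sample(s): %s", paste(missing, collapse = ", "))
    }
    extra <- setdiff(samples$sample_id, colnames(counts))
    if (length(extra)) {
      stop_ilc("metadata lists sample(s) absent from the count matrix: %s",
               paste(extra, collapse = ", "))
    }
  }
  invisible(samples)
}

# Align a sample table to the column order of a count matrix.
align_samples <- function(samples, counts) {
  check_samples(samples, counts)
  samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
}
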