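# Readers and writers for every external format the pipeline touches.
# All tables are tab-separated UTF-8 with a header row; gene matching across
# files is by gene_id, exactly and case-sensitively.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop_ilc("%s file not found: %s", what, path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a gene-level count matrix
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose remaining columns hold non-negative integer counts, one column per
#' sample. Row and column order are preserved.
#'
#' @param path file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path, "count matrix")
  if (ncol(df) < 2) stop_ilc("count matrix needs a gene column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_ilc("non-numeric count value in %s", path)
  if (anyNA(m)) stop_ilc("missing count value in %s", path)
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1L, ]
    stop_ilc("non-integer count for gene '%s', sample '%s'",
             ids[bad[1L]], colnames(m)[bad[2L]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  check_count_matrix(m)
  m
}

#' Write a count matrix
#' @param counts integer matrix, genes x samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  check_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read sample metadata
#'
#' @param path tab-separated file with columns sample_id, subset, donor.
#' @param counts optional count matrix; if given, the metadata must cover its
#'   columns exactly and is returned in the matrix's column order.
#' @return data.frame with columns sample_id, subset, donor.
#' @export
read_metadata <- function(path, counts = NULL) {
  df <- read_tsv_checked(path, "metadata")
  df$sample_id <- as.character(df$sample_id)
  check_samples(df, counts)
  if (!is.null(counts)) df <- align_samples(df, counts)
  df
}

#' Write sample metadata
#' @param samples data.frame with columns sample_id, subset, donor.
#' @param path output file path.
#' @export
write_metadata <- function(samples, path) {
  check_samples(samples)
  write_tsv(samples[, c("sample_id", "subset", "donor")], path)
}

#' Read a gene annotation table
#' @param path tab-separated file with columns gene_id, symbol, biotype.
#' @return data.frame; gene_id is checked unique.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path, "annotation")
  need <- c("gene_id", "symbol", "biotype")
  if (!all(need %in% names(df))) {
    stop_ilc("annotation must have columns %s", paste(need, collapse = ", "))
  }
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) {
    stop_ilc("duplicate gene_id in annotation: '%s'",
             df$gene_id[duplicated(df$gene_id)][1L])
  }
  df
}

#' Write a gene annotation table
#' @param annotation data.frame with columns gene_id, symbol, biotype.
#' @param path output file path.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv(annotation[, c("gene_id", "symbol", "biotype")], path)
}

#' Read a GMT gene-set collection
#'
#' Broad-convention GMT: one set per line, tab-separated fields
#' `name`, `description`, then one or more member gene ids. Duplicate members
#' within a set are removed; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return Named list of gene-id vectors of class `geneset_collection` with an
#'   `info` attribute (name, description).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ilc("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_ilc("malformed GMT line %d: expected >= 3 tab-separated fields", i)
    }
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop_ilc("GMT line %d has no gene members", i)
    sets[[i]] <- members
  }
  if (anyDuplicated(nm)) {
    stop_ilc("duplicate gene-set name in GMT: '%s'", nm[duplicated(nm)][1L])
  }
  names(sets) <- nm
  structure(sets, info = data.frame(name = nm, description = desc,
                                    stringsAsFactors = FALSE),
            class = "geneset_collection")
}

#' Write a gene-set collection as GMT
#' @param sets named list of gene-id vectors (optionally with an `info`
#'   attribute holding descriptions).
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_ilc("gene sets must have unique names")
  }
  info <- attr(sets, "info")
  desc <- if (!is.null(info) && "description" %in% names(info)) {
    info$description[match(names(sets), info$name)]
  } else rep("na", length(sets))
  desc[is.na(desc) | !nzchar(desc)] <- "na"
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.15g", x))
  })
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_ilc("cannot write to '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

CONTRAST_COLS <- c("gene_id", "log2fc", "t", "p", "adj_p")
GSEA_COLS <- c("set", "size", "direction", "es", "nes", "p", "adj_p")

#' Write / read a differential-expression contrast table
#'
#' Fixed column order `gene_id, log2fc, t, p, adj_p`; numbers are written with
#' 15 significant digits so write/read round-trips are stable to 1e-12.
#'
#' @param table a contrast table (see [test_contrast()]).
#' @param path file path.
#' @return `path` (writer, invisibly) or the table (reader).
#' @export
write_contrast_table <- function(table, path) {
  if (!all(CONTRAST_COLS %in% names(table))) {
    stop_ilc("contrast table must have columns %s",
             paste(CONTRAST_COLS, collapse = ", "))
  }
  write_tsv(as.data.frame(table)[, CONTRAST_COLS], path)
}

#' @rdname write_contrast_table
#' @export
read_contrast_table <- function(path) {
  df <- read_tsv_checked(path, "contrast table")
  if (!all(CONTRAST_COLS %in% names(df))) {
    stop_ilc("not a contrast table: %s", path)
  }
  df$gene_id <- as.character(df$gene_id)
  class(df) <- c("contrast_table", "data.frame")
  df
}

#' Write / read a GSEA result table
#'
#' Fixed column order `set, size, direction, es, nes, p, adj_p`.
#'
#' @param results a GSEA result table (see [gsea_run()]).
#' @param path file path.
#' @export
write_gsea_table <- function(results, path) {
  if (!all(GSEA_COLS %in% names(results))) {
    stop_ilc("GSEA table must have columns %s", paste(GSEA_COLS, collapse = ", "))
  }
  write_tsv(as.data.frame(results)[, GSEA_COLS], path)
}

#' @rdname write_gsea_table
#' @export
read_gsea_table <- function(path) {
  df <- read_tsv_checked(path, "GSEA table")
  if (!all(GSEA_COLS %in% names(df))) stop_ilc("not a GSEA table: %s", path)
  df
}

#' Read a pipeline configuration file
#'
#' A single YAML key-value file; keys mirror the arguments of
#' [pipeline_config()] (nested `sim:` and `gsea:` blocks allowed).
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_ilc("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
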