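# Readers and writers for the external file dialects the pipeline touches:
# MetaXcan association CSVs, GTEx-style normalised expression BEDs, the
# tissue sample-size table, and the ranking output TSV.

# Column-name aliases accepted in MetaXcan association output. Both the
# dotted and underscored spellings occur in the wild.
.twas_aliases <- list(
  gene         = c("gene", "gene_id"),
  gene_name    = c("gene_name", "genename"),
  zscore       = c("zscore", "z_score", "z-score"),
  pvalue       = c("pvalue", "p_value", "p-value"),
  pred_perf_r2 = c("pred_perf_r2", "pred.perf.r2", "pred.perf.r2.")
)

.match_column <- function(header, aliases) {
  hit <- which(tolower(header) %in% aliases)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Read a MetaXcan-style TWAS association table
#'
#' Parses the comma-separated association output of MetaXcan/S-PrediXcan for a
#' single tissue. The columns `gene` (or `gene_id`), `zscore`, `pvalue` and
#' `pred_perf_r2` (or `pred.perf.R2`) are required; `gene_name` is kept when
#' present and any other columns are ignored. Rows with a missing z-score or
#' prediction R-squared are dropped (with a logged count, retrievable from the
#' `"n_dropped"` attribute); p-values of exactly zero are floored to the
#' smallest positive double so that downstream log transforms are defined.
#'
#' @param path path to a MetaXcan association CSV (may be gzip-compressed).
#' @param tissue tissue name to attach; defaults to the file name without
#'   extension.
#' @return a `data.frame` of class `"twas_table"` with columns `gene_id`,
#'   `gene_name`, `zscore`, `pvalue`, `pred_perf_r2`, a `tissue` attribute and
#'   an `n_dropped` attribute.
#' @seealso [read_expression_bed()], [read_sample_sizes()]
#' @export
read_twas_csv <- function(path, tissue = NULL) {
  if (!file.exists(path)) gidee_stop(sprintf("file not found: %s", path), "gidee_io_error")
  if (is.null(tissue)) {
    tissue <- sub("\\.(csv|txt)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  }
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  header <- names(raw)
  idx <- vapply(.twas_aliases, function(a) .match_column(header, a), integer(1))
  required <- c("gene", "zscore", "pvalue", "pred_perf_r2")
  missing_cols <- required[is.na(idx[required])]
  if (length(missing_cols) > 0L) {
    gidee_stop(sprintf("missing required column(s) in %s: %s",
                       path, paste(missing_cols, collapse = ", ")),
               "gidee_format_error")
  }
  out <- data.frame(
    gene_id      = as.character(raw[[idx["gene"]]]),
    gene_name    = if (!is.na(idx["gene_name"])) as.character(raw[[idx["gene_name"]]]) else NA_character_,
    zscore       = as.numeric(raw[[idx["zscore"]]]),
    pvalue       = as.numeric(raw[[idx["pvalue"]]]),
    pred_perf_r2 = as.numeric(raw[[idx["pred_perf_r2"]]]),
    stringsAsFactors = FALSE
  )
  keep <- is.finite(out$zscore) & is.finite(out$pred_perf_r2)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    gidee_log(sprintf("%s: dropped %d row(s) with missing zscore/pred_perf_r2", tissue, n_dropped))
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    gidee_stop(sprintf("no usable rows in %s", path), "gidee_empty_input")
  }
  if (anyDuplicated(out$gene_id)) {
    dup <- out$gene_id[duplicated(out$gene_id)][1L]
    gidee_stop(sprintf("duplicated gene_id in %s: %s", path, dup), "gidee_format_error")
  }
  n_floored <- sum(out$pvalue <= 0, na.rm = TRUE)
  if (n_floored > 0L) {
    gidee_log(sprintf("%s: floored %d zero p-value(s)", tissue, n_floored))
    out$pvalue[out$pvalue <= 0] <- .p_floor
  }
  rownames(out) <- NULL
  structure(out,
            class = c("twas_table", "data.frame"),
            tissue = tissue, n_dropped = n_dropped, n_floored = n_floored)
}

#' Read a GTEx-style normalised expression BED file
#'
#' Reads a tab-separated expression matrix whose first four columns are
#' `#chr`, `start`, `end`, `gene_id` followed by one column per sample.
#' Genomic coordinates are discarded; gzip-compressed files are read
#' transparently.
#'
#' @param path path to the BED file (optionally `.gz`).
#' @param tissue tissue name to attach; defaults to the file name without
#'   extension.
#' @return a numeric matrix (genes x samples) with gene ids as row names,
#'   sample ids as column names, and a `tissue` attribute.
#' @export
read_expression_bed <- function(path, tissue = NULL) {
  if (!file.exists(path)) gidee_stop(sprintf("file not found: %s", path), "gidee_io_error")
  if (is.null(tissue)) {
    tissue <- sub("\\.bed(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  header <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 5L || tolower(sub("^#", "", header[1L])) != "chr") {
    gidee_stop(sprintf("%s: not a GTEx-style expression BED (header must start '#chr\tstart\tend\tgene_id')", path),
               "gidee_format_error")
  }
  sample_ids <- header[-(1:4)]
  body <- utils::read.table(con, sep = "\t", header = FALSE, quote = "",
                            comment.char = "", colClasses = c("character", "character",
                                                              "character", "character",
                                                              rep("character", length(sample_ids))),
                            stringsAsFactors = FALSE)
  if (ncol(body) != length(header)) {
    gidee_stop(sprintf("%s: rows have %d fields, header has %d", path, ncol(body), length(header)),
               "gidee_format_error")
  }
  gene_ids <- body[[4L]]
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    gidee_stop(sprintf("%s: duplicated gene_id %s", path, dup), "gidee_format_error")
  }
  vals <- as.matrix(body[, -(1:4), drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    gidee_stop(sprintf("%s: non-numeric expression value at gene row %d, sample column %d ('%s')",
                       path, bad[1L], bad[2L], vals[bad[1L], bad[2L]]),
               "gidee_format_error")
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  attr(num, "tissue") <- tissue
  num
}

#' Read a tissue sample-size table
#'
#' Two-column tab-separated file, `tissue<TAB>N`, with or without a header
#' line (a header is detected by a non-numeric second field on line one).
#'
#' @param path path to the TSV.
#' @return named integer vector of sample sizes (names are tissue names).
#' @export
read_sample_sizes <- function(path) {
  if (!file.exists(path)) gidee_stop(sprintf("file not found: %s", path), "gidee_io_error")
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           stringsAsFactors = FALSE, col.names = c("tissue", "n"),
                           colClasses = c("character", "character"))
  if (nrow(tab) > 0L && is.na(suppressWarnings(as.numeric(tab$n[1L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  n <- suppressWarnings(as.numeric(tab$n))
  if (anyNA(n) || any(n < 1)) {
    gidee_stop(sprintf("%s: sample sizes must be integers >= 1", path), "gidee_format_error")
  }
  stats::setNames(as.integer(round(n)), tab$tissue)
}

# Numeric columns are serialised with 17 significant digits so that a
# write/read round trip reproduces doubles exactly.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write the per-tissue ranking table
#'
#' Serialises the combined statistics/rank table produced by [gidee()] as a
#' plain TSV with a single header line and no row names. Numeric values are
#' written with enough precision that [read_ranking_table()] reproduces them
#' to better than 1e-12.
#'
#' @param ranking a data.frame as returned by `ranking_table(fit)`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ranking_table <- function(ranking, path) {
  stopifnot(is.data.frame(ranking))
  out <- ranking
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a ranking table written by [write_ranking_table()]
#'
#' @param path path to the TSV.
#' @return data.frame with `tissue` as character and all other columns numeric.
#' @export
read_ranking_table <- function(path) {
  if (!file.exists(path)) gidee_stop(sprintf("file not found: %s", path), "gidee_io_error")
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (j in seq_along(tab)) {
    if (names(tab)[j] != "tissue") tab[[j]] <- as.numeric(tab[[j]])
  }
  tab
}
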