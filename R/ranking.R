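# Rank construction and aggregation: per-test tissue ranks (rank 1 = most
# enriched), all 15 combinations of the four tests, and the trait-clustering
# order used for multi-trait heatmaps.

# Single-letter codes of the four tests, in canonical order:
#   S = sample-size-adjusted mean squared z-score residual (larger better)
#   B = sample-size-adjusted Brown residual (larger better)
#   P = binomial test, Bonferroni threshold (smaller p better)
#   F = binomial test, FDR threshold (smaller p better)
.test_letters <- c("S", "B", "P", "F")

#' Midranks of a statistic column
#'
#' Converts per-tissue statistics to ranks with rank 1 = most enriched. Ties
#' receive the mean of the rank positions they span (midranks), so each
#' column's ranks always sum to T(T+1)/2.
#'
#' @param values numeric vector (finite).
#' @param direction `"larger"` if a larger value means more enriched (the
#'   residual-based tests), `"smaller"` if a smaller value does (p-values).
#' @return numeric vector of midranks in \[1, T\].
#' @export
rank_column <- function(values, direction = c("larger", "smaller")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) gidee_stop("non-finite values in rank column", "gidee_validation_error")
  x <- if (direction == "larger") -values else values
  rank(x, ties.method = "average")
}

#' Enumerate all combinations of the four enrichment tests
#'
#' All 15 non-empty subsets of \{S, B, P, F\}, ordered by size then
#' lexicographically. Labels concatenate the member letters, except the
#' headline \{S, B\} combination which carries its conventional name `SZBP`
#' (mean squared z-score + Brown's p-value).
#'
#' @return a list of 15 entries, each with `label` and `members` (a character
#'   vector of test letters).
#' @export
enumerate_combinations <- function() {
  combos <- list()
  for (size in 1:4) {
    sets <- utils::combn(.test_letters, size, simplify = FALSE)
    labs <- vapply(sets, paste0, "", collapse = "")
    sets <- sets[order(labs)]
    combos <- c(combos, sets)
  }
  lapply(combos, function(s) {
    lab <- paste0(s, collapse = "")
    if (identical(sort(s), sort(c("S", "B")))) lab <- "SZBP"
    list(label = lab, members = s)
  })
}

# Resolve user-supplied combination specs ("all", "SZBP", "SB", "SBPF", ...)
# to entries of enumerate_combinations().
resolve_combinations <- function(spec = "all") {
  all15 <- enumerate_combinations()
  if (length(spec) == 1L && identical(tolower(spec), "all")) return(all15)
  keys <- vapply(all15, function(cb) paste0(sort(cb$members), collapse = ""), "")
  out <- lapply(spec, function(s) {
    su <- toupper(s)
    if (su == "SZBP") su <- "SB"
    letters_s <- sort(strsplit(su, "")[[1L]])
    if (!all(letters_s %in% .test_letters) || length(letters_s) == 0L ||
        anyDuplicated(letters_s)) {
      gidee_stop(sprintf("unknown combination '%s' (letters from S,B,P,F, or 'SZBP'/'all')", s),
                 "gidee_validation_error")
    }
    all15[[which(keys == paste0(letters_s, collapse = ""))]]
  })
  out[!duplicated(vapply(out, `[[`, "", "label"))]
}

#' Average and re-rank a combination of per-test ranks
#'
#' For a chosen subset of the four tests, computes each tissue's average rank
#' over the subset's rank columns, then midranks those averages (smaller
#' average rank = more enriched = final rank 1). A singleton subset reproduces
#' its own rank column.
#'
#' @param rank_matrix numeric matrix or data.frame, tissues x tests, with
#'   columns named by test letters `S`, `B`, `P`, `F`.
#' @param members character vector, subset of the test letters.
#' @return list with `label`, `average_rank` and `final_rank` (both named by
#'   tissue when the matrix has row names).
#' @export
combine_ranks <- function(rank_matrix, members) {
  rank_matrix <- as.matrix(rank_matrix)
  if (!all(members %in% colnames(rank_matrix))) {
    gidee_stop("rank matrix lacks a column for a requested test", "gidee_validation_error")
  }
  if (length(members) == 0L) gidee_stop("empty combination", "gidee_validation_error")
  avg <- rowMeans(rank_matrix[, members, drop = FALSE])
  lab <- paste0(members, collapse = "")
  if (identical(sort(members), sort(c("S", "B")))) lab <- "SZBP"
  list(label = lab,
       average_rank = avg,
       final_rank = rank(avg, ties.method = "average"))
}

#' Cluster traits by the similarity of their tissue-rank profiles
#'
#' Computes the Pearson correlation matrix between the traits' per-tissue
#' final-rank vectors, takes Euclidean distances between the rows of that
#' correlation matrix, and agglomerates with complete linkage. The returned
#' leaf order is the trait order used to draw a clustered trait-by-tissue
#' rank heatmap.
#'
#' @param rank_table numeric matrix, traits x tissues, of final ranks (row
#'   names are trait names).
#' @return list with `order` (leaf order indices), `labels` (trait names in
#'   leaf order), `hclust` (the `stats::hclust` tree) and `correlation` (the
#'   trait correlation matrix).
#' @export
cluster_traits <- function(rank_table) {
  rank_table <- as.matrix(rank_table)
  if (nrow(rank_table) < 2L) gidee_stop("need >= 2 traits to cluster", "gidee_validation_error")
  sds <- apply(rank_table, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(rank_table)[sds == 0][1L]
    gidee_stop(sprintf("trait '%s' has a constant rank vector (correlation undefined)",
                       if (is.null(bad) || is.na(bad)) "<unnamed>" else bad),
               "gidee_validation_error")
  }
  corr <- stats::cor(t(rank_table))
  d <- stats::dist(corr, method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  list(order = hc$order,
       labels = if (!is.null(rownames(rank_table))) rownames(rank_table)[hc$order] else hc$order,
       hclust = hc,
       correlation = corr)
}

#' Top fraction of tissues under a combination ranking
#'
#' The highlight rule used to report prioritised tissues: the tissues whose
#' final rank falls within the top `fraction` of all tissues (rounded up), by
#' default the top 10 percent.
#'
#' @param final_rank named numeric vector of final ranks (rank 1 = best).
#' @param fraction fraction of tissues to highlight, default 0.1.
#' @return character vector of the highlighted tissue names, best first.
#' @export
top_tissues <- function(final_rank, fraction = 0.1) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * length(final_rank))
  names(sort(final_rank))[seq_len(k)]
}
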