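# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from stored data files.

# Write a minimal MetaXcan-style association CSV and return its path.
write_twas_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                               gene = c("ENSG00000000001.1", "ENSG00000000002.2",
                                        "ENSG00000000003.1"),
                               zscore = c(1.2, -0.4, 2.5),
                               pvalue = 2 * pnorm(-abs(zscore)),
                               pred_perf_r2 = c(0.10, 0.30, 0.55),
                               file = "tissueA.csv",
                               header = "gene,gene_name,zscore,pvalue,pred_perf_r2") {
  path <- file.path(dir, file)
  rows <- sprintf("%s,G%d,%s,%s,%s", gene, seq_along(gene),
                  ifelse(is.na(zscore), "", format(zscore, digits = 15)),
                  format(pvalue, digits = 15),
                  ifelse(is.na(pred_perf_r2), "", format(pred_perf_r2, digits = 15)))
  writeLines(c(header, rows), path)
  path
}

# Write a small GTEx-style expression BED and return its path.
write_bed_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                              mat = matrix(c(1.5, -0.2, 0.3, 2.0, 0.1, -1.1), nrow = 2,
                                           dimnames = list(c("ENSG00000000001.5",
                                                             "ENSG00000000002.5"),
                                                           c("S1", "S2", "S3"))),
                              file = "tissueA.bed", gzip = FALSE) {
  path <- file.path(dir, file)
  header <- paste(c("#chr", "start", "end", "gene_id", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c("chr1", i * 100, i * 100 + 50, rownames(mat)[i],
            format(mat[i, ], digits = 15)), collapse = "\t")
  }, "")
  if (gzip) {
    con <- gzfile(paste0(path, ".gz"), "wt")
    writeLines(c(header, rows), con)
    close(con)
    return(paste0(path, ".gz"))
  }
  writeLines(c(header, rows), path)
  path
}

# Small in-memory scenario used where a full-size one would be wasteful.
small_scenario <- function(seed = 1L, ...) {
  args <- list(n_tissues = 5L, genes_per_tissue = 80L, samples_range = c(20L, 50L),
               block_size = 4L, block_rho = 0.3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(gidee_scenario, args)
}

# A small fitted object shared by tests that only need shape, memoised since
# several files use it.
gidee_fixture_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- simulate_gidee_data(small_scenario())
      cache <<- gidee(dat$twas, dat$expr, dat$sizes, combinations = "SZBP")
    }
    cache
  }
})

# Bin final ranks for goodness-of-fit tests: integer ranks count 1 in their
# bin, midranks (x.5 from ties) count 0.5 in each adjacent bin.
midrank_counts <- function(r, n_bins) {
  cnt <- numeric(n_bins)
  for (x in r) {
    if (x == floor(x)) cnt[x] <- cnt[x] + 1
    else {
      cnt[floor(x)] <- cnt[floor(x)] + 0.5
      cnt[ceiling(x)] <- cnt[ceiling(x)] + 0.5
    }
  }
  cnt
}

# Independent Fisher combination used as the Brown independence-limit oracle.
fisher_combine <- function(p) {
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# Brute-force BH step-up definition: adj_i = min_{j >= rank(i)} m * p_(j) / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive binomial upper tail via exact summation of the pmf.
binom_tail_bruteforce <- function(x, n, p) {
  if (x == 0) return(1)
  sum(vapply(x:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

# Naive O(n^3) complete-linkage agglomeration on a distance matrix; records
# merge heights, the leaf set of every merge, and the partition after each
# agglomeration step (partitions[[k]] = membership vector with k clusters).
complete_linkage_bruteforce <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  dist_cl <- function(a, b) max(d[clusters[[a]], clusters[[b]]])
  heights <- numeric(0)
  merge_sets <- list()
  ids <- seq_len(n)
  membership <- function(ids) {
    g <- integer(n)
    for (k in seq_along(ids)) g[clusters[[ids[k]]]] <- k
    g
  }
  partitions <- vector("list", n)
  partitions[[n]] <- membership(ids)
  while (length(ids) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
      dd <- dist_cl(ids[i], ids[j])
      if (dd < bestd) { bestd <- dd; best <- c(ids[j], ids[i]) }
    }
    clusters[[length(clusters) + 1L]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, bestd)
    merge_sets[[length(merge_sets) + 1L]] <- clusters[[length(clusters)]]
    ids <- c(setdiff(ids, best), length(clusters))
    partitions[[length(ids)]] <- membership(ids)
  }
  list(heights = heights, merge_sets = merge_sets, partitions = partitions)
}
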