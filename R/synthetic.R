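# Synthetic multi-tissue scenario generator. Emulates the three pipeline
# inputs — per-tissue TWAS association tables, normalised expression matrices
# and a tissue sample-size table — with a known planted enriched tissue, so
# the whole pipeline and its parameter-recovery checks run without any
# external data.

#' Define a synthetic multi-tissue scenario
#'
#' Parameters of a planted-enrichment fixture. Defaults describe a
#' down-scaled GTEx-like panel: 10 tissues of 500 genes each, expression
#' panels between 80 and 400 samples (GTEx v8 eQTL tissues range from ~70 to
#' ~700), gene-gene correlation in blocks of 10 at within-block correlation
#' 0.3, a sample-size power artefact of strength 1 (null z variance grows from
#' 1 to 2 with panel size, mimicking the greater power of large tissues), and
#' one planted tissue in which 10 percent of genes carry a differential-
#' expression shift of |z| = 3 with random sign.
#'
#' @param n_tissues number of tissues (>= 3).
#' @param genes_per_tissue genes per tissue.
#' @param samples_range integer vector `c(min, max)` for per-tissue expression
#'   sample sizes.
#' @param planted_tissue index of the enriched tissue, or `NA` for a global
#'   null scenario.
#' @param enriched_fraction fraction of the planted tissue's genes that are
#'   enriched.
#' @param effect_mean mean |z| shift added to enriched genes (sign random per
#'   gene: differential expression is signed).
#' @param block_size width of the correlated-gene blocks in the expression
#'   factor model.
#' @param block_rho within-block expression correlation, in \[0, 1).
#' @param size_power_slope strength of the sample-size/power artefact: null z
#'   are drawn with variance `1 + size_power_slope * N_t / max(N)`.
#' @param seed integer seed; the same scenario and seed reproduce identical
#'   data byte for byte.
#' @return an object of class `"gidee_scenario"` (a list of the above).
#' @export
gidee_scenario <- function(n_tissues = 10L,
                           genes_per_tissue = 500L,
                           samples_range = c(80L, 400L),
                           planted_tissue = 1L,
                           enriched_fraction = 0.1,
                           effect_mean = 3,
                           block_size = 10L,
                           block_rho = 0.3,
                           size_power_slope = 1,
                           seed = 1L) {
  stopifnot(n_tissues >= 3, genes_per_tissue >= 2,
            length(samples_range) == 2L, samples_range[1L] >= 3,
            samples_range[2L] >= samples_range[1L],
            enriched_fraction >= 0, enriched_fraction <= 1,
            block_rho >= 0, block_rho < 1, size_power_slope >= 0,
            block_size >= 1)
  if (!is.na(planted_tissue)) stopifnot(planted_tissue >= 1, planted_tissue <= n_tissues)
  structure(list(n_tissues = as.integer(n_tissues),
                 genes_per_tissue = as.integer(genes_per_tissue),
                 samples_range = as.integer(samples_range),
                 planted_tissue = if (is.na(planted_tissue)) NA_integer_ else as.integer(planted_tissue),
                 enriched_fraction = enriched_fraction,
                 effect_mean = effect_mean,
                 block_size = as.integer(block_size),
                 block_rho = block_rho,
                 size_power_slope = size_power_slope,
                 seed = as.integer(seed)),
            class = "gidee_scenario")
}

#' Block-correlated expression matrix
#'
#' Draws a genes x samples matrix from a one-factor-per-block model: genes are
#' partitioned into consecutive blocks of `block_size`; within a block, each
#' sample's values share a block factor, `x = sqrt(rho) * f_b + sqrt(1-rho) * e`
#' with `f_b` and `e` standard normal, so the within-block correlation tends
#' to `rho` as the sample count grows and between-block genes are independent.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param block_size block width (last block may be shorter).
#' @param rho within-block correlation, in \[0, 1).
#' @return numeric matrix, `n_genes` x `n_samples`.
#' @export
correlated_expression <- function(n_genes, n_samples, block_size, rho) {
  stopifnot(rho >= 0, rho < 1, n_genes >= 1, n_samples >= 1, block_size >= 1)
  block_of <- ((seq_len(n_genes) - 1L) %/% block_size) + 1L
  n_blocks <- max(block_of)
  f <- matrix(stats::rnorm(n_blocks * n_samples), n_blocks, n_samples)
  e <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  sqrt(rho) * f[block_of, , drop = FALSE] + sqrt(1 - rho) * e
}

# Deterministic per-tissue seed stream derived from the scenario seed.
.tissue_seed <- function(seed, t) {
  (as.integer(seed) + 104729L * as.integer(t)) %% .Machine$integer.max
}

#' Generate a synthetic scenario in memory
#'
#' Draws all per-tissue data for a scenario: sample sizes uniform over
#' `samples_range`, block-correlated expression, null TWAS z-scores with the
#' sample-size-dependent variance artefact, a planted shift of random sign for
#' the enriched genes of the planted tissue, two-sided normal p-values, and
#' prediction-performance R-squared drawn from Beta(2, 5) independently of z.
#' Gene ids are Ensembl-style with a version suffix in the TWAS tables and a
#' different suffix in the expression matrices, mirroring the real files'
#' inconsistent versioning.
#'
#' @param scenario a [gidee_scenario()].
#' @return list with `twas` (named list of `twas_table` data.frames), `expr`
#'   (named list of genes x samples matrices), `sizes` (named integer vector)
#'   and `truth` (planted tissue name, enriched gene ids, scenario echo).
#' @export
simulate_gidee_data <- function(scenario = gidee_scenario()) {
  stopifnot(inherits(scenario, "gidee_scenario"))
  sc <- scenario
  tissues <- sprintf("tissue%02d", seq_len(sc$n_tissues))
  set.seed(sc$seed)
  sizes <- stats::setNames(
    sample(seq(sc$samples_range[1L], sc$samples_range[2L]), sc$n_tissues, replace = TRUE),
    tissues
  )
  max_n <- max(sizes)
  gene_ids <- sprintf("ENSG%011d", seq_len(sc$genes_per_tissue))
  twas <- list()
  expr <- list()
  enriched_genes <- character(0)
  for (t in seq_len(sc$n_tissues)) {
    set.seed(.tissue_seed(sc$seed, t))
    n_t <- sizes[[t]]
    em <- correlated_expression(sc$genes_per_tissue, n_t, sc$block_size, sc$block_rho)
    rownames(em) <- paste0(gene_ids, ".", (t %% 3L) + 1L) # versioned differently per file
    colnames(em) <- sprintf("%s_S%04d", tissues[t], seq_len(n_t))
    attr(em, "tissue") <- tissues[t]
    sd_t <- sqrt(1 + sc$size_power_slope * n_t / max_n)
    z <- stats::rnorm(sc$genes_per_tissue, mean = 0, sd = sd_t)
    if (!is.na(sc$planted_tissue) && t == sc$planted_tissue && sc$enriched_fraction > 0) {
      n_enr <- round(sc$enriched_fraction * sc$genes_per_tissue)
      idx <- sample(sc$genes_per_tissue, n_enr)
      signs <- sample(c(-1, 1), n_enr, replace = TRUE)
      z[idx] <- z[idx] + signs * sc$effect_mean
      enriched_genes <- gene_ids[sort(idx)]
    }
    p <- 2 * stats::pnorm(-abs(z))
    p[p <= 0] <- .p_floor
    tt <- data.frame(
      gene_id = paste0(gene_ids, ".", ((t + 1L) %% 4L) + 1L),
      gene_name = sprintf("GENE%d", seq_len(sc$genes_per_tissue)),
      zscore = z,
      pvalue = p,
      pred_perf_r2 = stats::rbeta(sc$genes_per_tissue, 2, 5),
      stringsAsFactors = FALSE
    )
    twas[[tissues[t]]] <- structure(tt, class = c("twas_table", "data.frame"),
                                    tissue = tissues[t], n_dropped = 0L)
    expr[[tissues[t]]] <- em
  }
  list(twas = twas, expr = expr, sizes = sizes,
       truth = list(planted_tissue = if (is.na(sc$planted_tissue)) NA_character_ else tissues[sc$planted_tissue],
                    enriched_genes = enriched_genes,
                    scenario = unclass(sc)))
}

#' Write a synthetic scenario to disk in the pipeline's file dialects
#'
#' Materialises [simulate_gidee_data()] output as one MetaXcan-style CSV per
#' tissue under `outdir/twas/`, one expression BED per tissue under
#' `outdir/expression/`, a `sample_sizes.tsv`, and a `truth.json` recording
#' the planted tissue and enriched gene ids.
#'
#' @param scenario a [gidee_scenario()].
#' @param outdir output directory (created if needed).
#' @return the `truth` record, invisibly; files as a side effect.
#' @export
generate_synthetic_files <- function(scenario, outdir) {
  dat <- simulate_gidee_data(scenario)
  dir.create(file.path(outdir, "twas"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "expression"), recursive = TRUE, showWarnings = FALSE)
  for (tissue in names(dat$twas)) {
    tt <- dat$twas[[tissue]]
    out <- data.frame(gene = tt$gene_id, gene_name = tt$gene_name,
                      zscore = .fmt_num(tt$zscore), pvalue = .fmt_num(tt$pvalue),
                      pred_perf_r2 = .fmt_num(tt$pred_perf_r2),
                      stringsAsFactors = FALSE)
    utils::write.table(out, file.path(outdir, "twas", paste0(tissue, ".csv")),
                       sep = ",", quote = FALSE, row.names = FALSE)
    em <- dat$expr[[tissue]]
    bed <- data.frame(chr = "chr1",
                      start = seq_len(nrow(em)) * 1000L,
                      end = seq_len(nrow(em)) * 1000L + 500L,
                      gene_id = rownames(em),
                      stringsAsFactors = FALSE)
    bed <- cbind(bed, as.data.frame(apply(em, 2L, .fmt_num), stringsAsFactors = FALSE))
    names(bed) <- c("#chr", "start", "end", "gene_id", colnames(em))
    utils::write.table(bed, file.path(outdir, "expression", paste0(tissue, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(tissue = names(dat$sizes), n = as.integer(dat$sizes)),
                     file.path(outdir, "sample_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(dat$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dat$truth)
}
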