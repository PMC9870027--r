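# File-level orchestration: read every tissue's inputs from disk, fit the
# estimator, and write the ranking table plus an auditable run log.

#' Run the full enrichment pipeline from files
#'
#' Reads one MetaXcan-style CSV per tissue from `twas_dir`, the matching
#' expression BED (`<tissue>.bed` or `.bed.gz`) from `expr_dir` and the
#' two-column sample-size TSV, fits [gidee()], and writes to `outdir`:
#' `ranking.tsv` (the full ranking table), `per_tissue_stats.tsv` (all raw and
#' effective counts, including the x, n and null proportion of both binomial
#' tests, so the leave-one-out null is auditable) and `run_log.txt` (gene
#' counts per tissue before/after filtering and the configuration echo).
#'
#' @param twas_dir directory of per-tissue association CSVs (tissue name =
#'   file name without extension).
#' @param expr_dir directory of per-tissue expression BEDs.
#' @param sample_size_file two-column TSV `tissue<TAB>N`.
#' @param outdir output directory (created if needed); `NULL` writes nothing.
#' @param ... passed to [gidee()] (`combinations`, `alpha`, `meff_variant`,
#'   `r2_at_least_median`, `brown_raw_p`).
#' @return the `"gidee"` fit, invisibly.
#' @export
run_gidee <- function(twas_dir, expr_dir, sample_size_file, outdir = NULL, ...) {
  twas_files <- sort(list.files(twas_dir, pattern = "\\.csv(\\.gz)?$", full.names = TRUE))
  if (length(twas_files) == 0L) gidee_stop(sprintf("no TWAS CSVs in %s", twas_dir), "gidee_io_error")
  tissues <- sub("\\.csv(\\.gz)?$", "", basename(twas_files))
  sizes <- read_sample_sizes(sample_size_file)

  expr_path <- function(tissue) {
    for (ext in c(".bed", ".bed.gz")) {
      p <- file.path(expr_dir, paste0(tissue, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }
  expr_paths <- vapply(tissues, expr_path, "")
  missing_expr <- tissues[is.na(expr_paths)]
  missing_size <- setdiff(tissues, names(sizes))
  if (length(missing_expr) > 0L || length(missing_size) > 0L) {
    gidee_stop(sprintf("tissue(s) missing inputs — expression: %s; sample size: %s",
                       paste(missing_expr, collapse = ", "),
                       paste(missing_size, collapse = ", ")),
               "gidee_validation_error")
  }

  twas <- stats::setNames(lapply(seq_along(tissues), function(i)
    read_twas_csv(twas_files[i], tissue = tissues[i])), tissues)
  expr <- stats::setNames(lapply(seq_along(tissues), function(i)
    read_expression_bed(expr_paths[i], tissue = tissues[i])), tissues)

  fit <- gidee(twas, expr, sizes[tissues], ...)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_ranking_table(ranking_table(fit), file.path(outdir, "ranking.tsv"))
    stats_out <- fit$stats
    for (j in seq_along(stats_out)) {
      if (is.numeric(stats_out[[j]])) stats_out[[j]] <- .fmt_num(stats_out[[j]])
    }
    utils::write.table(stats_out, file.path(outdir, "per_tissue_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(
      sprintf("gidee run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("config: %s", paste(names(fit$config),
                                  vapply(fit$config, function(v) paste(v, collapse = ","), ""),
                                  sep = "=", collapse = "; ")),
      sprintf("tissues: %d", length(fit$tissues)),
      vapply(fit$per_tissue, function(p) {
        sprintf("%s: n_before=%d n_after=%d n_matched=%d meff=%.3f x_bonf=%.3f x_fdr=%.3f",
                p$tissue, p$n_before, p$n_after, p$n_matched,
                p$n_eff, p$x_eff_bonf, p$x_eff_fdr)
      }, ""),
      {
        hc <- headline_combination(fit)
        sprintf("headline %s top tissue: %s (final rank %g)",
                hc$label, fit$tissues[which.min(hc$final_rank)], min(hc$final_rank))
      }
    )
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  invisible(fit)
}

#' Cluster several traits' ranking tables and optionally draw a heatmap
#'
#' Reads previously written ranking TSVs (one per trait), extracts each
#' trait's final ranks under the chosen combination, clusters traits by the
#' Pearson correlation of their rank profiles (complete linkage on Euclidean
#' distances between correlation rows), and optionally renders a reordered
#' trait-by-tissue rank heatmap to PNG.
#'
#' @param ranking_files named character vector of ranking TSV paths (names are
#'   trait labels; file names are used otherwise).
#' @param combination combination label to use, default `"SZBP"`.
#' @param png_file optional output PNG path.
#' @return the [cluster_traits()] result plus the traits x tissues `ranks`
#'   matrix.
#' @export
cluster_trait_rankings <- function(ranking_files, combination = "SZBP", png_file = NULL) {
  if (length(ranking_files) < 2L) gidee_stop("need >= 2 trait ranking files", "gidee_validation_error")
  labels <- names(ranking_files)
  if (is.null(labels)) labels <- sub("\\.tsv$", "", basename(ranking_files))
  col <- paste0("finalrank_", combination)
  tabs <- lapply(ranking_files, read_ranking_table)
  tissues <- tabs[[1L]]$tissue
  ranks <- t(vapply(tabs, function(tb) {
    if (!col %in% names(tb)) {
      gidee_stop(sprintf("ranking file lacks column %s", col), "gidee_format_error")
    }
    if (!identical(tb$tissue, tissues)) {
      m <- match(tissues, tb$tissue)
      if (anyNA(m)) gidee_stop("tissue sets differ across ranking files", "gidee_validation_error")
      tb <- tb[m, , drop = FALSE]
    }
    tb[[col]]
  }, numeric(length(tissues))))
  dimnames(ranks) <- list(labels, tissues)
  cl <- cluster_traits(ranks)
  if (!is.null(png_file)) {
    grDevices::png(png_file, width = 1200, height = 150 + 40 * length(labels))
    on.exit(grDevices::dev.off(), add = TRUE)
    ord <- cl$order
    graphics::image(t(ranks[rev(ord), , drop = FALSE]),
                    col = grDevices::hcl.colors(49, "YlOrRd", rev = FALSE),
                    axes = FALSE, main = sprintf("tissue final ranks (%s)", combination))
    graphics::axis(2, at = seq(0, 1, length.out = length(ord)),
                   labels = rev(labels[ord]), las = 2, cex.axis = 0.7)
  }
  c(cl, list(ranks = ranks))
}
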