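# The central estimator: given per-tissue TWAS tables, expression matrices
# and sample sizes, compute the four enrichment tests, the sample-size
# adjustment and the rank combinations, returning a classed fit object.

#' Rank tissues by enrichment of trait-associated differential expression
#'
#' Fits the genome-wide imputed differential expression enrichment estimator.
#' For each tissue the TWAS table is restricted to robustly imputed genes
#' (prediction R-squared above the per-tissue median), and four enrichment
#' tests are computed:
#'
#' * **S** — mean squared z-score over the retained genes, residualised on
#'   tissue sample size (OLS across tissues);
#' * **B** — empirical Brown's combined p-value of the retained genes'
#'   p-values (dependence estimated from the tissue's expression matrix),
#'   transformed to -log10 and residualised on sample size;
#' * **P** — one-sided binomial test of the effective (matSpD) count of genes
#'   passing the per-tissue Bonferroni threshold `alpha / Meff`, against a
#'   leave-one-tissue-out null proportion;
#' * **F** — the same binomial test with BH-FDR `< alpha` as the significance
#'   threshold.
#'
#' The binomial tests are not additionally adjusted for sample size (their
#' counts are already tissue-specific). Per-test midranks (rank 1 = most
#' enriched) are averaged over the requested combinations of tests and
#' re-ranked; the headline combination `SZBP` averages the S and B ranks.
#'
#' Gene matching between TWAS tables and expression matrices is by
#' unversioned Ensembl id ([strip_gene_version()]). Genes retained by the
#' filter but absent from the expression matrix still contribute to the mean
#' squared z-score, but are excluded from Brown's combination and from the
#' effective counts, which require expression rows.
#'
#' @param twas named list (by tissue) of TWAS tables as from [read_twas_csv()].
#' @param expr named list (by tissue) of expression matrices as from
#'   [read_expression_bed()].
#' @param sizes named numeric vector of tissue sample sizes.
#' @param combinations character vector of rank combinations to compute:
#'   `"all"` (default) for all 15, or labels such as `"SZBP"` (alias `"SB"`),
#'   `"S"`, `"SBPF"`.
#' @param alpha significance level for the binomial-test thresholds (0.05).
#' @param meff_variant which spectral-decomposition effective-count estimator
#'   feeds the binomial tests: `"liji"` (default) or `"nyholt"`.
#' @param r2_at_least_median use `>=` instead of `>` in the prediction
#'   R-squared filter (for tie-heavy data).
#' @param brown_raw_p regress the untransformed Brown p-value on sample size
#'   (residual sign flipped) instead of -log10(p).
#' @return an object of class `"gidee"`; see [ranking_table()],
#'   [summary.gidee()], [residuals.gidee()], [coef.gidee()], [plot.gidee()].
#' @examples
#' dat <- simulate_gidee_data(gidee_scenario(n_tissues = 5, genes_per_tissue = 60,
#'                                           samples_range = c(20, 40), seed = 7))
#' fit <- gidee(dat$twas, dat$expr, dat$sizes, combinations = "SZBP")
#' fit
#' @export
gidee <- function(twas, expr, sizes,
                  combinations = "all",
                  alpha = 0.05,
                  meff_variant = c("liji", "nyholt"),
                  r2_at_least_median = FALSE,
                  brown_raw_p = FALSE) {
  meff_variant <- match.arg(meff_variant)
  tissues <- names(twas)
  if (is.null(tissues) || any(tissues == "")) gidee_stop("twas list must be named by tissue", "gidee_validation_error")
  missing_expr <- setdiff(tissues, names(expr))
  missing_size <- setdiff(tissues, names(sizes))
  if (length(missing_expr) > 0L || length(missing_size) > 0L) {
    gidee_stop(sprintf("tissue(s) missing inputs — expression: %s; sample size: %s",
                       paste(missing_expr, collapse = ", "),
                       paste(missing_size, collapse = ", ")),
               "gidee_validation_error")
  }
  if (length(tissues) < 3L) gidee_stop("need >= 3 tissues", "gidee_validation_error")
  combos <- resolve_combinations(combinations)

  per <- lapply(tissues, function(tissue) {
    tab <- filter_top_half(twas[[tissue]], at_least = r2_at_least_median)
    em <- expr[[tissue]]
    key_twas <- strip_gene_version(tab$gene_id)
    key_expr <- strip_gene_version(rownames(em))
    matched <- key_twas %in% key_expr
    sub <- tab[matched, , drop = FALSE]
    rows <- match(strip_gene_version(sub$gene_id), key_expr)
    esub <- em[rows, , drop = FALSE]
    if (nrow(sub) == 0L) {
      gidee_stop(sprintf("tissue %s: no filtered gene has an expression row", tissue),
                 "gidee_alignment_error")
    }
    p <- pmax(sub$pvalue, .p_floor)
    brown <- empirical_browns(stats::setNames(p, rownames(esub)), esub)
    n_eff <- effective_count(esub, variant = meff_variant)
    thr <- bonferroni_threshold(max(n_eff, 1), alpha = alpha)
    sig_bonf <- p < thr
    sig_fdr <- bh_fdr(p) < alpha
    x_bonf <- effective_count(esub[sig_bonf, , drop = FALSE], variant = meff_variant)
    x_fdr <- effective_count(esub[sig_fdr, , drop = FALSE], variant = meff_variant)
    gidee_log(sprintf("%s: %d genes -> %d after R2 filter, %d with expression; Meff %.1f, x_bonf %.1f, x_fdr %.1f",
                      tissue, attr(tab, "n_before"), attr(tab, "n_after"), nrow(sub),
                      n_eff, x_bonf, x_fdr))
    list(tissue = tissue,
         median_r2 = attr(tab, "median_r2"),
         n_before = attr(tab, "n_before"),
         n_after = attr(tab, "n_after"),
         n_matched = nrow(sub),
         mean_sq_z = mean_squared_z(tab$zscore),
         brown = brown,
         n_eff = n_eff,
         bonf_threshold = thr,
         n_sig_bonf = sum(sig_bonf),
         n_sig_fdr = sum(sig_fdr),
         x_eff_bonf = x_bonf,
         x_eff_fdr = x_fdr)
  })
  names(per) <- tissues

  pull <- function(field) vapply(per, `[[`, numeric(1), field)
  msz <- pull("mean_sq_z")
  brown_p <- vapply(per, function(x) x$brown$p_combined, numeric(1))

  # sample-size adjustment (S and B only; binomial tests are size-specific)
  res_s <- residualize(stats::setNames(msz, tissues), sizes)
  if (brown_raw_p) {
    res_b <- residualize(stats::setNames(brown_p, tissues), sizes)
    brown_resid <- -res_b$residual # more enriched = smaller p than fitted
  } else {
    res_b <- residualize(stats::setNames(-log10(brown_p), tissues), sizes)
    brown_resid <- res_b$residual
  }

  # binomial tests with the leave-one-tissue-out null (unrounded Eq. counts)
  x_bonf <- pull("x_eff_bonf"); x_fdr <- pull("x_eff_fdr"); n_eff <- pull("n_eff")
  binom_bonf <- lapply(seq_along(tissues), function(i)
    binomial_enrichment(x_bonf, n_eff, i, kind = "bonferroni"))
  binom_fdr <- lapply(seq_along(tissues), function(i)
    binomial_enrichment(x_fdr, n_eff, i, kind = "fdr"))

  stats_df <- data.frame(
    tissue = tissues,
    size = as.numeric(sizes[tissues]),
    n_genes = pull("n_after"),
    n_matched = pull("n_matched"),
    mean_sq_z = msz,
    mean_sq_z_residual = res_s$residual,
    brown_p = brown_p,
    brown_residual = brown_resid,
    n_eff = n_eff,
    x_eff_bonf = x_bonf,
    x_eff_fdr = x_fdr,
    binom_bonf_x = vapply(binom_bonf, `[[`, numeric(1), "x_successes"),
    binom_bonf_n = vapply(binom_bonf, `[[`, numeric(1), "n_trials"),
    binom_bonf_null = vapply(binom_bonf, `[[`, numeric(1), "null_p"),
    binom_bonf_p = vapply(binom_bonf, `[[`, numeric(1), "p_value"),
    binom_fdr_x = vapply(binom_fdr, `[[`, numeric(1), "x_successes"),
    binom_fdr_n = vapply(binom_fdr, `[[`, numeric(1), "n_trials"),
    binom_fdr_null = vapply(binom_fdr, `[[`, numeric(1), "null_p"),
    binom_fdr_p = vapply(binom_fdr, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE, row.names = NULL
  )

  rank_matrix <- cbind(
    S = rank_column(stats_df$mean_sq_z_residual, "larger"),
    B = rank_column(stats_df$brown_residual, "larger"),
    P = rank_column(stats_df$binom_bonf_p, "smaller"),
    F = rank_column(stats_df$binom_fdr_p, "smaller")
  )
  rownames(rank_matrix) <- tissues

  combo_results <- lapply(combos, function(cb) combine_ranks(rank_matrix, cb$members))
  names(combo_results) <- vapply(combo_results, `[[`, "", "label")

  structure(list(
    tissues = tissues,
    stats = stats_df,
    rank_matrix = rank_matrix,
    combinations = combo_results,
    size_fit = list(
      S = list(slope = attr(res_s, "slope"), intercept = attr(res_s, "intercept"),
               values = stats::setNames(res_s$raw_value, tissues)),
      B = list(slope = attr(res_b, "slope"), intercept = attr(res_b, "intercept"),
               values = stats::setNames(res_b$raw_value, tissues))
    ),
    per_tissue = per,
    config = list(combinations = combinations, alpha = alpha,
                  meff_variant = meff_variant,
                  r2_at_least_median = r2_at_least_median,
                  brown_raw_p = brown_raw_p)
  ), class = "gidee")
}

#' Headline combination of a fit
#'
#' The first requested combination; `SZBP` when all were computed.
#' @param fit a `"gidee"` object.
#' @return the combination entry (`label`, `average_rank`, `final_rank`).
#' @export
headline_combination <- function(fit) {
  stopifnot(inherits(fit, "gidee"))
  labs <- names(fit$combinations)
  if ("SZBP" %in% labs) fit$combinations[["SZBP"]] else fit$combinations[[1L]]
}

#' Full per-tissue ranking table of a fit
#'
#' One row per tissue with the raw statistics, residuals, binomial p-values,
#' the four per-test rank columns, and an average-rank and final-rank column
#' per computed combination. This is the table serialised by
#' [write_ranking_table()].
#'
#' @param fit a `"gidee"` object.
#' @return a data.frame.
#' @export
ranking_table <- function(fit) {
  stopifnot(inherits(fit, "gidee"))
  s <- fit$stats
  out <- data.frame(
    tissue = s$tissue,
    mean_sq_z = s$mean_sq_z,
    mean_sq_z_residual = s$mean_sq_z_residual,
    brown_p = s$brown_p,
    brown_residual = s$brown_residual,
    binom_bonf_p = s$binom_bonf_p,
    binom_fdr_p = s$binom_fdr_p,
    rank_S = fit$rank_matrix[, "S"],
    rank_B = fit$rank_matrix[, "B"],
    rank_P = fit$rank_matrix[, "P"],
    rank_F = fit$rank_matrix[, "F"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (cb in fit$combinations) {
    out[[paste0("avgrank_", cb$label)]] <- as.numeric(cb$average_rank)
    out[[paste0("finalrank_", cb$label)]] <- as.numeric(cb$final_rank)
  }
  out
}

#' @export
print.gidee <- function(x, n = 5L, ...) {
  hc <- headline_combination(x)
  cat("Tissue enrichment ranking (", length(x$tissues), " tissues, ",
      length(x$combinations), " rank combination(s))\n", sep = "")
  cat("Headline combination:", hc$label, "\n")
  ord <- order(hc$final_rank)
  top <- utils::head(ord, n)
  for (i in top) {
    cat(sprintf("  %2g  %s  (avg rank %.2f)\n",
                hc$final_rank[i], x$tissues[i], hc$average_rank[i]))
  }
  if (length(x$tissues) > n) cat("  ... use summary() for the full table\n")
  invisible(x)
}

#' Summary of a tissue-enrichment fit
#'
#' @param object a `"gidee"` object.
#' @param ... unused.
#' @return the full ranking table (invisibly classed for printing).
#' @export
summary.gidee <- function(object, ...) {
  tab <- ranking_table(object)
  hc <- headline_combination(object)
  tab <- tab[order(hc$final_rank), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, headline = hc$label,
                 size_fit = object$size_fit, config = object$config),
            class = "summary.gidee")
}

#' @export
print.summary.gidee <- function(x, ...) {
  cat("gidee fit — headline combination", x$headline, "\n")
  cat(sprintf("size regression: mean z^2 slope %.3g; Brown slope %.3g\n",
              x$size_fit$S$slope, x$size_fit$B$slope))
  print(x$table, digits = 4)
  invisible(x)
}

#' Sample-size-adjustment residuals of a fit
#'
#' @param object a `"gidee"` object.
#' @param ... unused.
#' @return matrix (tissues x 2) of the mean-z-squared and Brown residuals.
#' @export
residuals.gidee <- function(object, ...) {
  cbind(mean_sq_z = stats::setNames(object$stats$mean_sq_z_residual, object$tissues),
        brown = stats::setNames(object$stats$brown_residual, object$tissues))
}

#' Coefficients of the sample-size regressions
#'
#' @param object a `"gidee"` object.
#' @param ... unused.
#' @return matrix with rows `mean_sq_z` and `brown`, columns `intercept`,
#'   `slope`.
#' @export
coef.gidee <- function(object, ...) {
  rbind(mean_sq_z = c(intercept = object$size_fit$S$intercept, slope = object$size_fit$S$slope),
        brown = c(intercept = object$size_fit$B$intercept, slope = object$size_fit$B$slope))
}

#' Plot an enrichment statistic against tissue sample size
#'
#' Scatter of the raw statistic (mean squared z, or the Brown statistic on the
#' regression scale) against expression-panel sample size with the fitted OLS
#' line; the vertical distance to the line is the adjusted enrichment. The
#' most enriched tissue is labelled.
#'
#' @param x a `"gidee"` object.
#' @param which `"S"` (mean squared z, default) or `"B"` (Brown).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gidee <- function(x, which = c("S", "B"), ...) {
  which <- match.arg(which)
  f <- x$size_fit[[which]]
  sz <- x$stats$size
  vals <- as.numeric(f$values)
  ylab <- if (which == "S") "mean squared z-score"
          else if (x$config$brown_raw_p) "Brown p-value" else "-log10 Brown p-value"
  graphics::plot(sz, vals, xlab = "tissue sample size", ylab = ylab,
                 pch = 19, ...)
  graphics::abline(a = f$intercept, b = f$slope, col = "blue")
  resid <- vals - (f$intercept + f$slope * sz)
  top <- which.max(if (which == "B" && x$config$brown_raw_p) -resid else resid)
  graphics::text(sz[top], vals[top], labels = x$tissues[top], pos = 3, cex = 0.8)
  invisible(x)
}
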