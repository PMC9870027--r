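# Prediction-performance prefilter: each tissue's TWAS results are restricted
# to robustly imputed genes before any enrichment test is run.

#' Restrict a TWAS table to the top half of accurately imputed genes
#'
#' Computes the per-tissue median of the cross-validated prediction
#' performance R-squared over all genes with a result, and retains the genes
#' whose `pred_perf_r2` is strictly greater than that median (the top 50th
#' percentile of accurately imputed genes). For an even gene count the median
#' is the midpoint of the two central values, so with tie-free R-squared the
#' filter keeps exactly half the genes.
#'
#' Real prediction R-squared values can tie at the median; with `at_least =
#' TRUE` the comparison becomes `>=`, which keeps tied genes. Under the
#' default strict rule, a table in which every gene shares one R-squared value
#' would be emptied, which is reported as a degenerate-input error suggesting
#' the fallback.
#'
#' @param table a `twas_table` from [read_twas_csv()] (any data.frame with the
#'   same columns works).
#' @param at_least use `>=` instead of the strict `>` comparison.
#' @return the filtered table, with attributes `median_r2`, `n_before`,
#'   `n_after` and the original `tissue`. Row order is preserved.
#' @export
filter_top_half <- function(table, at_least = FALSE) {
  stopifnot(is.data.frame(table), "pred_perf_r2" %in% names(table))
  if (nrow(table) == 0L) gidee_stop("empty TWAS table", "gidee_empty_input")
  med <- stats::median(table$pred_perf_r2)
  keep <- if (at_least) table$pred_perf_r2 >= med else table$pred_perf_r2 > med
  if (!any(keep)) {
    gidee_stop(paste0("strict median filter retains no genes (all pred_perf_r2 equal?); ",
                      "use at_least = TRUE (--r2-at-least-median) for tie-heavy data"),
               "gidee_degenerate_input")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("twas_table", "data.frame"),
            tissue = attr(table, "tissue"),
            median_r2 = med,
            n_before = nrow(table),
            n_after = nrow(out))
}
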