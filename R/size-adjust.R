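# Sample-size adjustment: tissues with larger expression panels impute more
# genes with more power, inflating both whole-distribution enrichment
# statistics. A linear regression of the statistic on the panel sample size
# is fitted across tissues and the residual is the adjusted statistic.

#' Residualise per-tissue statistics on tissue sample size
#'
#' Fits an ordinary least squares regression (with intercept) of a per-tissue
#' statistic on the expression-panel sample size, jointly over all tissues,
#' and returns each tissue's residual. The larger the residual, the more the
#' tissue is enriched beyond what its sample size predicts.
#'
#' If every tissue has the same sample size the predictor is degenerate; with
#' `allow_degenerate = TRUE` the function falls back to mean-centred values
#' (slope 0) with a warning, otherwise it errors.
#'
#' @param values named numeric vector, one statistic per tissue.
#' @param sizes named numeric vector of sample sizes covering every tissue in
#'   `values`.
#' @param allow_degenerate fall back to mean-centring when all sizes are equal.
#' @return a data.frame with columns `tissue`, `size`, `raw_value`, `fitted`,
#'   `residual`, and attributes `slope` and `intercept`.
#' @export
residualize <- function(values, sizes, allow_degenerate = FALSE) {
  if (is.null(names(values))) gidee_stop("values must be named by tissue", "gidee_validation_error")
  if (length(values) < 3L) gidee_stop("need >= 3 tissues for the size regression", "gidee_validation_error")
  missing_sz <- setdiff(names(values), names(sizes))
  if (length(missing_sz) > 0L) {
    gidee_stop(sprintf("no sample size for tissue(s): %s", paste(missing_sz, collapse = ", ")),
               "gidee_validation_error")
  }
  sz <- as.numeric(sizes[names(values)])
  if (stats::var(sz) == 0) {
    if (!allow_degenerate) {
      gidee_stop("all tissue sample sizes are equal: size regression is degenerate",
                 "gidee_degenerate_input")
    }
    warning("all tissue sample sizes equal; residuals are mean-centred values")
    fitted <- rep(mean(values), length(values))
    slope <- 0
    intercept <- mean(values)
  } else {
    fit <- stats::lm(values ~ sz)
    fitted <- unname(stats::fitted(fit))
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
  }
  structure(
    data.frame(tissue = names(values), size = sz,
               raw_value = as.numeric(values),
               fitted = fitted,
               residual = as.numeric(values) - fitted,
               stringsAsFactors = FALSE, row.names = NULL),
    slope = slope, intercept = intercept
  )
}
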