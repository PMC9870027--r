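# The four enrichment tests: mean squared z-score, empirical Brown's combined
# p-value, and one-sided binomial tests on effective (matSpD) gene counts
# under Bonferroni and FDR significance thresholds.

#' Mean squared differential-expression z-score
#'
#' The first enrichment statistic: the arithmetic mean of the squared TWAS
#' z-scores across the retained genes of one tissue. Squaring removes the sign
#' of differential expression, so the statistic measures average association
#' strength; under a global null of standard-normal z it has expectation 1.
#'
#' @param zscores numeric vector of z-scores (finite, non-empty).
#' @return a single non-negative number.
#' @export
mean_squared_z <- function(zscores) {
  if (length(zscores) == 0L) gidee_stop("empty z-score vector", "gidee_empty_input")
  if (!all(is.finite(zscores))) gidee_stop("non-finite z-scores", "gidee_validation_error")
  mean(zscores^2)
}

# -2 * log empirical CDF transform of one data row, using <=-counting so the
# smallest attainable ecdf value is 1/n (never 0, so the log is defined).
.w_transform <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "max") # #{x_j <= x_s} under <=-counting
  -2 * log(r / n)
}

#' Combine dependent p-values with the empirical Brown's method
#'
#' Fisher-style combination of one tissue's per-gene differential-expression
#' p-values with a chi-square reference rescaled for the dependence between
#' genes, estimated empirically from that tissue's expression matrix.
#'
#' Each gene's expression row is transformed to `w_i(s) = -2 log(ecdf_i(x_i(s)))`
#' (the empirical CDF of the gene's own values, `<=`-counting). With
#' `psi = -2 sum(log p_i)`, the moments `E(psi) = 2k` and
#' `Var(psi) = 4k + 2 sum_{i<j} cov(w_i, w_j)` give the rescaled reference:
#' scale factor `c = Var/(2E)` and degrees of freedom `f = 2E^2/Var`, and the
#' combined p-value is the upper tail of a chi-square with `f` degrees of
#' freedom evaluated at `psi/c`. Under independence `c = 1`, `f = 2k` and the
#' method reduces to Fisher's. Sampling noise can push the empirical variance
#' below its independence value, which would make the combination
#' anti-conservative, so `c` is clamped to `>= 1` (equivalently `f <= 2k`).
#'
#' @param pvalues numeric vector of k p-values in (0, 1]; if named, names must
#'   match `rownames(expr)`.
#' @param expr numeric matrix of expression values with k rows (one per gene,
#'   in the same order as `pvalues`) and at least 3 sample columns.
#' @return a list with elements `psi`, `df`, `scale_c`, `p_combined` and
#'   `n_genes_combined`.
#' @references Brown, M.B. (1975) Biometrics 31:987-992; Poole, W. et al.
#'   (2016) Bioinformatics 32:i430-i436 (empirical variant).
#' @export
empirical_browns <- function(pvalues, expr) {
  k <- length(pvalues)
  if (k == 0L) gidee_stop("no p-values to combine", "gidee_empty_input")
  if (!is.matrix(expr) || nrow(expr) != k) {
    gidee_stop("expression matrix must have one row per p-value", "gidee_alignment_error")
  }
  if (!is.null(names(pvalues)) && !is.null(rownames(expr)) &&
      !identical(unname(names(pvalues)), unname(rownames(expr)))) {
    gidee_stop("gene set mismatch between p-values and expression rows", "gidee_alignment_error")
  }
  if (ncol(expr) < 3L) gidee_stop("need >= 3 samples to estimate covariance", "gidee_validation_error")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    gidee_stop("p-values must lie in (0, 1]", "gidee_validation_error")
  }
  psi <- -2 * sum(log(pvalues))
  e_psi <- 2 * k
  if (k == 1L) {
    var_psi <- 4
  } else {
    w <- t(apply(expr, 1L, .w_transform))          # k x n_samples
    cw <- stats::cov(t(w))                         # k x k sample covariance
    var_psi <- 4 * k + 2 * sum(cw[upper.tri(cw)])
  }
  scale_c <- max(1, var_psi / (2 * e_psi))         # clamp at independence
  df <- 2 * e_psi^2 / max(var_psi, 2 * e_psi)      # = 2k when clamped
  p <- stats::pchisq(psi / scale_c, df = df, lower.tail = FALSE)
  p <- min(1, max(p, .p_floor))
  list(psi = psi, df = df, scale_c = scale_c, p_combined = p,
       n_genes_combined = k)
}

#' Effective number of independent tests from a correlation matrix
#'
#' Spectral-decomposition (matSpD) estimates of the effective number of
#' independent variables among M correlated ones. Two published estimators are
#' returned: Nyholt's `1 + (M-1) * (1 - Var(lambda)/M)` (sample variance of
#' the eigenvalues, denominator M-1) and Li & Ji's
#' `sum_i [ 1(|lambda_i| >= 1) + (|lambda_i| - floor(|lambda_i|)) ]`.
#' An identity correlation matrix gives M under both; a unit-rank matrix
#' (all pairwise correlations 1) gives 1 under both.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param tol tolerance for symmetry/diagonal validation.
#' @return list with `eigenvalues` (descending), `veff_nyholt`, `veff_liji`.
#' @references Nyholt, D.R. (2004) Am J Hum Genet 74:765-769; Li, J. & Ji, L.
#'   (2005) Heredity 95:221-227.
#' @export
effective_tests <- function(corr, tol = 1e-8) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    gidee_stop("correlation matrix must be square", "gidee_validation_error")
  }
  if (max(abs(corr - t(corr))) > tol) {
    gidee_stop("correlation matrix is not symmetric", "gidee_validation_error")
  }
  if (max(abs(diag(corr) - 1)) > tol) {
    gidee_stop("correlation matrix diagonal must be 1", "gidee_validation_error")
  }
  m <- nrow(corr)
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  lambda <- sort(lambda, decreasing = TRUE)
  veff_nyholt <- if (m == 1L) 1 else 1 + (m - 1) * (1 - stats::var(lambda) / m)
  al <- abs(lambda)
  veff_liji <- sum(as.numeric(al >= 1) + (al - floor(al)))
  list(eigenvalues = lambda,
       veff_nyholt = min(max(veff_nyholt, 1), m),
       veff_liji = min(max(veff_liji, 1), m))
}

#' Bonferroni significance threshold for an effective test count
#'
#' Tissue-wide significance threshold `0.05 / meff`, where `meff` is the
#' effective number of independent genes in the tissue.
#'
#' @param meff effective number of independent tests (>= 1).
#' @param alpha family-wise error rate, default 0.05.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(meff, alpha = 0.05) {
  stopifnot(meff >= 1)
  alpha / meff
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; a thin wrapper
#' around `stats::p.adjust(method = "BH")` kept as a named operation so the
#' FDR-threshold binomial test reads explicitly.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values, in input order.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Effective number of independent genes in an expression subset
#'
#' For a set of genes, computes the Pearson correlation matrix of their
#' expression rows across samples and returns the requested spectral-
#' decomposition effective count. Degenerate sizes short-circuit: an empty set
#' has effective count 0 and a single gene counts 1. Genes with zero
#' expression variance cannot enter a correlation matrix and are excluded
#' (logged); each excluded-but-present gene still represents at most itself,
#' so exclusion only affects the correlation estimate, not validity.
#'
#' @param expr numeric matrix, genes x samples, for the gene set.
#' @param variant which estimator to return: `"liji"` (default) or `"nyholt"`.
#' @return a single effective count (real, in \[0, nrow(expr)\]).
#' @export
effective_count <- function(expr, variant = c("liji", "nyholt")) {
  variant <- match.arg(variant)
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1L)
  m <- nrow(expr)
  if (m == 0L) return(0)
  v <- apply(expr, 1L, stats::var)
  zerovar <- !is.finite(v) | v <= 0
  if (any(zerovar)) {
    gidee_log(sprintf("excluding %d zero-variance gene(s) from effective count", sum(zerovar)))
    expr <- expr[!zerovar, , drop = FALSE]
    m <- nrow(expr)
    if (m == 0L) return(0)
  }
  if (m == 1L) return(1)
  corr <- stats::cor(t(expr))
  est <- effective_tests(corr)
  if (variant == "liji") est$veff_liji else est$veff_nyholt
}

#' One-sided binomial enrichment test with a leave-one-tissue-out null
#'
#' Tests whether tissue `i` carries a greater proportion of tissue-wide
#' significant differentially expressed genes than expected from the other
#' tissues. Successes and trials are effective (matSpD) gene counts per
#' tissue; the null proportion for tissue `i` is computed on the unrounded
#' values as
#' `null_p_i = (sum(successes) - successes_i) / (sum(trials) - trials_i)`,
#' while the test itself uses the tissue's counts rounded to integers
#' (x floored at 0 and capped at n, n floored at 1). The p-value is the exact
#' binomial upper tail `P(X >= x)` with `X ~ Binomial(n, null_p)`; `x = 0`
#' gives p = 1.
#'
#' @param successes numeric vector of effective significant-gene counts, one
#'   per tissue (unrounded).
#' @param trials numeric vector of effective gene counts, one per tissue.
#' @param i index of the tissue under test.
#' @param kind label recorded in the result: `"bonferroni"` or `"fdr"`.
#' @return list with `tissue_index`, `x_successes`, `n_trials`, `null_p`,
#'   `p_value`, `threshold_kind`.
#' @export
binomial_enrichment <- function(successes, trials, i,
                                kind = c("bonferroni", "fdr")) {
  kind <- match.arg(kind)
  t_n <- length(trials)
  if (length(successes) != t_n) {
    gidee_stop("successes and trials must cover the same tissues", "gidee_validation_error")
  }
  if (t_n < 2L) gidee_stop("need >= 2 tissues (leave-one-out null undefined)", "gidee_validation_error")
  if (i < 1L || i > t_n) gidee_stop("tissue index out of range", "gidee_validation_error")
  denom <- sum(trials) - trials[i]
  if (denom <= 0) gidee_stop("leave-one-out trial total is zero", "gidee_validation_error")
  null_p <- (sum(successes) - successes[i]) / denom
  null_p <- min(1, max(0, null_p))
  n <- max(1L, as.integer(round(trials[i])))
  x <- max(0L, as.integer(round(successes[i])))
  x <- min(x, n)
  # exact upper tail P(X >= x); pbinom accumulates the lower tail stably
  p <- if (x == 0L) 1 else stats::pbinom(x - 1L, size = n, prob = null_p, lower.tail = FALSE)
  p <- min(1, max(p, .p_floor))
  list(tissue_index = i, x_successes = x, n_trials = n, null_p = null_p,
       p_value = p, threshold_kind = kind)
}
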