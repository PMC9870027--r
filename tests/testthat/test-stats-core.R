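# The four enrichment tests and their supporting operations.

test_that("mean squared z-score matches hand arithmetic and the chi-square moment", {
  expect_equal(mean_squared_z(c(0, 0, 0)), 0)
  expect_equal(mean_squared_z(c(1, 2, 3)), 14 / 3)
  expect_error(mean_squared_z(numeric(0)), class = "gidee_empty_input")
  # under a standard-normal null the statistic estimates E(z^2) = 1 with
  # Var(mean z^2) = 2/n
  set.seed(11)
  n <- 1e4
  v <- mean_squared_z(rnorm(n))
  expect_lt(abs(v - 1), 3 * sqrt(2 / n))
})

test_that("a single p-value passes through Brown's combination unchanged", {
  set.seed(2)
  expr <- matrix(rnorm(12), nrow = 1)
  out <- empirical_browns(0.037, expr)
  expect_equal(out$p_combined, 0.037, tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$scale_c, 1)
})

test_that("Brown's combination approaches Fisher under independent expression", {
  set.seed(21)
  k <- 50; n <- 200
  d <- replicate(100, {
    p <- runif(k)
    expr <- matrix(rnorm(k * n), k, n)
    pb <- empirical_browns(p, expr)$p_combined
    abs(log10(pb) - log10(fisher_combine(p)))
  })
  expect_lt(mean(d), 0.1)
})

test_that("perfect expression dependence collapses Brown toward a single test", {
  # 20 genes whose expression rows are identical: effectively one test, so
  # combining twenty p = 0.05 should return ~0.05, not Fisher's tiny value
  set.seed(5)
  row <- rnorm(100)
  expr <- matrix(rep(row, 20), nrow = 20, byrow = TRUE)
  p <- rep(0.05, 20)
  out <- empirical_browns(p, expr)
  expect_lt(out$df, 4)        # df collapses toward 2
  expect_gt(out$p_combined, 0.01)
  expect_lt(out$p_combined, 0.2)
  expect_lt(fisher_combine(p), 1e-8) # the independence assumption would explode
})

test_that("Brown rejects misaligned or invalid inputs", {
  expr <- matrix(rnorm(30), nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
  expect_error(empirical_browns(setNames(c(.1, .2, .3), c("a", "c", "b")), expr),
               class = "gidee_alignment_error")
  expect_error(empirical_browns(c(.1, .2), expr), class = "gidee_alignment_error")
  expect_error(empirical_browns(numeric(0), expr[0, , drop = FALSE]),
               class = "gidee_empty_input")
  expect_error(empirical_browns(c(.1, .2, 1.5), expr), class = "gidee_validation_error")
})

test_that("effective test counts hit the closed-form and hand-computed cases", {
  id5 <- diag(5)
  out <- effective_tests(id5)
  expect_equal(out$veff_nyholt, 5)
  expect_equal(out$veff_liji, 5)

  ones5 <- matrix(1, 5, 5)
  out <- effective_tests(ones5)
  expect_equal(sort(out$eigenvalues, decreasing = TRUE)[1], 5, tolerance = 1e-12)
  expect_equal(out$veff_nyholt, 1)
  expect_equal(out$veff_liji, 1, tolerance = 1e-12)

  # hand eigendecomposition: 2x2 with r = 0.5 has eigenvalues 1 +/- r
  r <- 0.5
  m <- matrix(c(1, r, r, 1), 2)
  out <- effective_tests(m)
  expect_equal(out$eigenvalues, c(1.5, 0.5), tolerance = 1e-12)
  # Nyholt: 1 + (M-1) (1 - Var(lambda)/M), Var({1.5, 0.5}) = 0.5
  expect_equal(out$veff_nyholt, 1 + 1 * (1 - 0.5 / 2))
  # Li-Ji: f(1.5) + f(0.5) = (1 + 0.5) + (0 + 0.5)
  expect_equal(out$veff_liji, (1 + 0.5) + 0.5, tolerance = 1e-12)

  expect_error(effective_tests(matrix(c(1, .2, .4, 1), 2)), class = "gidee_validation_error")
  expect_error(effective_tests(matrix(c(2, .2, .2, 2), 2)), class = "gidee_validation_error")
})

test_that("effective counts stay in [1, M] and shrink as exchangeable correlation grows", {
  prev_n <- Inf; prev_l <- Inf
  for (rho in seq(0, 0.95, by = 0.05)) {
    m <- matrix(rho, 10, 10); diag(m) <- 1
    out <- effective_tests(m)
    expect_gte(out$veff_nyholt, 1); expect_lte(out$veff_nyholt, 10)
    expect_gte(out$veff_liji, 1); expect_lte(out$veff_liji, 10)
    expect_lte(out$veff_nyholt, prev_n + 1e-12)
    expect_lte(out$veff_liji, prev_l + 1e-12)
    prev_n <- out$veff_nyholt; prev_l <- out$veff_liji
  }
})

test_that("effective_count handles degenerate gene sets", {
  expect_equal(effective_count(matrix(numeric(0), nrow = 0, ncol = 5)), 0)
  expect_equal(effective_count(matrix(rnorm(10), nrow = 1)), 1)
  # duplicated rows form a unit-rank correlation matrix
  row <- rnorm(50)
  dup <- matrix(rep(row, 10), nrow = 10, byrow = TRUE)
  expect_equal(effective_count(dup, "liji"), 1, tolerance = 1e-8)
  expect_equal(effective_count(dup, "nyholt"), 1, tolerance = 1e-8)
  # zero-variance genes are excluded before the correlation
  m <- rbind(rnorm(50), rep(2, 50), rnorm(50))
  expect_lte(effective_count(m), 2)
})

test_that("Bonferroni threshold is alpha over the effective count", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(500), 1e-4)
  expect_equal(bonferroni_threshold(2500.7), 0.05 / 2500.7)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.5), 0.5)
  set.seed(33)
  for (rep in 1:5) {
    p <- runif(100)^2
    adj <- bh_fdr(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(adj >= p) && all(adj <= 1))
  }
})

test_that("binomial enrichment implements the leave-one-tissue-out null", {
  out <- binomial_enrichment(c(5, 10, 15), c(100, 100, 100), i = 1)
  expect_equal(out$null_p, (30 - 5) / (300 - 100))
  expect_equal(out$x_successes, 5L)
  expect_equal(out$n_trials, 100L)
  # x = 0 spans the whole support
  expect_equal(binomial_enrichment(c(0, 10, 15), c(100, 100, 100), i = 1)$p_value, 1)
  expect_error(binomial_enrichment(5, 10, 1), class = "gidee_validation_error")
  # leave-one-out trial total of zero is undefined
  expect_error(binomial_enrichment(c(1, 1), c(0, 5), i = 2), class = "gidee_validation_error")
})

test_that("the binomial upper tail equals exhaustive enumeration", {
  # spot value from the stated example
  out <- binomial_enrichment(c(20, 12.5, 12.5), c(100, 100, 100), i = 1)
  expect_equal(out$null_p, 0.125)
  expect_equal(out$p_value, binom_tail_bruteforce(20, 100, 0.125), tolerance = 1e-12)
  # full grid for all n <= 25 at three null proportions; the second tissue's
  # unrounded counts pin the leave-one-out null at exactly p0
  for (p0 in c(0.05, 0.125, 0.5)) {
    for (n in 1:25) {
      for (x in 0:n) {
        got <- binomial_enrichment(c(x, p0 * 1000), c(n, 1000), i = 1)
        expect_equal(got$null_p, p0)
        expect_equal(got$p_value, binom_tail_bruteforce(x, n, p0), tolerance = 1e-12)
      }
    }
  }
})
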