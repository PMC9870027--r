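# Readers and writers for the external file dialects.

test_that("read_twas_csv parses a valid table and drops incomplete rows", {
  dir <- withr::local_tempdir()
  path <- write_twas_fixture(dir)
  tab <- read_twas_csv(path)
  expect_s3_class(tab, "twas_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "tissue"), "tissueA")
  expect_equal(tab$zscore, c(1.2, -0.4, 2.5))
  # p-values must be consistent with z under the two-sided normal relation
  expect_equal(tab$pvalue, 2 * pnorm(-abs(tab$zscore)), tolerance = 1e-6)

  # a row with empty zscore is dropped with a recorded count
  path2 <- write_twas_fixture(dir, zscore = c(1.2, NA, 2.5),
                              pvalue = c(0.2, 0.5, 0.01), file = "drop.csv")
  tab2 <- read_twas_csv(path2)
  expect_equal(nrow(tab2), 2L)
  expect_equal(attr(tab2, "n_dropped"), 1L)
})

test_that("read_twas_csv accepts column aliases and errors on missing columns", {
  dir <- withr::local_tempdir()
  aliased <- write_twas_fixture(dir, file = "alias.csv",
                                header = "gene_id,gene_name,zscore,pvalue,pred.perf.R2")
  expect_equal(nrow(read_twas_csv(aliased)), 3L)

  no_r2 <- file.path(dir, "nor2.csv")
  writeLines(c("gene,zscore,pvalue", "ENSG1,1.0,0.3"), no_r2)
  expect_error(read_twas_csv(no_r2), "pred_perf_r2", class = "gidee_format_error")

  empty <- write_twas_fixture(dir, zscore = c(NA, NA, NA),
                              pvalue = c(.1, .2, .3), file = "empty.csv")
  expect_error(read_twas_csv(empty), class = "gidee_empty_input")
})

test_that("zero p-values are floored to the smallest positive double at read time", {
  dir <- withr::local_tempdir()
  path <- write_twas_fixture(dir, pvalue = c(0, 0.5, 1e-300), file = "p0.csv")
  tab <- read_twas_csv(path)
  expect_true(all(tab$pvalue > 0))
  expect_equal(tab$pvalue[1], .Machine$double.xmin)
  expect_equal(attr(tab, "n_floored"), 1L)
})

test_that("read_expression_bed parses plain and gzipped BEDs identically", {
  dir <- withr::local_tempdir()
  mat <- matrix(rnorm(6), nrow = 2,
                dimnames = list(c("ENSG00000000001.5", "ENSG00000000002.5"),
                                c("S1", "S2", "S3")))
  plain <- read_expression_bed(write_bed_fixture(dir, mat))
  gz <- read_expression_bed(write_bed_fixture(dir, mat, file = "tissueB.bed", gzip = TRUE))
  expect_equal(dim(plain), c(2L, 3L))
  expect_equal(rownames(plain), rownames(mat))
  expect_equal(colnames(plain), colnames(mat))
  expect_equal(unname(plain), unname(mat), tolerance = 1e-12, ignore_attr = "tissue")
  expect_equal(unname(gz), unname(plain), ignore_attr = "tissue")
})

test_that("read_expression_bed reports duplicated genes and non-numeric cells", {
  dir <- withr::local_tempdir()
  mat <- matrix(1:6, nrow = 2, dimnames = list(c("ENSGX.1", "ENSGX.1"), c("S1", "S2", "S3")))
  expect_error(read_expression_bed(write_bed_fixture(dir, mat, file = "dup.bed")),
               "ENSGX.1", class = "gidee_format_error")

  bad <- file.path(dir, "bad.bed")
  writeLines(c("#chr\tstart\tend\tgene_id\tS1\tS2",
               "chr1\t1\t2\tENSG1\t0.5\toops"), bad)
  err <- tryCatch(read_expression_bed(bad), error = function(e) conditionMessage(e))
  expect_match(err, "row 1")
  expect_match(err, "column 2")
})

test_that("gene version stripping joins inconsistently versioned ids", {
  expect_equal(strip_gene_version(c("ENSG1.12", "ENSG1", "ENSG2.1.b")),
               c("ENSG1", "ENSG1", "ENSG2"))
})

test_that("ranking table writer round-trips values and column layout", {
  fit <- gidee_fixture_fit()
  tab <- ranking_table(fit)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_table(tab, path)
  back <- read_ranking_table(path)
  expect_equal(names(back), names(tab))
  for (cn in names(tab)) {
    if (is.numeric(tab[[cn]])) {
      expect_equal(back[[cn]], tab[[cn]], tolerance = 1e-12)
    } else {
      expect_identical(back[[cn]], tab[[cn]])
    }
  }
  # SZBP-only output: 11 fixed columns + average-rank + final-rank
  expect_equal(ncol(tab), 13L)

  # degenerate: empty record list still writes a header-only file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_table(tab[0, , drop = FALSE], path2)
  expect_equal(length(readLines(path2)), 1L)
  expect_equal(nrow(read_ranking_table(path2)), 0L)
})

test_that("sample-size reader handles header and no-header files", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "nohead.tsv")
  writeLines(c("tissueA\t100", "tissueB\t250"), f1)
  expect_equal(read_sample_sizes(f1), c(tissueA = 100L, tissueB = 250L))
  f2 <- file.path(dir, "head.tsv")
  writeLines(c("tissue\tn", "tissueA\t100"), f2)
  expect_equal(read_sample_sizes(f2), c(tissueA = 100L))
  f3 <- file.path(dir, "bad.tsv")
  writeLines(c("tissueA\t0"), f3)
  expect_error(read_sample_sizes(f3), class = "gidee_format_error")
})
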