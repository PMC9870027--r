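---
title: "Methods: ranking tissues by imputed differential expression enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking tissues by imputed differential expression enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gidee)
```

## The estimation problem

A TWAS produces, per tissue, a z-score and p-value for the association of
each gene's genetically imputed expression with a trait. If a tissue's
regulatory architecture matters for the trait, its distribution of
differential-expression p-values should be enriched for small values relative
to other tissues. `gidee` turns that idea into a per-tissue ranking. Three
features of the data make this harder than it sounds and drive the design:

1. **Imputation quality varies by gene.** Genes with poor prediction models
   contribute noise, so each tissue is first restricted to genes whose
   cross-validated prediction R² exceeds that tissue's median (strictly; the
   `r2_at_least_median` flag switches to `>=` for data with heavy ties, which
   would otherwise empty a degenerate table). The median is computed over the
   genes for which the TWAS produced a result — genes with missing R² cannot
   be ranked and are dropped at read time.
2. **Genes are co-expressed.** Neither a p-value combination nor a count of
   significant genes may treat genes as independent.
3. **Expression panels differ in size.** Larger panels support prediction
   models for more genes and detect associations with more power, so raw
   enrichment statistics correlate with panel sample size for reasons that
   have nothing to do with trait biology.

## The four tests

**Mean squared z-score (S).** The average of squared z-scores over retained
genes; squaring removes the sign (differential expression is directional, the
enrichment question is not). It uses the entire p-value distribution and is
the most powerful test against diffuse enrichment, but also the most exposed
to the sample-size artefact.

**Empirical Brown's combination (B).** Fisher's method applied to dependent
p-values is anti-conservative, so the χ² reference is rescaled using the
dependence visible in the tissue's own expression matrix. Each gene's
expression row is transformed to `w_g(s) = −2 ln(ecdf_g(x_g(s)))`; the
pairwise sample covariances of these rows estimate
`Var(ψ) = 4k + 2 Σ_{i<j} cov_ij` with `E(ψ) = 2k`, giving scale
`c = Var/(2E)` and degrees of freedom `f = 2E²/Var` for the statistic
`ψ = −2 Σ ln p`. Numerical conventions:

* The empirical CDF uses `<=`-counting, so its smallest value is `1/n` and
  the log never sees 0. Because ranks are unchanged by monotone maps,
  standardising the expression rows first would not change anything.
* Sampling noise can push the empirical `Var(ψ)` *below* its independence
  value `4k`, which would make the combination anti-conservative relative to
  Fisher; `c` is therefore clamped to `>= 1` (equivalently `f <= 2k`), making
  Fisher the exact independence limit of the implementation.
* A single p-value passes through unchanged (`c = 1`, `f = 2`).

**Binomial tests on effective counts (P, F).** The number of significant
genes is converted to an *effective* number of independent significant genes
before testing, because co-expressed significant genes are partly the same
evidence. The effective count is estimated from the eigenvalue spread of the
genes' Pearson correlation matrix (computed across samples on the normalised
expression values). Both published spectral estimators are available:
Nyholt's `1 + (M−1)(1 − Var(λ)/M)` and Li & Ji's
`Σ_i [ 1{|λ_i| ≥ 1} + frac(|λ_i|) ]`. The pipeline default is Li–Ji
(`meff_variant = "liji"`), the estimator the matSpD tool reports as its
recommended output; Nyholt is one switch away and all per-tissue effective
counts are written to the per-tissue statistics table so the choice is
auditable. Two significance thresholds define "tissue-wide significant":
Bonferroni at `alpha/Meff` (test P) and BH-FDR < `alpha` (test F), with
`alpha = 0.05` by default. The null proportion for tissue *i* is the
leave-one-tissue-out ratio `(Σ x − x_i)/(Σ n − n_i)`, computed on the
*unrounded* effective counts — the exact binomial test needs integer `x` and
`n`, so those are rounded, but rounding the null's numerator and denominator
would add avoidable bias. A tissue with no significant genes gets `x = 0`
and hence p = 1: it stays in the ranking as maximally unenriched rather than
being dropped, which would silently change the other tissues' null.

Degenerate inputs are short-circuited: an empty gene set has effective count
0, a single gene counts 1, and zero-variance genes are excluded from the
correlation (they carry no dependence information).

## Sample-size adjustment

S and B are regressed on panel sample size by OLS across tissues (at least 3
tissues required), and the residual is the adjusted statistic; residuals are
orthogonal to the predictor and invariant to affine rescaling of it, so the
adjusted ranking does not depend on the units in which sample size is
recorded. The Brown p-value is transformed to `−log10 p` before regression:
enrichment is monotone in significance, and a linear model on the
significance scale makes "larger residual = more enriched" hold uniformly
for both adjusted tests. The alternative — regressing the raw p-value and
flipping the residual sign — is available as `brown_raw_p = TRUE` for
comparison; it compresses all strong signals near p = 0 and is not the
default for that reason. The binomial tests are deliberately not
size-adjusted: their `x` and `n` are tissue-specific effective counts and
already reflect the tissue's panel. If all panels have equal size the
predictor is degenerate; the pipeline then refuses unless explicitly told to
fall back to mean-centred values.

## Ranks and combinations

Each test's statistics become midranks (ties get the mean of the positions
they span, so every column sums to `T(T+1)/2`): residuals are ranked
descending (larger = rank 1), binomial p-values ascending (smaller =
rank 1). All 15 non-empty subsets of the four tests are formed; a subset's
average rank per tissue is re-midranked into its final ranking. Labels
concatenate the member letters, except `{S, B}`, which carries its
conventional name **SZBP** and is the headline combination: the two
whole-distribution tests are individually the strongest and their average is
more stable than either alone, while the binomial tests read only the extreme
tail and are more sensitive to trait polygenicity and GWAS power.

For multi-trait summaries, traits are clustered on their final-rank vectors:
Pearson correlation between traits, Euclidean distance between the rows of
that correlation matrix, complete-linkage agglomeration; the dendrogram leaf
order arranges the heatmap. Distance on correlation rows (rather than the
more common `1 − r`) treats two traits as close when they relate to *all*
other traits similarly, which is the property a heatmap ordering should
preserve; the tested artefact is the leaf order and linkage, not the pixels.

## The synthetic scenario generator

`gidee_scenario()` / `simulate_gidee_data()` emulate the three inputs with a
known truth. Per tissue: the panel size is uniform on `samples_range`
(default 80–400, a down-scaled version of a real multi-tissue panel's ~70 to
~700 range); expression comes from a one-factor-per-block model
(`x = √ρ·f_b + √(1−ρ)·e`, default blocks of 10 at ρ = 0.3, a typical
magnitude for co-expression modules); null z-scores are
`N(0, 1 + slope·N_t/max N)` with `slope = 1` by default, planting the
power-versus-panel-size artefact that the residualisation must remove; in
the planted tissue a fraction (default 0.1) of genes is shifted by
±`effect_mean` (default 3, a clearly detectable but not overwhelming
signal); p-values are two-sided normal tails; prediction R² is Beta(2, 5)
(right-skewed mass around 0.2–0.4, as cross-validated prediction quality
tends to be), independent of z under the null. Per-tissue random streams are
derived from the scenario seed via fixed per-tissue offsets, so identical
scenario + seed reproduces files byte for byte.

What the generator does **not** emulate: tissue-sharing of true effects
(each tissue's z-scores are drawn independently, whereas real eQTL effects
are often active in many tissues), heavy-tailed or winner's-curse z
inflation, missingness patterns that correlate with R², isoform-level
signal, and the dependence between imputation quality and association
strength (a coupling option exists for stress-testing the prefilter). A
passing recovery test therefore shows the pipeline's statistics and ranking
behave correctly under controlled dependence and confounding — not that any
particular real trait's ranking is right.

## Problem sizes and verification

The test suite verifies the statistical primitives against independent
oracles (exhaustive binomial tail summation for all n ≤ 25, brute-force BH,
hand eigendecompositions, naive O(n³) complete-linkage agglomeration,
Fisher's closed form as the Brown independence limit), checks Brown's type-I
error on 1000 correlated-null replicates (20 genes, blocks of 5 at ρ = 0.5,
100 samples), and runs parameter recovery at 10 tissues × 500 genes over 100
seeded replicates with the planted tissue expected at SZBP rank 1 in at
least 95, plus a 200-replicate exchangeable-null check that one tissue's
final rank is uniform. The null check uses 200 genes per tissue — rank
uniformity does not depend on the gene count, and the smaller panel keeps
the suite fast. `scripts/acceptance.R` re-runs the pipeline at full 49-tissue
panel width.

## Known limitations

The output is a prioritisation, not a formal cross-tissue test: panel sizes,
gene sets and dependence structures differ across tissues in ways no single
null accommodates. Tissues can also rank highly because their expression is
strongly correlated with a truly causal tissue's; the ranking cannot
distinguish a pathogenic tissue from a well-correlated proxy, and users
should read high-ranking unexpected tissues with that in mind. The binomial
tests can be uninformative for weakly powered GWAS (few or no tissue-wide
significant genes ⇒ p = 1 in many tissues). Finally, p-values of exactly 0
in the input are floored to the smallest positive double at read time so
that log transforms are defined; ranks among such genes are not meaningful
below that floor.
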