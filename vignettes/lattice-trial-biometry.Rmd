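---
title: "Biometry of simple-lattice germplasm trials with lattivar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biometry of simple-lattice germplasm trials with lattivar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lattivar)
```

## The problem

Germplasm evaluation trials screen dozens of accessions — here, barley
landraces — for quantitative traits such as days to heading (DTH), plant
height, kernel counts and grain yield. With 49 entries, a randomized
complete block would put 49 plots in every block and swallow real field
heterogeneity, so such trials are laid out as a **simple (square)
lattice**: `g = k^2` genotypes in two replications, each replication split
into `k` incomplete blocks of `k` plots. Replication 1 blocks are the rows
of the `k x k` square of genotypes and replication 2 blocks its columns,
so any two genotypes meet in at most one block. `lattivar` implements the
complete downstream biometry: intra-block ANOVA, variance components and
selection parameters, correlation and path analysis, distance-based
clustering, and correlation-matrix PCA, together with a simulator that
generates trials with the same statistical anatomy for parameter-recovery
testing.

## The model and its analysis

For a plot carrying accession $a$ in block $b$ of replication $j$, trait
value

$$y_{ajb} = \mu + \rho_j + \beta_b + G_a + \varepsilon_{ajb},$$

with fixed replication shifts $\rho_j$, block effects
$\beta_b \sim N(0, \sigma^2_b)$, genotype effects
$G_a \sim N(0, \sigma^2_g)$ and plot error
$\varepsilon \sim N(0, \sigma^2_e)$. The intra-block analysis partitions
the total sum of squares sequentially by least-squares projection. Two
complementary orders share the replication and residual strata:

* replication → accessions (unadjusted) → blocks (adjusted),
* replication → blocks (unadjusted) → accessions (adjusted).

`anova_table()` computes both and reports the **block-adjusted accession
mean square** in its table (with the unadjusted one kept alongside), for a
reason that matters downstream: under the model above the adjusted
accession mean square has expectation

$$E[Msg_{adj}] = \sigma^2_e + \frac{kr}{k+1}\,\sigma^2_g,$$

which the concurrence structure of the square lattice delivers exactly
(the treatment information matrix eliminating blocks has eigenvalue 1 on
the $2(k-1)$-dimensional row/column contrast space and 2 on its
$(k-1)^2$-dimensional complement, giving trace $2k(k-1)$ over $k^2-1$
degrees of freedom). Inverting it yields the moment estimator implemented
by `variance_components()`:

$$\hat\sigma^2_g = \frac{(k+1)\,(Msg - Mse)}{k\,r}, \qquad
  \hat\sigma^2_e = Mse, \qquad \hat\sigma^2_p = \hat\sigma^2_g +
  \hat\sigma^2_e.$$

The unadjusted accession mean square, by contrast, expects
$r\sigma^2_g + \sigma^2_e$ plus a block-variance term, so feeding it
through the same formula inflates $\hat\sigma^2_g$ by the factor
$(k+1)/k$ plus half the block variance; the package therefore defaults to
the adjusted mean square (`genetic_params(..., msg = "adjusted")`) and the
unadjusted route stays available for comparison. The displayed four-row
table uses the adjusted accession stratum with the *unadjusted* block
stratum so its sums of squares add exactly to the total; the
block-adjusted block mean square is exposed as `ms_block_adjusted` since
classical lattice reports print both adjusted strata side by side despite
their non-additivity.

F tests use the intra-block residual; there is no recovery of inter-block
information (no REML), matching how such trials are conventionally
reported. Adjusted accession means come from the full fixed-effects fit
under sum-to-zero constraints (`adjusted_means()`), and Tukey mean
separation (`tukey_hsd()`) uses $HSD = q_{1-\alpha}(g, df_e)\sqrt{MSe/r}$
with the nominal replicate count; the mild effective-error inflation of
lattice-adjusted means is deliberately omitted and documented here.

## Selection parameters

`derived_parameters()` converts components to the breeder's scale:
GCV and PCV ($100\sqrt{\sigma^2}/\bar X$, in %), broad-sense heritability
$H^2 = 100\,\sigma^2_g/\sigma^2_p$, expected genetic advance
$GA = k_{sel}\,\sigma_p\,H^2$ with $k_{sel} = 2.063$ (the standardized
selection differential at 5% selection intensity) and GAM, the advance as
a percent of the mean. Negative $\hat\sigma^2_g$ is truncated at zero and
flagged rather than propagated into square roots. Classification
thresholds are configurable with the conventional defaults: CVs low < 10,
moderate 10–20, high > 20; $H^2$ low < 30, moderate 30–60, high > 60;
GAM low < 10, moderate 10–20, high > 20 (all %).

## Correlations and path analysis

Covariance components reuse the identical sequential projections
bilinearly ($CP_s = x' P_s y$), so `covariance_components(x, x)` equals
the variance component exactly and the polarization identity
$cov(x,y) = [var(x+y) - var(x) - var(y)]/2$ holds stratum by stratum.
Genotypic correlations are $cov_g/\sqrt{\sigma^2_{g,x}\sigma^2_{g,y}}$;
being ratios of moment estimates they can stray outside $[-1, 1]$, in
which case the stored value is clamped and the raw overflow flagged.
Significance marks use the t approximation
$t = r\sqrt{g-2}/\sqrt{1-r^2}$ at both levels; for genotypic correlations
this is approximate (their exact sampling variance is not tractable from
a single trial) and is documented as such.

Path analysis partitions each predictor's correlation with grain yield
into a direct effect and indirect effects via the other predictors by
solving $R_{xx} P = r_{xy}$ (`path_coefficients()`, a linear solve —
never an explicit inverse). Predictors default to the traits
significantly correlated with yield (`select_predictors()`). The residual
effect is reported as $1 - \sum_i P_i r_{iy}$ — the share of yield
variation left unexplained — with its square root as the residual path
coefficient; the share convention is primary because it is the quantity
customarily quoted alongside such tables. Rounded published inputs can
make it slightly negative, which triggers a warning rather than clamping.
A condition number above $10^3$ on $R_{xx}$ also warns, since direct
effects from near-collinear predictor sets amplify input rounding.

## Diversity and ordination

`standardize_and_distance()` z-scores each trait with the sample (n − 1)
standard deviation — the convention is switch-free but stated here because
published descriptions rarely specify it — and computes Euclidean
distances between accession profiles. `upgma_cluster()` implements UPGMA
agglomeration with the size-weighted average-linkage update and a
deterministic tie-break (the lexicographically smallest pair of smallest
member indices), so dendrograms are identical across platforms; merge
heights are the raw merging distances, and only the newick export halves
them into branch lengths so leaf depths equal half the root height
(ultrametric). The number of clusters K is a required input — no optimal-K
statistic is implied — and cluster labels follow the first accession index
in each cluster. Cluster means are taken on the raw (unstandardized)
adjusted means; the whole diversity stage runs on block-adjusted accession
means for consistency with the ANOVA.

`pca_correlation()` analyses the trait correlation matrix (via the SVD of
the standardized data), fixes each eigenvector's sign so its
largest-magnitude loading is positive (eigenvector signs being otherwise
arbitrary), and retains components with eigenvalue > 1 (Kaiser). Variance
explained is $100\lambda_j/t$ because the eigenvalues of a correlation
matrix sum to the trait count.

## The simulator and what passing tests mean

`simulate_trial()` draws genotype effect vectors from a multivariate
normal with covariance $D_g R_g D_g$, plot errors likewise from $R_e$,
and independent-per-trait block effects, on top of fixed replication
shifts. `barley_reference_model()` is the default study condition: an
11-trait model whose means, genotypic variances and both correlation
structures are calibrated to a published barley landrace trial
(7 × 7 lattice, 49 accessions). Two derived quantities need construction:
the error correlation matrix, obtained from the difference between
phenotypic and genotypic covariances and projected to the nearest
positive semi-definite correlation matrix (eigenvalue clipping at
$10^{-6}$, rescaled diagonal) because the published 2-decimal inputs are
not exactly consistent; and the block variances, back-calculated from the
block-adjusted mean squares via $E[MS_{block(adj)}] \approx \sigma^2_e +
(k/2)\,\sigma^2_b$. Replication shifts default to zero.

The simulator emulates the variance anatomy the estimators assume —
normal effects, homogeneous error, no genotype × environment interaction,
no spatial gradient within blocks, one season, one site. Passing
parameter-recovery tests therefore demonstrates that the estimator chain
is correct under its own model, not that real field data meet these
assumptions; skewed traits, spatial trend or G×E would need the
multi-environment machinery this package deliberately leaves out.

Recovery checks run 200 simulated trials at days-to-heading scale
($\sigma^2_g = 51.12$, $\sigma^2_e = 4.15$, $\sigma^2_b = 3$, with days
to maturity and grain yield correlated at their published genotypic
correlations): the median $\hat\sigma^2_g$ lands within 10% of truth, the
mean $\hat H^2$ within 3 points, and the mean genotypic correlation
within 0.05 of the planted value. These problem sizes (98-plot trials,
200 replicates; 8-leaf matrices for the 50-fold UPGMA oracle comparison)
were chosen so the whole suite exercises every estimator at the study's
own scale while remaining quick to run routinely.

## Numerical choices and degenerate inputs

* Sequential projections use QR factorizations with pivoting; sums of
  squares are additive to numerical precision and a property test holds
  them to 1e-8.
* Missing plots are an error naming the missing (accession, replication)
  cells — no imputation; duplicated plots are an error, never averaged.
* Zero-variance traits stop standardization and PCA by name; fewer than
  3 accessions stop the distance summary; a zero phenotypic variance
  yields $H^2 = 0$ rather than NaN.
* More traits than accessions − 1 gives trailing zero eigenvalues and a
  warning rather than failure.
* Accession ids are opaque strings in I/O; external tables with arbitrary
  ids are recoded internally (`design_from_plots()`) and restored on
  output.

## One worked flow

```{r, eval = FALSE}
design <- make_design(7)
model <- barley_reference_model()
plots <- simulate_trial(design, model, seed = 1)

anova_table(plots, design, "DTH")
genetic_params(plots, design)

corr <- correlation_matrices(plots, design, model$trait_names)
path_analysis(corr, "GY", "genotypic")

am <- sapply(model$trait_names, function(tr)
  adjusted_means(plots, design, tr)$adjusted_mean)
rownames(am) <- 1:49
d <- standardize_and_distance(am)
upgma_cluster(d$D, K = 6)
pca_correlation(am)

# or everything at once, written as a report bundle:
run_pipeline(pipeline_config(model = model, outdir = "report", seed = 1))
```

## Known limitations

No inter-block information recovery or REML variance components; no
standard errors for genotypic correlations or path coefficients; no
missing-plot handling; rectangular lattices, alpha designs and more than
two replications are out of scope, as are Mahalanobis distances,
alternative linkages, bootstrap support and varimax rotation. One printed
cell of the calibration table (the NKPS genetic-advance-as-percent value)
is internally inconsistent with its own GA and mean as published and is
excluded from the reproduction checks.
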