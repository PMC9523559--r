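---
title: "Scanning mitochondrial heteroplasmy against metabolite ratios"
author: "mtMetaboScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning mitochondrial heteroplasmy against metabolite ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtMetaboScan)
```

## The analysis

Mitochondrial DNA is present in many copies per cell, so a position can
carry a mixture of alleles within one person (heteroplasmy).
High-coverage sequencing of the 16,569 bp mitochondrial genome (rCRS
coordinates) quantifies that mixture directly from read counts, without
genotype calling: at position $i$ in individual $k$, $A$ is the read
count of the reference allele and $B$ the count of the cohort-wide
second most frequent allele. The response analysed here is the
heteroplasmy log-ratio

$$y_{ik} = \log_2\!\frac{B_{ik} + 2}{A_{ik} + 2},$$

with a pseudocount of 2 in numerator and denominator so that the
logarithm is defined for individuals carrying only the reference
allele. At a typical depth of ~3,500 reads the pseudocount is
negligible.

The design is an *inverted* association scan: the genetic quantity is
the response and the metabolic trait the predictor, reflecting the
working hypothesis that altered metabolite concentrations drive
mitochondrial mutation load rather than the reverse. For metabolite
ratio $j$ (all $N(N-1)/2$ pairwise concentration ratios of an
$N$-metabolite serum panel, plus each single metabolite) the model is

$$y_{ik} = \beta_0 + \beta_1 \mathrm{MR}_{jk} + \beta_2\,\mathrm{age}_k
 + \beta_3\,\mathrm{sex}_k + \beta_4\,\mathrm{Cov}_{ik}
 + \beta_5\,\mathrm{Batch}_k + e_{ijk},$$

fitted by ordinary least squares with the total coverage
$\mathrm{Cov}_{ik} = A_{ik}+B_{ik}$ and the sequencing plate (one-hot,
first plate as reference) as technical covariates. The Wald statistic
$z = \hat\beta_1/\mathrm{SE}(\hat\beta_1)$ is referred to the standard
normal, per the asymptotic-normality justification; p-values are
two-sided.

Because the scan fits every phenotype at every retained position,
`runScan()` residualises the response and all phenotype columns against
the covariate projection once per position and recovers each
$\hat\beta_1$ from the residual-on-residual slope
(Frisch–Waugh–Lovell). This is algebraically identical to the full OLS
fit — the test suite asserts agreement to $10^{-10}$ against
`fitInvertedModel()` — and turns an $s \times m$ scan into $s$ QR
decompositions plus matrix products.

## Quality control

**Step 1 (sequencing side).** Individuals flagged as DNA-contaminated,
individuals with overall mean coverage strictly below 1,000, and
individuals with type 2 diabetes (to avoid confounding) are removed
first, in that order with disjoint attribution. Position filters then
run on the retained cohort, sequentially: the PCR primer region
16,401–16,449 (inclusive, 49 positions), the reference-gap position
3,107 (spacer `N` in the rCRS), the phantom-mutation sites {3166, 3170,
16390}, the blacklisted sites {301, 302, 310, 316, 16182}, positions
with cohort mean coverage strictly below 1,000, and homoplasmic
positions. A position is called homoplasmic when the *maximum* over
individuals of the minor-allele fraction $B/(A+B)$ is strictly below
0.007; the per-cohort maximum is the least destructive reading of
"provides no heteroplasmy information" (the alternatives — mean or
per-individual calls — would discard more). All thresholds use strict
inequalities because they are printed as strict bounds. Every exclusion
is recorded in a `QCReport` whose validity check enforces conservation:
per-rule exclusions plus retained equal the input count. NUMTs
(nuclear copies of mtDNA) are deliberately *not* filtered: with
mtDNA-specific long-range PCR they contribute usable signal, so the
package only carries flags through.

The alternative allele is defined cohort-wide (the non-reference base
with the largest total count, ties broken alphabetically), not per
individual, so that each position defines exactly one phenotype. This
was a genuinely open choice; a per-individual definition would make
$y$ incomparable across individuals at multi-allelic positions.

**Step 2 (metabolite side).** Metabolites observed in fewer than 80% of
individuals are dropped (a metabolite at exactly 80% is kept). Observed
values more than three standard deviations from the per-metabolite mean
(both computed on observed values) are masked. Missing values —
including freshly masked outliers — are then imputed by chained
equations with predictive mean matching (PMM): cycling over incomplete
metabolites, each is regressed on all others, and every missing entry
receives a value copied from one of the 5 observed donors with the
nearest fitted mean, for 10 cycles. The order
completeness → mask → impute and the re-imputation of masked outliers
are design choices (the source rules are listed without an order);
imputing last guarantees a complete matrix for ratio enumeration. A
single completed panel is returned rather than pooled multiple
imputations because the downstream scan consumes one matrix and the
reported associations are single estimates. PMM guarantees every
imputed value is an observed value of the same metabolite, preserving
positivity, and donor draws are deterministic under the run seed.

Ratios are enumerated with the numerator earlier in panel order;
orientation is a presentation choice. The default scan uses
untransformed ratios, with a `log2Ratios` option; in log2 mode swapping
a pair's orientation negates the phenotype, flips the sign of
$\hat\beta_1$ and leaves $|z|$, the p-value and the P-gain unchanged.

## Multiple testing

With $m$ = 11,325 correlated ratio phenotypes, Bonferroni on $m$ would
be far too severe. The effective number of independent tests follows
the Li–Ji spectral rule: with eigenvalues $\lambda_i$ of the phenotype
correlation matrix,

$$M_\mathrm{eff} = \sum_i \left[ \mathbf{1}(|\lambda_i| \ge 1) +
 (|\lambda_i| - \lfloor |\lambda_i| \rfloor) \right],$$

and the familywise threshold is $\alpha / M_\mathrm{eff}$. For large
panels the eigenvalues are taken from the singular values of the
standardised phenotype matrix (rank at most $n$), which is exact and
avoids materialising an $m \times m$ matrix. By default the correlation
is computed over the ratio phenotypes after imputation
(`meffScope = "ratios"`); the trait set that should enter the
decomposition (ratios only, ratios plus singles, or traits crossed with
positions) is not unambiguously determined, so the scope is exposed as
an option.

A ratio can associate merely because one component does. The P-gain
statistic,
$p_\mathrm{gain} = \min(p_\mathrm{num}, p_\mathrm{den}) / p_\mathrm{ratio}$,
quantifies the improvement of the ratio over the better single
concentration; the conservative critical value is the number of
metabolites in the panel (151 for the full kit). An association is
flagged significant only when $p < \alpha/M_\mathrm{eff}$ *and*
$p_\mathrm{gain}$ exceeds the critical value, both strictly.

Genomic-control $\lambda$ — the median of the implied
$\chi^2_1$ statistics divided by 0.4549364 — is computed per phenotype
across positions, matching one QQ plot per scan; under a uniform null
it is 1 and the package's null simulations land within a few percent of
it.

## The synthetic cohort generator

No individual-level cohort data are distributable, so
`simulateMetabolites()`, `simulateCovariates()`, `simulateCounts()` and
`makeQCFixture()` generate cohorts with the statistical structure the
analysis assumes. Defaults mirror the analysed study: 1,163
individuals, a 151-metabolite panel split into the five serum classes
(1 hexose, 35 acylcarnitines, 14 amino acids, 14 sphingomyelins, 87
glycerophospholipids, scaled proportionally for smaller panels), and
Poisson read depth with mean 3,500.

Concentrations are log-normal on a common abundance scale
(`meanlog = log 50`, `sdlog = 0.25`, i.e. a coefficient of variation of
about 25%), equicorrelated within class at `blockCorrelation`
(default 0.5) and independent across classes. High-side outliers
(default 0.5% of cells, 3.5–6 SD above the mean) are injected after the
correlation structure; missingness (default 2%) is completely at
random, as nothing is stated about the missingness mechanism. The
common abundance scale is deliberate: causal effects are specified on
the raw-ratio scale, so ratios must be $O(1)$ — like the same-class
ratios the analysis highlights — for a fixed $\beta_1$ to have a
stable, interpretable magnitude. Cross-metabolite abundance
heterogeneity (hexose at mM against nM acylcarnitines) is therefore
*not* emulated; nor are assay batch effects on metabolites, informative
missingness, per-read sequencing error profiles, NUMTs or haplogroup
structure. Passing tests consequently certify the statistical machinery
of the pipeline, not robustness to those features of real data.

Counts follow the analysis model run generatively: at a causal position
the log2-odds of the minor-allele fraction is
$\eta_k = \eta_0 + \beta_1 (\mathrm{MR}_k - \overline{\mathrm{MR}})$
plus a per-plate shift ($\mathrm{SD}$ 0.2) and individual noise
(`noiseSd`, default 1 on the log2-odds scale); null positions omit the
ratio term. Centring the ratio leaves the slope untouched (the
intercept absorbs it) and keeps $\theta = 2^\eta/(1+2^\eta)$ in a
heteroplasmic range regardless of the ratio's mean. Then
$B \sim \mathrm{Binomial}(\mathrm{depth}, \theta)$, $A =
\mathrm{depth} - B$, and the two remaining bases stay at zero, matching
the two-allele structure the response uses. Age and sex are carried as
null covariates: the generative model assigns them no effect, and the
fitted model adjusts for them regardless.

The baseline log2-odds default, $\eta_0 = -4.5$ (mean minor fraction
≈ 0.04), is a free parameter — the distribution of heteroplasmy
fractions in the source cohort is not published. It was chosen so that
the expected minor count at 3,500-fold coverage (~150 reads) stays far
above the +2 pseudocount: in that regime
$\mathrm{E}[y\,|\,\mathrm{MR}] \approx \eta$ and the fitted slope is an
unbiased estimate of $\beta_1$. Driving $\theta$ toward the 0.007 call
threshold pushes minor counts into the pseudocount regime, where the
log-ratio response is no longer linear in the log2-odds and raw-scale
slopes attenuate — a limitation inherent to the pseudocount, not to the
implementation.

`makeQCFixture()` builds exact-count accounting cohorts: requested
numbers of contaminated, low-coverage and diabetic individuals
(pairwise disjoint), and low-coverage (depth 900) and homoplasmic
(zero minor reads) positions realised in the counts themselves, on top
of the fixed-site rules. One designated retained individual carries a
minor-allele fraction of ~0.028 at every heteroplasmic position so that
the homoplasmy rule separates the two groups exactly.

All randomness flows from one master seed per config; per-stage streams
are derived deterministically, so equal seeds give bit-identical
cohorts and the caller's RNG state is never disturbed.

## Numerical and degenerate-input choices

* Rank-deficient designs (constant age in a fixture, a collinear plate
  contrast) are handled by QR pivoting: redundant columns are dropped
  and reported; a constant predictor is an error, and within the scan
  such fits go to a skip ledger rather than vanishing silently.
* Minor-fraction maxima over whole-genome cohorts are computed in
  column-bound chunks so sparse minor-count matrices never densify; a
  position with zero total depth contributes fraction 0.
* Alphabetical tie-breaks (alternative allele, all-reference positions)
  make outputs reproducible; an all-reference position receives the
  alphabetically first non-reference base and is subsequently removed
  by the homoplasmy rule.
* Eigen decomposition (`liJiMeff`) and the SVD route
  (`meffFromPhenotypes`) are both provided and tested against each
  other to $10^{-8}$.

## Test and calibration problem sizes

The suite exercises the statistical properties at sizes chosen to make
Monte-Carlo error small relative to the assertion bands: type-I error
and p-value uniformity on 2,000 independent null fits at $n = 500$
(rejection rate within binomial 99% bounds of 0.05,
Kolmogorov–Smirnov at $\alpha = 0.01$); parameter recovery over 200
replicates at $n = 1{,}000$ for $\beta_1 \in \{0.5, 0.909, 1.5\}$
(mean bias within three Monte-Carlo standard errors, 95% CI coverage in
[0.92, 0.98]); and planted-signal recovery through the full pipeline in
50 seeded runs of a 200-individual, 50-position, 10-metabolite cohort
with one causal pair at $\beta_1 = 1.5$. In the occasional run the top
hit is a *proxy* ratio — one sharing a metabolite with the causal pair
at the causal position — which is a real feature of correlated ratio
phenotypes, and exactly the ambiguity the P-gain statistic exists to
police.

## Known limitations

* The fitted model is homoscedastic OLS; the binomial variance of $y$
  shrinks as $\theta$ grows, so coverage-weighted or GLM-style fits
  could be slightly more efficient. The source analysis uses OLS, so
  the package does too.
* The homoplasmy call (max over individuals) and the Meff trait scope
  are interpretations of under-specified rules; both are exposed as
  parameters.
* Published cohort-specific values (the 404 significant positions, the
  specific Table-1 effect sizes) cannot be reproduced without the
  non-public cohort; the package reproduces the QC arithmetic, the
  printed thresholds and the statistical calibration of the method
  instead.
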