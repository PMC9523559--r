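# mtMetaboScan

Association scanning of mitochondrial DNA heteroplasmy against serum
metabolite concentration ratios — an "inverted" mitochondrial GWAS in
which the genetic quantity is the response.

## The problem

Mitochondrial DNA exists in many copies per cell, so a position can
carry a mixture of alleles within one individual (heteroplasmy).
High-coverage sequencing quantifies that mixture directly from read
counts. The working hypothesis behind this design is that altered
metabolite concentrations drive mitochondrial mutation load; the
natural regression therefore puts heteroplasmy on the left-hand side.
The package is for statistical geneticists and metabolomics analysts
who want that analysis as a tested, reusable pipeline: per-position
allele counts and a metabolite panel in, QC ledgers and a gated
association table out.

## The model

For position *i*, metabolite ratio *j* and individual *k*, with *A* the
reference-allele read count and *B* the count of the cohort-wide second
most frequent allele, the response is the heteroplasmy log-ratio
`y = log2((B + 2) / (A + 2))` and the fitted model is

    y_ik = b0 + b1 * MR_jk + b2 * age_k + b3 * sex_k
          + b4 * Cov_ik + b5 * Batch_k + e_ijk

by OLS, where `MR_jk` runs over all N(N−1)/2 pairwise concentration
ratios and all single metabolites, `Cov = A + B` is the position's
total coverage and `Batch` the sequencing plate. Wald p-values use the
standard normal. Two gates control multiple testing: the Li–Ji
effective number of independent tests `Meff` from the eigenvalue
spectrum of the phenotype correlation matrix (threshold `alpha/Meff`),
and the P-gain `min(p_num, p_den)/p_ratio`, which must exceed the
number of panel metabolites for a ratio to count as more informative
than its components. Genomic-control lambda (median chi-square over
0.4549) diagnoses inflation.

Upstream of the scan sit the two QC stages: individual filters
(contamination, mean coverage < 1000, diabetes), position filters
(primer region 16401–16449, reference gap 3107, phantom sites,
blacklist, mean coverage < 1000, homoplasmy at max minor fraction
< 0.007), then metabolite completeness (≥ 80% observed), 3-SD outlier
masking and chained predictive-mean-matching imputation.

Because no individual-level cohort of this kind is public, the package
ships a synthetic-cohort generator (`simulateCohort()`,
`makeQCFixture()`) whose defaults mirror the study conditions (1,163
individuals, 151 metabolites in five classes, 3,500-fold mean
coverage) and whose planted causal effects give every downstream stage
a ground truth to recover.

## Worked example

```r
library(mtMetaboScan)

cfg <- SimulationConfig(
  nIndividuals = 300, nMetabolites = 8, nPositions = 40,
  causalEffects = data.frame(position = 12, numerator = "AC001",
                             denominator = "PC001", beta = 1.2),
  seed = 20)
cohort <- simulateCohort(cfg)

bundle <- runPipeline(runConfig(
  counts = cohort$counts, panel = cohort$panel,
  covariates = cohort$covariates, reference = cohort$reference,
  seed = 20))

bundle$meff
#> MeffResult: M = 28 traits, Meff = 11.00
#>   alpha = 0.05  ->  threshold = 0.00454545

head(bundle$results[, c("position", "phenotype_id", "type",
                        "beta", "se", "p", "p_gain", "significant")], 4)
#>   position phenotype_id  type     beta        se            p       p_gain significant
#> 1       12  AC001/PC001 ratio 1.409862 0.1520429 1.813374e-20 2.096138e+09        TRUE
#> 2       12  AC001/PC004 ratio 1.265737 0.1699839 9.605257e-14 3.957293e+02        TRUE
#> 3       12  AC001/PC003 ratio 1.231134 0.1681049 2.414002e-13 1.574598e+02        TRUE
#> 4       12  AC001/PC002 ratio 1.333332 0.1850018 5.714399e-13 6.651760e+01        TRUE
```

The planted pair (position 12, `AC001/PC001`) tops the scan with
`beta` ≈ 1.4 against a planted 1.2 (within sampling error at n = 300),
a P-gain of ~2×10⁹, and the runner-up rows are proxy ratios sharing the
causal numerator — the correlation structure the P-gain gate exists to
police. The 28 scanned phenotypes collapse to an effective 11
independent tests, giving the 4.5×10⁻³ threshold shown. With
`outDir` set, `runPipeline()` also writes the QC ledgers,
`results.tsv` (sorted by p), a Table-style `significant.tsv` with rCRS
gene annotation, `meff.tsv`, `lambda.tsv` and optional Manhattan/QQ
plots.

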