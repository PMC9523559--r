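Package: mtMetaboScan
Title: Inverted Mitochondrial GWAS of Heteroplasmy Against Metabolite Ratios
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Association scanning of mitochondrial DNA heteroplasmy against
    serum metabolite concentration ratios. From per-position allele read
    counts and a metabolite panel, the package performs two-step quality
    control (individual and position filters on the sequencing side;
    completeness filtering, outlier masking and predictive-mean-matching
    chained imputation on the metabolite side), defines per-position
    heteroplasmy log2-ratio phenotypes, fits the inverted regression of
    heteroplasmy on every pairwise metabolite ratio and every single
    metabolite with age, sex, coverage and sequencing-plate covariates, and
    gates significance by a Li-Ji effective-number-of-tests threshold
    combined with the P-gain statistic. A synthetic-cohort generator with
    known ground truth supports testing and calibration without access to
    cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, Metabolomics, Sequencing, QualityControl, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
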