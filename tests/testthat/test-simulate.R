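test_that("metabolite panel has the requested shape, positivity and missingness", {
  cfg <- tinyConfig(nIndividuals = 100L, nMetabolites = 10L, missingRate = 0)
  panel <- simulateMetabolites(cfg)
  conc <- concentrations(panel)
  expect_identical(dim(conc), c(10L, 100L))
  expect_false(anyNA(conc))
  expect_true(all(conc > 0))

  # observed missing fraction within binomial 99% bounds of the rate
  cfg2 <- tinyConfig(nIndividuals = 500L, nMetabolites = 10L,
                     missingRate = 0.1, seed = 11L)
  conc2 <- concentrations(simulateMetabolites(cfg2))
  nMiss <- sum(is.na(conc2))
  cells <- length(conc2)
  bounds <- qbinom(c(0.005, 0.995), cells, 0.1)
  expect_gte(nMiss, bounds[1])
  expect_lte(nMiss, bounds[2])
})

test_that("block correlation is realised within metabolite classes", {
  cfg <- tinyConfig(nIndividuals = 500L, nMetabolites = 10L,
                    blockCorrelation = 0.9, seed = 3L)
  panel <- simulateMetabolites(cfg)
  cls <- metaboliteClasses(panel)
  block <- names(cls)[cls == "glycerophospholipid"]
  expect_gte(length(block), 2L)
  conc <- concentrations(panel)
  r_within <- cor(conc[block[1], ], conc[block[2], ])
  expect_gt(r_within, 0.7)
  # across blocks: uncorrelated up to sampling noise
  other <- names(cls)[cls != "glycerophospholipid"][1]
  r_across <- cor(conc[block[1], ], conc[other, ])
  expect_lt(abs(atanh(r_across)), 3 / sqrt(500 - 3))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- tinyConfig(missingRate = 0.05, outlierRate = 0.01)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(SummarizedExperiment::assays(a$counts),
                   SummarizedExperiment::assays(b$counts))
  expect_identical(concentrations(a$panel), concentrations(b$panel))
  expect_identical(a$covariates, b$covariates)
  d <- simulateCohort(tinyConfig(seed = 8L))
  expect_false(identical(concentrations(a$panel), concentrations(d$panel)))
})

test_that("simulated depth matches the configured mean coverage", {
  cfg <- tinyConfig(nIndividuals = 500L, nPositions = 20L)
  coh <- simulateCohort(cfg)
  total <- Reduce(`+`, lapply(c("A", "C", "G", "T"), function(b)
    SummarizedExperiment::assay(coh$counts, b)))
  expect_lt(abs(mean(total) - 3500) / 3500, 0.01)
  # counts are non-negative and only two bases carry reads per position
  perBase <- vapply(c("A", "C", "G", "T"), function(b)
    Matrix::rowSums(SummarizedExperiment::assay(coh$counts, b)),
    numeric(nrow(coh$counts)))
  expect_true(all(rowSums(perBase > 0) <= 2L))
})

test_that("null positions show no association with a metabolite ratio", {
  cfg <- tinyConfig(nIndividuals = 500L, nPositions = 1L, seed = 21L)
  coh <- simulateCohort(cfg)
  truth <- SummarizedExperiment::assay(coh$panel, "truth")
  mr <- truth["AC001", ] / truth["PC001", ]
  ab <- heteroplasmyPhenotype(coh$counts,
                              callAlleles(coh$counts, coh$reference), 1L)
  r <- cor(ab$y, mr)
  expect_lt(abs(atanh(r)), 3 / sqrt(500 - 3))
})

test_that("theta = 0 gives pure-reference counts and negative log-ratios", {
  cfg <- tinyConfig(nIndividuals = 50L, nPositions = 4L,
                    baselineLogit = -Inf)
  coh <- simulateCohort(cfg)
  al <- callAlleles(coh$counts, coh$reference)
  expect_true(all(coh$truth$trueTheta == 0))
  for (p in seq_len(4)) {
    ph <- heteroplasmyPhenotype(coh$counts, al, p)
    expect_true(all(ph$y < 0))
  }
  total <- Reduce(`+`, lapply(c("A", "C", "G", "T"), function(b)
    SummarizedExperiment::assay(coh$counts, b)))
  refOnly <- vapply(seq_len(4), function(i) {
    b <- coh$truth$refBase[i]
    all(SummarizedExperiment::assay(coh$counts, b)[i, ] == total[i, ])
  }, logical(1))
  expect_true(all(refOnly))
})

test_that("a planted positive effect yields a positive slope of y on MR", {
  cfg <- tinyConfig(nIndividuals = 1000L, nPositions = 2L,
                    causalEffects = data.frame(
                      position = 1L, numerator = "AC001",
                      denominator = "PC001", beta = 0.9),
                    seed = 5L)
  coh <- simulateCohort(cfg)
  truth <- SummarizedExperiment::assay(coh$panel, "truth")
  mr <- truth["AC001", ] / truth["PC001", ]
  al <- callAlleles(coh$counts, coh$reference)
  y <- heteroplasmyPhenotype(coh$counts, al, 1L)$y
  expect_gt(coef(lm(y ~ mr))[["mr"]], 0)
})

test_that("causal ratios must reference panel metabolites", {
  cfg <- tinyConfig(causalEffects = data.frame(
    position = 1L, numerator = "NOPE", denominator = "PC001", beta = 1))
  panel <- simulateMetabolites(cfg)
  covs <- simulateCovariates(cfg)
  expect_error(simulateCounts(cfg, panel, covs), "NOPE")
})

test_that("QC fixture realises the requested flag counts exactly", {
  spec <- QCFixtureSpec(nTotal = 50L, nContaminated = 3L,
                        nLowCoverageIndividuals = 2L, nDiabetic = 5L,
                        nLowcovPositions = 20L,
                        nHomoplasmicPositions = 100L, genomeLength = 600L)
  fx <- makeQCFixture(spec)
  expect_identical(sum(fx$covariates$contaminated), 3L)
  expect_identical(sum(fx$covariates$diabetic), 5L)
  expect_length(fx$flags$lowCoverageIndividuals, 2L)
  expect_length(fx$flags$lowCoveragePositions, 20L)
  expect_length(fx$flags$homoplasmicPositions, 100L)
  # flag groups pairwise disjoint
  expect_identical(
    anyDuplicated(c(fx$flags$contaminated, fx$flags$lowCoverageIndividuals,
                    fx$flags$diabetic)), 0L)

  # homoplasmic positions carry max minor fraction < 0.007 in the counts
  al <- callAlleles(fx$counts, fx$reference)
  for (b in c("C", "G", "T")) {
    m <- SummarizedExperiment::assay(fx$counts, b)
    expect_true(all(Matrix::rowSums(m)[fx$flags$homoplasmicPositions] == 0))
  }
  # heteroplasmic positions exceed the threshold for some individual
  Cm <- SummarizedExperiment::assay(fx$counts, "C")
  Am <- SummarizedExperiment::assay(fx$counts, "A")
  het <- fx$flags$heteroplasmicPositions
  frac <- Matrix::rowSums(Cm)[het] /
    (Matrix::rowSums(Cm)[het] + 3500)
  expect_true(all(frac >= 0.007))

  # empty spec flags nothing
  fx0 <- makeQCFixture(QCFixtureSpec(nTotal = 5L, genomeLength = 50L))
  expect_false(any(fx0$covariates$contaminated))
  expect_false(any(fx0$covariates$diabetic))
})
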