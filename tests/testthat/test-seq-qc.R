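test_that("individual exclusion honours flags and the strict coverage bound", {
  # 3 individuals x 2 positions; per-individual mean depths 1000, 999.5, 3000
  A <- cbind(c(1000L, 1000L), c(999L, 1000L), c(3000L, 3000L))
  dimnames(A) <- list(c("1", "2"), sprintf("ind_%05d", 1:3))
  cov <- toyCovariates(3)
  ac <- toyCounts(A, colData = cov)
  res <- excludeIndividuals(ac, cov, minMeanCoverage = 1000)
  expect_identical(exclusionCounts(res$report)[["low_mean_coverage"]], 1L)
  expect_setequal(retainedIds(res$report), c("ind_00001", "ind_00003"))

  # no flags, everything covered: nothing excluded
  res2 <- excludeIndividuals(toyCounts(A[, 3, drop = FALSE],
                                       colData = cov[3, , drop = FALSE]),
                             cov[3, , drop = FALSE])
  expect_identical(sum(exclusionCounts(res2$report)), 0L)

  # contamination and diabetes flags are honoured with disjoint attribution
  cov3 <- toyCovariates(3, contaminated = c(TRUE, FALSE, FALSE),
                        diabetic = c(TRUE, FALSE, TRUE))
  res3 <- excludeIndividuals(ac, cov3)
  cnt <- exclusionCounts(res3$report)
  expect_identical(unname(cnt[c("contamination", "low_mean_coverage",
                                "diabetes")]), c(1L, 1L, 1L))
  expect_identical(retainedIds(res3$report), character(0))

  # missing covariate rows are an error
  expect_error(excludeIndividuals(ac, cov[1:2, ]), "missing")
})

test_that("alternative allele is the cohort-wide runner-up with alphabetical ties", {
  # position 1: ref G dominating, A runner-up; position 2: tie C == T;
  # position 3: all reads reference
  G <- rbind(c(5000L, 5000L), c(0L, 0L), c(0L, 0L))
  A <- rbind(c(30L, 20L), c(1000L, 1000L), c(2000L, 2000L))
  C <- rbind(c(10L, 5L), c(40L, 10L), c(0L, 0L))
  T <- rbind(c(0L, 0L), c(25L, 25L), c(0L, 0L))
  dimnames(G) <- dimnames(A) <- dimnames(C) <- dimnames(T) <-
    list(as.character(1:3), c("i1", "i2"))
  ref <- Biostrings::DNAString("GAA")
  ac <- AlleleCounts(A = A, C = C, G = G, T = T, positions = 1:3)
  al <- callAlleles(ac, ref)
  expect_identical(al$ref, c("G", "A", "A"))
  expect_identical(al$alt, c("A", "C", "C"))

  # reference gap (N) is flagged, not assigned an alternative
  al2 <- callAlleles(ac, Biostrings::DNAString("GNA"))
  expect_true(al2$refGap[2])
  expect_true(is.na(al2$alt[2]))

  # reference shorter than the largest position is an error
  expect_error(callAlleles(ac, Biostrings::DNAString("GA")), "shorter")
})

test_that("homoplasmy call uses a strict bound on the max minor fraction", {
  # one individual, depth 10000: fractions 0.0069 and 0.0071
  A <- matrix(c(9931L, 9929L), 2, 1)
  C <- matrix(c(69L, 71L), 2, 1)
  dimnames(A) <- dimnames(C) <- list(c("1", "2"), "i1")
  ac <- toyCounts(A, C = C)
  al <- callAlleles(ac, toyReference(2))
  res <- filterPositions(ac, al, minMeanCoverage = 1000,
                         primerRegion = NULL, phantom = integer(0),
                         blacklist = integer(0))
  expect_identical(excludedIds(res$report)$homoplasmic, "1")
  expect_identical(retainedIds(res$report), "2")
})

test_that("position filters account exactly and are idempotent", {
  spec <- QCFixtureSpec(nTotal = 40L, nContaminated = 3L,
                        nLowCoverageIndividuals = 2L, nDiabetic = 5L,
                        nLowcovPositions = 20L,
                        nHomoplasmicPositions = 100L, genomeLength = 600L)
  fx <- makeQCFixture(spec)
  st1 <- excludeIndividuals(fx$counts, fx$covariates)
  expect_identical(sum(exclusionCounts(st1$report)), 10L)
  al <- callAlleles(st1$counts, fx$reference)
  st2 <- filterPositions(st1$counts, al)
  cnt <- exclusionCounts(st2$report)
  # genome of 600 bp contains 4 blacklisted sites and none of the other
  # fixed sites
  expect_identical(unname(cnt), c(0L, 0L, 0L, 4L, 20L, 100L))
  expect_identical(length(retainedIds(st2$report)), 600L - 124L)

  # ledger conservation
  expect_identical(sum(cnt) + length(retainedIds(st2$report)), 600L)

  # idempotence: re-running on the filtered output removes nothing
  again <- filterPositions(st2$counts, st2$alleles)
  expect_identical(sum(exclusionCounts(again$report)), 0L)
  agi <- excludeIndividuals(st1$counts, fx$covariates)
  expect_identical(sum(exclusionCounts(agi$report)), 0L)
})

test_that("fixed-site filter order does not change the retained set", {
  fx <- makeQCFixture(QCFixtureSpec(nTotal = 10L, nLowcovPositions = 5L,
                                    nHomoplasmicPositions = 30L,
                                    genomeLength = 400L))
  al <- callAlleles(fx$counts, fx$reference)
  r1 <- filterPositions(fx$counts, al, phantom = c(310L, 316L),
                        blacklist = c(301L, 302L))
  r2 <- filterPositions(fx$counts, al, phantom = c(301L, 302L),
                        blacklist = c(310L, 316L))
  expect_identical(retainedIds(r1$report), retainedIds(r2$report))
})

test_that("an empty cohort cannot be position-filtered", {
  A <- matrix(integer(0), 2, 0, dimnames = list(c("1", "2"), NULL))
  ac <- toyCounts(A)
  al <- S4Vectors::DataFrame(position = 1:2, ref = c("A", "A"),
                             alt = c("C", "C"), refGap = c(FALSE, FALSE))
  expect_error(filterPositions(ac, al), "empty cohort")
})
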