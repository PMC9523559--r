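test_that("heteroplasmy log-ratio handles symmetry, zeros and bad input", {
  expect_identical(heteroplasmyLogRatio(350, 350), 0)
  expect_equal(heteroplasmyLogRatio(3500, 0), log2(2 / 3502))
  expect_equal(heteroplasmyLogRatio(3500, 0), -10.774, tolerance = 1e-4)
  # antisymmetry under count swap
  A <- c(0, 5, 3500, 17)
  B <- c(2, 5, 120, 0)
  expect_equal(heteroplasmyLogRatio(A, B), -heteroplasmyLogRatio(B, A))
  expect_true(all(is.finite(heteroplasmyLogRatio(A, B))))
  expect_error(heteroplasmyLogRatio(-1, 5), "non-negative")
})

test_that("the inverted fit matches a closed-form normal-equations oracle", {
  set.seed(4)
  n <- 12L
  cov <- toyCovariates(n)
  mr <- runif(n, 0.5, 2)
  coverage <- rpois(n, 3000)
  y <- 0.3 + 1.2 * mr + 0.01 * cov$age + rnorm(n, 0, 0.2)
  fit <- fitInvertedModel(y, mr, cov, coverage)

  # independent oracle: solve the normal equations directly
  X <- cbind(1, mr, cov$age, cov$sex, coverage,
             as.integer(cov$batch == 2))
  XtX <- t(X) %*% X
  betaHat <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% betaHat
  s2 <- sum(resid^2) / (n - ncol(X))
  seHat <- sqrt(s2 * diag(solve(XtX)))
  expect_equal(fit$beta, unname(betaHat[2]), tolerance = 1e-10)
  expect_equal(fit$se, unname(seHat[2]), tolerance = 1e-10)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$beta / fit$se)), tolerance = 1e-12)

  # degenerate designs error out
  expect_error(fitInvertedModel(y, rep(1, n), cov, coverage), "constant")
})

test_that("a planted effect at the study scale is recovered within 3 SE", {
  cfg <- tinyConfig(nIndividuals = 1163L, nPositions = 2L,
                    causalEffects = data.frame(
                      position = 1L, numerator = "AC001",
                      denominator = "PC001", beta = 0.909),
                    seed = 31L)
  coh <- simulateCohort(cfg)
  al <- callAlleles(coh$counts, coh$reference)
  ph <- heteroplasmyPhenotype(coh$counts, al, 1L)
  truth <- SummarizedExperiment::assay(coh$panel, "truth")
  mr <- truth["AC001", ] / truth["PC001", ]
  fit <- fitInvertedModel(ph$y, mr, coh$covariates, ph$coverage)
  expect_lt(abs(fit$beta - 0.909), 3 * fit$se)
})

test_that("the scan emits one row per position-phenotype pair and matches single fits", {
  cfg <- tinyConfig(nIndividuals = 150L, nMetabolites = 3L, nPositions = 3L,
                    seed = 13L)
  coh <- simulateCohort(cfg)
  al <- callAlleles(coh$counts, coh$reference)
  ph <- makeScanPhenotypes(coh$panel)
  res <- runScan(coh$counts, al, ph, coh$covariates)

  # 3 positions x (3 ratios + 3 singles)
  expect_identical(sum(res$type == "ratio"), 9L)
  expect_identical(sum(res$type == "single"), 9L)

  # Frisch-Waugh equivalence: the residualised scan reproduces the full
  # per-pair OLS fit
  pick <- res[res$position == 2 & res$phenotype_id == ph$index$phenotype_id[1], ]
  php <- heteroplasmyPhenotype(coh$counts, al, 2L)
  direct <- fitInvertedModel(php$y, ph$values[colnames(coh$counts), 1],
                             coh$covariates, php$coverage)
  expect_equal(pick$beta, direct$beta, tolerance = 1e-10)
  expect_equal(pick$se, direct$se, tolerance = 1e-10)
  expect_equal(pick$p, direct$p, tolerance = 1e-10)

  # determinism
  res2 <- runScan(coh$counts, al, ph, coh$covariates)
  expect_identical(res, res2)
})

test_that("log2-ratio orientation flips the sign but not the p-value", {
  cfg <- tinyConfig(nIndividuals = 120L, nMetabolites = 3L, nPositions = 1L,
                    seed = 17L)
  coh <- simulateCohort(cfg)
  al <- callAlleles(coh$counts, coh$reference)
  ph <- makeScanPhenotypes(coh$panel, log2Ratios = TRUE,
                           includeSingles = FALSE)
  flipped <- ph
  flipped$values <- -ph$values
  r1 <- runScan(coh$counts, al, ph, coh$covariates)
  r2 <- runScan(coh$counts, al, flipped, coh$covariates)
  expect_equal(r1$beta, -r2$beta, tolerance = 1e-12)
  expect_equal(abs(r1$z), abs(r2$z), tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("degenerate phenotypes are reported in the skip ledger", {
  cfg <- tinyConfig(nIndividuals = 60L, nMetabolites = 3L, nPositions = 2L)
  coh <- simulateCohort(cfg)
  al <- callAlleles(coh$counts, coh$reference)
  ph <- makeScanPhenotypes(coh$panel, includeSingles = FALSE)
  ph$values[, 2] <- 1  # constant phenotype
  res <- runScan(coh$counts, al, ph, coh$covariates)
  sk <- attr(res, "skipped")
  expect_identical(nrow(sk), 2L)
  expect_true(all(sk$phenotype_id == ph$index$phenotype_id[2]))
  expect_false(ph$index$phenotype_id[2] %in% res$phenotype_id)
})

test_that("genomic-control lambda is calibrated and scale-equivariant", {
  expect_equal(genomicLambda(rep(0.5, 7)), 1.0, tolerance = 1e-12)

  set.seed(2)
  p <- runif(1e5)
  expect_lt(abs(genomicLambda(p) - 1), 0.02)

  # doubling every chi-square statistic doubles lambda
  chi <- qchisq(p[1:1000], df = 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, df = 1, lower.tail = FALSE)
  expect_equal(genomicLambda(p2), 2 * genomicLambda(p[1:1000]),
               tolerance = 1e-10)

  expect_error(genomicLambda(numeric(0)), "no p-values")
  expect_error(genomicLambda(c(0.5, 0)), "0, 1")
})
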