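makePanel <- function(conc) {
  MetabolitePanel(conc = conc, class = rep("glycerophospholipid", nrow(conc)))
}

test_that("completeness filter keeps metabolites observed in at least 80%", {
  n <- 100L
  conc <- matrix(runif(4 * n, 1, 10), 4, n,
                 dimnames = list(c("m79", "m80", "full", "none"),
                                 sprintf("i%03d", 1:n)))
  conc["m79", 1:21] <- NA    # 79% observed -> dropped
  conc["m80", 1:20] <- NA    # exactly 80% -> kept
  conc["none", ] <- NA       # fully missing -> dropped
  res <- applyCompletenessFilter(makePanel(conc))
  expect_setequal(rownames(res$panel), c("m80", "full"))
  expect_setequal(excludedIds(res$report)$incomplete, c("m79", "none"))

  # fully observed panel passes unchanged
  full <- makePanel(matrix(runif(20, 1, 10), 2, 10,
                           dimnames = list(c("a", "b"), paste0("i", 1:10))))
  expect_identical(rownames(applyCompletenessFilter(full)$panel),
                   c("a", "b"))
})

test_that("outlier masking uses the 3-SD rule on observed values", {
  set.seed(1)
  x <- c(rnorm(60, 10, 1), 30)  # last value far out
  conc <- rbind(spread = x, flat = rep(5, 61), center = rnorm(61, 10, 1))
  colnames(conc) <- sprintf("i%03d", 1:61)
  res <- maskOutliers(makePanel(conc), kSd = 3)
  out <- concentrations(res$panel)

  # independent check: a cell is masked iff |x - mean| > 3 sd (per row)
  for (r in rownames(conc)) {
    mu <- mean(conc[r, ])
    sg <- sd(conc[r, ])
    expected <- if (sg > 0) abs(conc[r, ] - mu) > 3 * sg else
      rep(FALSE, ncol(conc))
    expect_identical(unname(is.na(out[r, ])), unname(expected))
  }
  expect_true(is.na(out["spread", "i061"]))
  # a value at the mean survives; constant metabolites mask nothing
  expect_false(anyNA(out["flat", ]))
  expect_identical(res$masked$metabolite, "spread")
})

test_that("chained PMM imputes from observed donor values, deterministically", {
  set.seed(42)
  n <- 80L
  base <- rnorm(n)
  conc <- rbind(
    a = exp(base + rnorm(n, 0, 0.1)) + 1,
    b = exp(base + rnorm(n, 0, 0.1)) + 1,
    c = exp(rnorm(n)) + 1
  )
  colnames(conc) <- sprintf("i%03d", seq_len(n))
  holes <- cbind(c(1, 1, 2, 3), c(3, 10, 20, 40))
  withNA <- conc
  withNA[holes] <- NA
  panel <- makePanel(withNA)

  done <- imputePMM(panel, seed = 99L)
  cc <- concentrations(done)
  expect_false(anyNA(cc))
  # donor-set membership: every imputed value is an observed value of the
  # same metabolite
  for (k in seq_len(nrow(holes))) {
    r <- holes[k, 1]
    expect_true(cc[holes[k, , drop = FALSE]] %in%
                  withNA[r, !is.na(withNA[r, ])])
  }
  # determinism under the same seed; a different seed may differ
  expect_identical(cc, concentrations(imputePMM(panel, seed = 99L)))

  # complete panels come back unchanged
  expect_identical(concentrations(imputePMM(makePanel(conc), seed = 1L)),
                   conc)
  # metabolites with < 2 observed values are an error
  bad <- conc
  bad[1, -1] <- NA
  expect_error(imputePMM(makePanel(bad), seed = 1L), "fewer than 2")
})

test_that("ratio enumeration yields all unordered pairs in panel order", {
  conc <- matrix(runif(15, 1, 10), 3, 5,
                 dimnames = list(c("x", "y", "z"), paste0("i", 1:5)))
  er <- enumerateRatios(makePanel(conc))
  expect_identical(nrow(er$index), 3L)
  expect_identical(er$index$numerator, c("x", "x", "y"))
  expect_identical(er$index$denominator, c("y", "z", "z"))
  expect_equal(er$values[, "x/y"], conc["x", ] / conc["y", ],
               ignore_attr = TRUE)
  expect_true(all(er$values > 0))

  # two metabolites give exactly one phenotype
  er2 <- enumerateRatios(makePanel(conc[1:2, ]))
  expect_identical(nrow(er2$index), 1L)

  # a 151-metabolite panel gives 11,325 = N(N-1)/2 ratio phenotypes
  big <- matrix(runif(151 * 4, 1, 10), 151, 4,
                dimnames = list(sprintf("m%03d", 1:151), paste0("i", 1:4)))
  er3 <- enumerateRatios(makePanel(big))
  expect_identical(nrow(er3$index), 151L * 150L %/% 2L)
  expect_identical(ncol(er3$values), 11325L)

  # log2 mode: swapping orientation negates the phenotype
  lg <- enumerateRatios(makePanel(conc), log2 = TRUE)
  expect_equal(lg$values[, "x/y"], -log2(conc["y", ] / conc["x", ]),
               ignore_attr = TRUE)
  expect_true(all(is.finite(lg$values)))

  # incomplete panels must be imputed first
  holey <- conc
  holey[1, 1] <- NA
  expect_error(enumerateRatios(makePanel(holey)), "impute")
})
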