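# The inverted regression scan: heteroplasmy log2-ratio response against
# metabolite-ratio (and single-metabolite) predictors with age, sex,
# coverage and sequencing-plate covariates.

#' Heteroplasmy log-ratio response
#'
#' \code{y = log2((B + pseudocount) / (A + pseudocount))} where A is the
#' reference-allele read count and B the count of the cohort-wide second
#' most frequent allele.  The pseudocount (default 2) keeps the logarithm
#' defined for individuals carrying only the reference allele; against a
#' typical depth of ~3500 reads it is negligible.
#'
#' @param A,B non-negative read counts (vectorised).
#' @param pseudocount added to both counts, default 2.
#' @return numeric vector of log2 ratios (finite whenever
#'   \code{pseudocount > 0}).
#' @export
heteroplasmyLogRatio <- function(A, B, pseudocount = 2) {
  if (any(A < 0) || any(B < 0)) stop("counts must be non-negative")
  base::log2((B + pseudocount) / (A + pseudocount))
}

#' Heteroplasmy phenotype for one position
#'
#' @param counts an \linkS4class{AlleleCounts}
#' @param alleles output of \code{\link{callAlleles}}
#' @param position 1-based rCRS coordinate present in \code{counts}.
#' @param pseudocount see \code{\link{heteroplasmyLogRatio}}.
#' @return data.frame with \code{individual_id}, \code{y} and
#'   \code{coverage} (A + B reads).
#' @export
heteroplasmyPhenotype <- function(counts, alleles, position, pseudocount = 2) {
  i <- match(as.integer(position),
             SummarizedExperiment::rowData(counts)$position)
  if (is.na(i)) stop("position ", position, " not present")
  ab <- .positionAB(counts, alleles, i)
  data.frame(
    individual_id = colnames(counts),
    y = heteroplasmyLogRatio(ab$A, ab$B, pseudocount),
    coverage = ab$A + ab$B,
    row.names = NULL
  )
}

.positionAB <- function(counts, alleles, i) {
  refb <- alleles$ref[i]
  altb <- alleles$alt[i]
  if (is.na(altb)) stop("no alternative allele defined at row ", i,
                        " (reference gap)")
  list(
    A = as.numeric(SummarizedExperiment::assay(counts, refb)[i, ]),
    B = as.numeric(SummarizedExperiment::assay(counts, altb)[i, ])
  )
}

# Covariate design shared by single fits and the scan:
# intercept, phenotype slot (filled later), age, sex, coverage, plate
# contrasts (first level reference).
.covariateMatrix <- function(covariates, coverage) {
  df <- data.frame(age = as.numeric(covariates$age),
                   sex = as.numeric(covariates$sex),
                   coverage = as.numeric(coverage),
                   batch = factor(covariates$batch))
  if (nlevels(df$batch) > 1L)
    model.matrix(~ age + sex + coverage + batch, df)
  else
    model.matrix(~ age + sex + coverage, df)
}

#' Fit the inverted regression for one (position, phenotype) pair
#'
#' Ordinary least squares of the heteroplasmy log2-ratio on the
#' metabolite predictor with age, sex, total coverage and sequencing
#' plate as covariates.  The Wald statistic \code{z = beta1 / SE(beta1)}
#' is referred to the standard normal (asymptotic normality), giving a
#' two-sided p-value.  Redundant plate contrasts are dropped; a constant
#' predictor is an error.
#'
#' @param y heteroplasmy log2-ratio response.
#' @param mr metabolite ratio (or single-metabolite concentration).
#' @param covariates data.frame with \code{age}, \code{sex}, \code{batch}.
#' @param coverage per-individual total reads A + B at the position.
#' @return one-row data.frame: \code{beta}, \code{se}, \code{z}, \code{p},
#'   \code{n}.
#' @export
fitInvertedModel <- function(y, mr, covariates, coverage) {
  ok <- complete.cases(y, mr, covariates$age, covariates$sex,
                       covariates$batch, coverage)
  y <- y[ok]
  mr <- mr[ok]
  coverage <- coverage[ok]
  covariates <- covariates[ok, , drop = FALSE]
  if (length(unique(mr)) < 2L) stop("constant predictor (MR)")
  Xc <- .covariateMatrix(covariates, coverage)
  X <- cbind(Xc[, 1L, drop = FALSE], MR = mr, Xc[, -1L, drop = FALSE])
  if (nrow(X) < ncol(X) + 1L)
    stop("not enough complete rows for the design")
  fit <- .olsWald(X, y)
  if (!"MR" %in% fit$kept) stop("predictor dropped as collinear")
  beta <- unname(fit$coef["MR"])
  se <- unname(fit$se["MR"])
  z <- beta / se
  data.frame(beta = beta, se = se, z = z,
             p = 2 * pnorm(-abs(z)), n = fit$n, row.names = NULL)
}

#' Scan every retained position against every phenotype
#'
#' For each position the covariate projection (intercept, age, sex,
#' coverage, plate) is computed once; the response and all phenotype
#' columns are residualised against it and the slope of each
#' residual-on-residual regression equals the full-model beta1
#' (Frisch-Waugh-Lovell), with the standard error using the full-model
#' residual degrees of freedom.  Phenotype columns with missing entries
#' fall back to a per-column complete-case fit.  Fits with a degenerate
#' (constant after residualisation) predictor are reported in the
#' \code{skipped} attribute, not silently dropped.
#'
#' @param counts QC'd \linkS4class{AlleleCounts}
#' @param alleles output of \code{\link{callAlleles}} aligned to
#'   \code{counts}.
#' @param phenotypes list(\code{values}, \code{index}) from
#'   \code{\link{makeScanPhenotypes}} (ratio and single-metabolite
#'   columns).
#' @param covariates data.frame with \code{age}, \code{sex}, \code{batch};
#'   defaults to \code{colData(counts)}.
#' @param pseudocount see \code{\link{heteroplasmyLogRatio}}.
#' @return data.frame with one row per (position, phenotype): columns
#'   \code{position}, \code{ref}, \code{alt}, \code{phenotype_id},
#'   \code{type}, \code{numerator}, \code{denominator}, \code{beta},
#'   \code{se}, \code{z}, \code{p}, \code{n}; attribute \code{skipped}
#'   records degenerate fits.
#' @export
runScan <- function(counts, alleles, phenotypes, covariates = NULL,
                    pseudocount = 2) {
  stopifnot(is(counts, "AlleleCounts"))
  if (is.null(covariates))
    covariates <- as.data.frame(SummarizedExperiment::colData(counts))
  ids <- colnames(counts)
  covariates <- covariates[ids, , drop = FALSE]
  V <- phenotypes$values
  if (!all(ids %in% rownames(V)))
    stop("phenotype values missing for some sequenced individuals")
  V <- V[ids, , drop = FALSE]
  index <- phenotypes$index
  stopifnot(identical(colnames(V), index$phenotype_id))
  m <- ncol(V)
  pos <- SummarizedExperiment::rowData(counts)$position

  completeCols <- !apply(is.na(V), 2L, any)
  results <- vector("list", length(pos))
  skipped <- list()

  for (r in seq_along(pos)) {
    ab <- .positionAB(counts, alleles, r)
    y <- heteroplasmyLogRatio(ab$A, ab$B, pseudocount)
    coverage <- ab$A + ab$B
    Xc <- .covariateMatrix(covariates, coverage)
    qrX <- qr(Xc)
    rk <- qrX$rank
    n <- length(y)
    df <- n - rk - 1L
    ry <- qr.resid(qrX, y)
    syy <- sum(ry^2)

    beta <- se <- rep(NA_real_, m)
    nUsed <- rep(n, m)
    if (any(completeCols)) {
      RP <- qr.resid(qrX, V[, completeCols, drop = FALSE])
      ss <- colSums(RP^2)
      xy <- colSums(RP * ry)
      ok <- ss > 1e-10 * n
      b <- xy / ss
      rss <- pmax(syy - b * xy, 0)
      s2 <- rss / df
      bse <- sqrt(s2 / ss)
      b[!ok] <- NA_real_
      bse[!ok] <- NA_real_
      beta[completeCols] <- b
      se[completeCols] <- bse
    }
    for (j in which(!completeCols)) {
      fit <- tryCatch(
        fitInvertedModel(y, V[, j], covariates, coverage),
        error = function(e) NULL)
      if (is.null(fit)) next
      beta[j] <- fit$beta
      se[j] <- fit$se
      nUsed[j] <- fit$n
    }
    bad <- which(is.na(beta))
    if (length(bad))
      skipped[[length(skipped) + 1L]] <- data.frame(
        position = pos[r], phenotype_id = index$phenotype_id[bad],
        reason = "degenerate predictor", row.names = NULL)

    z <- beta / se
    results[[r]] <- data.frame(
      position = pos[r], ref = alleles$ref[r], alt = alleles$alt[r],
      phenotype_id = index$phenotype_id, type = index$type,
      numerator = index$numerator, denominator = index$denominator,
      beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)), n = nUsed,
      row.names = NULL
    )
  }
  out <- as.data.frame(data.table::rbindlist(results))
  out <- out[!is.na(out$beta), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped))
    as.data.frame(data.table::rbindlist(skipped))
  else data.frame(position = integer(), phenotype_id = character(),
                  reason = character())
  out
}

#' Combine ratio and single-metabolite phenotypes for the scan
#'
#' Single metabolites are scanned alongside ratios both as phenotypes in
#' their own right and because the P-gain statistic needs the component
#' p-values of every ratio.
#'
#' @param panel completed \linkS4class{MetabolitePanel}.
#' @param log2Ratios log2-transform ratio phenotypes?
#' @param includeSingles also scan each single metabolite (required for
#'   P-gain)?
#' @return list(\code{values} individuals x phenotypes, \code{index}
#'   data.frame with \code{phenotype_id}, \code{type} ("ratio"/"single"),
#'   \code{numerator}, \code{denominator}).
#' @export
makeScanPhenotypes <- function(panel, log2Ratios = FALSE,
                               includeSingles = TRUE) {
  er <- enumerateRatios(panel, log2 = log2Ratios)
  index <- cbind(er$index[, "phenotype_id", drop = FALSE],
                 type = "ratio",
                 er$index[, c("numerator", "denominator")])
  values <- er$values
  if (includeSingles) {
    singles <- t(concentrations(panel))
    sIndex <- data.frame(phenotype_id = colnames(singles), type = "single",
                         numerator = colnames(singles),
                         denominator = NA_character_, row.names = NULL)
    values <- cbind(values, singles)
    index <- rbind(index, sIndex)
  }
  rownames(index) <- NULL
  list(values = values, index = index)
}

#' Genomic-control lambda
#'
#' Median of the chi-square(1 df) statistics implied by the p-values,
#' divided by the chi-square(1) median (0.4549364): 1 under a uniform
#' null, > 1 under test-statistic inflation.
#'
#' @param p p-values in (0, 1].
#' @return lambda (scalar).
#' @export
genomicLambda <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
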