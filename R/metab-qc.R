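# Metabolite-side QC (step 2): completeness filter, outlier masking,
# predictive-mean-matching chained imputation, ratio enumeration.

#' Drop metabolites with too many missing values
#'
#' A metabolite is retained only if at least \code{minFraction} of its
#' values are observed (non-missing); the comparison is strict below the
#' threshold, so a metabolite observed in exactly 80\% of individuals is
#' kept at the default.
#'
#' @param panel a \linkS4class{MetabolitePanel}
#' @param minFraction minimum observed fraction, default 0.8.
#' @return list(\code{panel} filtered, \code{report}
#'   \linkS4class{QCReport}).
#' @export
applyCompletenessFilter <- function(panel, minFraction = 0.8) {
  stopifnot(is(panel, "MetabolitePanel"))
  if (nrow(panel) == 0L || ncol(panel) == 0L) stop("empty panel")
  conc <- concentrations(panel)
  obsFrac <- rowMeans(!is.na(conc))
  drop <- rownames(panel)[obsFrac < minFraction]
  keep <- setdiff(rownames(panel), drop)
  report <- QCReport(unit = "metabolites", nInput = nrow(panel),
                     exclusions = list(incomplete = drop), retained = keep)
  list(panel = panel[keep, ], report = report)
}

#' Mask metabolite outliers
#'
#' Observed values lying strictly more than \code{kSd} standard
#' deviations from the per-metabolite mean (mean and SD computed on
#' observed values) are set to missing.  Metabolites with undefined or
#' zero SD mask nothing.
#'
#' @param panel a \linkS4class{MetabolitePanel}
#' @param kSd number of standard deviations, default 3.
#' @return list(\code{panel} with outliers masked, \code{masked}
#'   data.frame of metabolite/individual/value for every masked cell).
#' @export
maskOutliers <- function(panel, kSd = 3) {
  stopifnot(is(panel, "MetabolitePanel"))
  conc <- concentrations(panel)
  mu <- rowMeans(conc, na.rm = TRUE)
  sg <- apply(conc, 1, sd, na.rm = TRUE)
  z <- abs(conc - mu) / sg
  mask <- !is.na(conc) & !is.na(z) & sg > 0 & z > kSd
  cells <- which(mask, arr.ind = TRUE)
  masked <- data.frame(
    metabolite = rownames(conc)[cells[, 1L]],
    individual = colnames(conc)[cells[, 2L]],
    value = conc[cells],
    row.names = NULL
  )
  conc[mask] <- NA_real_
  SummarizedExperiment::assay(panel, "conc") <- conc
  list(panel = panel, masked = masked)
}

#' Impute missing metabolite values by chained predictive mean matching
#'
#' Chained equations: the imputer cycles over metabolites with missing
#' values; each is regressed (OLS) on all other metabolites using the
#' individuals where it is observed, with the other metabolites at their
#' current completed values.  For every missing entry the \code{nDonors}
#' observed values whose fitted means lie nearest the entry's fitted mean
#' form the donor pool and one donor value is copied at random.  Cycles
#' repeat \code{nIterations} times; one completed panel is returned and
#' every imputed value is an observed value of the same metabolite.
#' Missing values start at the per-metabolite observed mean before the
#' first cycle.
#'
#' @param panel a \linkS4class{MetabolitePanel}
#' @param nIterations chained-equation cycles, default 10.
#' @param nDonors donor pool size, default 5.
#' @param seed RNG seed for donor draws (required for determinism).
#' @return the completed \linkS4class{MetabolitePanel} (no missing
#'   entries).
#' @export
imputePMM <- function(panel, nIterations = 10, nDonors = 5, seed = 1L) {
  stopifnot(is(panel, "MetabolitePanel"))
  X <- t(concentrations(panel))  # individuals x metabolites
  missMask <- is.na(X)
  nobs <- colSums(!missMask)
  if (any(nobs < 2L))
    stop("metabolites with fewer than 2 observed values: ",
         paste(colnames(X)[nobs < 2L], collapse = ", "))
  incomplete <- which(colSums(missMask) > 0L)
  if (!length(incomplete)) return(panel)

  .withSeed(.stageSeed(seed, "impute"), {
    # deterministic start: observed mean
    for (j in incomplete)
      X[missMask[, j], j] <- mean(X[!missMask[, j], j])
    for (it in seq_len(nIterations)) {
      for (j in incomplete) {
        obs <- !missMask[, j]
        D <- cbind(1, X[, -j, drop = FALSE])
        fit <- lm.fit(D[obs, , drop = FALSE], X[obs, j])
        coefs <- fit$coefficients
        coefs[is.na(coefs)] <- 0  # collinear predictors drop out
        pred <- drop(D %*% coefs)
        predObs <- pred[obs]
        valObs <- X[obs, j]
        for (i in which(!obs)) {
          d <- abs(predObs - pred[i])
          pool <- order(d)[seq_len(min(nDonors, length(d)))]
          X[i, j] <- valObs[pool[sample.int(length(pool), 1L)]]
        }
      }
    }
    SummarizedExperiment::assay(panel, "conc") <- t(X)
    panel
  })
}

#' Enumerate all pairwise metabolite ratios
#'
#' For N metabolites, builds all N(N-1)/2 unordered pair phenotypes; the
#' numerator is the metabolite earlier in panel order.  With
#' \code{log2 = TRUE} the phenotype is log2(numerator/denominator), so
#' swapping a pair's orientation negates it.
#'
#' @param panel a completed \linkS4class{MetabolitePanel} (no missing
#'   values).
#' @param log2 log2-transform the ratios?
#' @return list(\code{index} data.frame with \code{phenotype_id},
#'   \code{numerator}, \code{denominator}; \code{values}
#'   individuals-by-ratios matrix).
#' @export
enumerateRatios <- function(panel, log2 = FALSE) {
  stopifnot(is(panel, "MetabolitePanel"))
  conc <- concentrations(panel)
  if (anyNA(conc))
    stop("panel has missing values; impute before enumerating ratios")
  N <- nrow(conc)
  if (N < 2L) stop("need at least two metabolites")
  pairs <- utils::combn(N, 2L)
  nm <- rownames(conc)
  num <- nm[pairs[1L, ]]
  den <- nm[pairs[2L, ]]
  V <- t(conc[pairs[1L, ], , drop = FALSE] / conc[pairs[2L, ], , drop = FALSE])
  if (log2) V <- base::log2(V)
  ids <- paste(num, den, sep = "/")
  colnames(V) <- ids
  list(
    index = data.frame(phenotype_id = ids, numerator = num,
                       denominator = den, row.names = NULL),
    values = V
  )
}
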