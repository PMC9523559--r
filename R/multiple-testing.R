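# Multiple-testing machinery: Li-Ji effective number of tests, the
# corrected threshold, the P-gain statistic, and the combined gate.

.liJiFromEigenvalues <- function(lambda, M, alpha) {
  lambda <- abs(lambda)
  meffVal <- sum((lambda >= 1) + (lambda - floor(lambda)))
  new("MeffResult", M = as.integer(M), eigenvalues = lambda,
      Meff = meffVal, alpha = alpha, threshold = alpha / meffVal)
}

#' Li-Ji effective number of independent tests
#'
#' Spectral decomposition of the trait correlation matrix; each
#' eigenvalue lambda contributes \code{1} if \code{|lambda| >= 1} plus
#' its fractional part, so M independent traits give Meff = M and M
#' perfectly correlated traits give Meff = 1.
#'
#' @param corMatrix symmetric correlation matrix with unit diagonal.
#' @param alpha nominal familywise level, default 0.05.
#' @return a \linkS4class{MeffResult}.
#' @export
liJiMeff <- function(corMatrix, alpha = 0.05) {
  if (!is.matrix(corMatrix) || nrow(corMatrix) != ncol(corMatrix))
    stop("corMatrix must be square")
  if (max(abs(corMatrix - t(corMatrix))) > 1e-8)
    stop("corMatrix must be symmetric")
  if (max(abs(diag(corMatrix) - 1)) > 1e-8)
    stop("corMatrix must have unit diagonal")
  ev <- eigen(corMatrix, symmetric = TRUE, only.values = TRUE)$values
  .liJiFromEigenvalues(ev, nrow(corMatrix), alpha)
}

#' Li-Ji Meff straight from a phenotype matrix
#'
#' For very large trait panels the eigenvalues of the correlation matrix
#' are obtained from the singular values of the standardised phenotype
#' matrix (rank at most n), which is exact and avoids materialising the
#' m-by-m correlation matrix; constant columns are excluded and
#' correlations use pairwise-complete standardisation only when the
#' matrix is complete (impute first otherwise).
#'
#' @param values individuals-by-traits matrix (complete).
#' @param alpha nominal familywise level.
#' @return a \linkS4class{MeffResult} (M = number of non-constant traits).
#' @export
meffFromPhenotypes <- function(values, alpha = 0.05) {
  if (anyNA(values))
    stop("phenotype matrix must be complete; run imputation first")
  sds <- apply(values, 2L, sd)
  keep <- which(sds > 0)
  Z <- scale(values[, keep, drop = FALSE])
  n <- nrow(Z)
  d <- svd(Z, nu = 0, nv = 0)$d
  ev <- d^2 / (n - 1)
  M <- length(keep)
  ev <- c(ev, rep(0, max(0L, M - length(ev))))
  .liJiFromEigenvalues(ev, M, alpha)
}

#' Meff-corrected significance threshold
#'
#' @param alpha nominal familywise level, default 0.05.
#' @param meff effective number of independent tests (scalar >= 1 or a
#'   \linkS4class{MeffResult}).
#' @return alpha / Meff.
#' @export
significanceThreshold <- function(alpha = 0.05, meff) {
  if (is(meff, "MeffResult")) meff <- meff(meff)
  if (meff < 1) stop("Meff must be >= 1")
  alpha / meff
}

#' P-gain of a metabolite ratio
#'
#' \code{p_gain = min(p_numerator, p_denominator) / p_ratio}: how much
#' the ratio's association p-value improves on the better of its two
#' component concentrations.  Values above 1 mean the ratio beats both
#' singles; the conservative critical value is the number of metabolites
#' in the panel (see \code{\link{pGainCritical}}).
#'
#' @param pNum,pDen,pRatio p-values in (0, 1] (vectorised).
#' @return numeric vector of P-gains.
#' @export
pGain <- function(pNum, pDen, pRatio) {
  ps <- c(pNum, pDen, pRatio)
  if (any(is.na(ps)) || any(ps <= 0 | ps > 1))
    stop("p-values must lie in (0, 1]")
  pmin(pNum, pDen) / pRatio
}

#' Bonferroni-type critical value for the P-gain
#'
#' @param nMetabolites number of metabolites in the tested panel.
#' @return the critical value (ratios must exceed it strictly).
#' @export
pGainCritical <- function(nMetabolites) {
  if (nMetabolites < 1) stop("need at least one metabolite")
  as.numeric(nMetabolites)
}

#' Attach P-gain to scan results
#'
#' For every ratio row, looks up the single-metabolite p-values of its
#' numerator and denominator at the same position and computes the
#' P-gain; single rows get \code{NA}.
#'
#' @param results scan results from \code{\link{runScan}} containing both
#'   ratio and single rows.
#' @return \code{results} with columns \code{p_num}, \code{p_den},
#'   \code{p_gain} added.
#' @export
computePGain <- function(results) {
  need <- c("position", "phenotype_id", "type", "numerator", "denominator",
            "p")
  stopifnot(all(need %in% names(results)))
  singles <- results[results$type == "single", ]
  key <- function(pos, met) paste(pos, met, sep = "\r")
  skey <- key(singles$position, singles$phenotype_id)
  ratio <- results$type == "ratio"
  pn <- singles$p[match(key(results$position, results$numerator), skey)]
  pd <- singles$p[match(key(results$position, results$denominator), skey)]
  results$p_num <- ifelse(ratio, pn, NA_real_)
  results$p_den <- ifelse(ratio, pd, NA_real_)
  results$p_gain <- ifelse(ratio & !is.na(pn) & !is.na(pd),
                           pmin(pn, pd) / results$p, NA_real_)
  results
}

#' Combined significance gate
#'
#' A ratio association is significant iff its p-value is strictly below
#' the Meff-corrected threshold AND its P-gain strictly exceeds the
#' critical value.  Both inequalities are strict; single-metabolite rows
#' are gated on the p-value threshold alone (their P-gain is undefined).
#'
#' @param results scan results carrying \code{p} and \code{p_gain}
#'   (see \code{\link{computePGain}}).
#' @param threshold Meff-corrected p-value threshold.
#' @param pGainCritical critical P-gain (number of metabolites).
#' @return \code{results} with a logical \code{significant} column.
#' @export
applySignificanceGate <- function(results, threshold, pGainCritical) {
  stopifnot(all(c("p", "p_gain", "type") %in% names(results)))
  isRatio <- results$type == "ratio"
  sig <- results$p < threshold
  sig[isRatio] <- sig[isRatio] &
    !is.na(results$p_gain[isRatio]) &
    results$p_gain[isRatio] > pGainCritical
  results$significant <- sig & !is.na(results$p)
  results
}
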