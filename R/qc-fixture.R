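# Exact-count QC fixture: a cohort whose flag counts equal the requested
# layout, with every position-level flag realised in the counts themselves.

# Fixed-site exclusions on the rCRS coordinate system.
.PRIMER_REGION <- c(16401L, 16449L)
.REFERENCE_GAP <- 3107L
.PHANTOM_SITES <- c(3166L, 3170L, 16390L)
.BLACKLIST_SITES <- c(301L, 302L, 310L, 316L, 16182L)

.fixedSites <- function(genomeLength) {
  s <- c(
    if (genomeLength >= .PRIMER_REGION[1])
      seq(.PRIMER_REGION[1], min(.PRIMER_REGION[2], genomeLength)),
    .REFERENCE_GAP[.REFERENCE_GAP <= genomeLength],
    .PHANTOM_SITES[.PHANTOM_SITES <= genomeLength],
    .BLACKLIST_SITES[.BLACKLIST_SITES <= genomeLength]
  )
  sort(unique(as.integer(s)))
}

#' Build an exact-count QC fixture cohort
#'
#' Constructs an \linkS4class{AlleleCounts} cohort whose QC accounting is
#' known by design: the requested numbers of contaminated, low-coverage
#' and diabetic individuals (pairwise disjoint groups) and of
#' low-coverage and homoplasmic positions, on top of the fixed-site
#' exclusions (primer region, reference gap, phantom mutations,
#' blacklist) present on a full-length genome.  Position flags are
#' realised in the counts: low-coverage positions have mean depth 900,
#' homoplasmic positions carry zero minor-allele reads everywhere, and
#' every retained position carries a minor-allele fraction of about 0.028
#' in one retained individual.  The reference is all \code{A} with an
#' \code{N} at the rCRS gap position when the genome covers it; minor
#' counts live on base \code{C} in sparse storage.
#'
#' @param spec a \linkS4class{QCFixtureSpec}
#' @return list with \code{counts} (\linkS4class{AlleleCounts}),
#'   \code{covariates} (its \code{colData} as a data.frame),
#'   \code{reference} (\link[Biostrings]{DNAString}) and \code{flags}
#'   (the ground-truth id/position sets).
#' @export
makeQCFixture <- function(spec) {
  stopifnot(is(spec, "QCFixtureSpec"))
  n <- spec@nTotal
  L <- spec@genomeLength
  ids <- sprintf("ind_%05d", seq_len(n))

  contaminated <- seq_len(spec@nContaminated)
  lowcov_ind <- seq_len(spec@nLowCoverageIndividuals) + spec@nContaminated
  diabetic <- seq_len(spec@nDiabetic) + spec@nContaminated +
    spec@nLowCoverageIndividuals

  fixed <- .fixedSites(L)
  eligible <- setdiff(seq_len(L), fixed)
  if (spec@nLowcovPositions + spec@nHomoplasmicPositions > length(eligible))
    stop("flagged positions exceed the non-fixed-site genome")
  lowcov_pos <- eligible[seq_len(spec@nLowcovPositions)]
  homo_pos <- eligible[seq_len(spec@nHomoplasmicPositions) +
                         spec@nLowcovPositions]
  het_pos <- setdiff(eligible, c(lowcov_pos, homo_pos))

  # reference-base (A) depth: 3500 everywhere, 900 at low-coverage
  # positions, 800 for low-coverage individuals
  A <- matrix(3500L, L, n)
  if (length(lowcov_pos)) A[lowcov_pos, ] <- 900L
  if (length(lowcov_ind)) A[, lowcov_ind] <- 800L

  # one retained carrier individual holds the minor allele at every
  # heteroplasmic position: 100 / (3500 + 100) ~ 0.028 >= 0.007
  flagged <- c(contaminated, lowcov_ind, diabetic)
  carrier <- max(setdiff(seq_len(n), flagged), 0L)
  if (carrier == 0L) carrier <- n  # fully flagged cohort: degenerate but valid
  Csp <- if (length(het_pos))
    Matrix::sparseMatrix(i = het_pos, j = rep(carrier, length(het_pos)),
                         x = rep(100, length(het_pos)), dims = c(L, n))
  else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(L, n))
  zero <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(L, n))

  covariates <- data.frame(
    age = rep(55L, n),
    sex = rep(c(0L, 1L), length.out = n),
    batch = factor(rep(1L, n)),
    contaminated = seq_len(n) %in% contaminated,
    diabetic = seq_len(n) %in% diabetic,
    row.names = ids
  )

  ref_chars <- rep("A", L)
  if (L >= .REFERENCE_GAP) ref_chars[.REFERENCE_GAP] <- "N"
  reference <- Biostrings::DNAString(paste(ref_chars, collapse = ""))

  dimnames(A) <- list(as.character(seq_len(L)), ids)
  dimnames(Csp) <- dimnames(zero) <- dimnames(A)
  counts <- AlleleCounts(A = A, C = Csp, G = zero, T = zero,
                         positions = seq_len(L), colData = covariates,
                         reference = reference)
  list(
    counts = counts,
    covariates = covariates,
    reference = reference,
    flags = list(
      contaminated = ids[contaminated],
      lowCoverageIndividuals = ids[lowcov_ind],
      diabetic = ids[diabetic],
      fixedSites = fixed,
      lowCoveragePositions = lowcov_pos,
      homoplasmicPositions = homo_pos,
      heteroplasmicPositions = het_pos
    )
  )
}
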