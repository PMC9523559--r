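# Sequencing-side QC (step 1): individual exclusions, cohort-wide
# reference/alternative allele definition, position filters.

# Total read depth per position x individual, summed over the four bases.
# Returns column sums / row sums without materialising the dense total.
.totalColSums <- function(ac) {
  Reduce(`+`, lapply(.BASES, function(b)
    Matrix::colSums(SummarizedExperiment::assay(ac, b))))
}

.totalRowSums <- function(ac, cols = NULL) {
  Reduce(`+`, lapply(.BASES, function(b) {
    m <- SummarizedExperiment::assay(ac, b)
    if (!is.null(cols)) m <- m[, cols, drop = FALSE]
    Matrix::rowSums(m)
  }))
}

#' Exclude individuals (QC step 1, individual side)
#'
#' Removes, in order and with disjoint attribution: individuals flagged as
#' DNA-contaminated, individuals whose mean total coverage across all
#' positions is strictly below \code{minMeanCoverage}, and individuals
#' flagged as diabetic (excluded to avoid confounding with
#' insulin-dependent disease).
#'
#' @param counts an \linkS4class{AlleleCounts}
#' @param covariates data.frame with logical \code{contaminated} and
#'   \code{diabetic} columns, rownames covering every individual in
#'   \code{counts}; defaults to \code{colData(counts)}.
#' @param minMeanCoverage exclusion threshold on mean depth (strict \code{<}).
#' @return list(\code{counts} filtered, \code{report}
#'   \linkS4class{QCReport}).
#' @export
excludeIndividuals <- function(counts, covariates = NULL,
                               minMeanCoverage = 1000) {
  stopifnot(is(counts, "AlleleCounts"))
  if (is.null(covariates))
    covariates <- as.data.frame(SummarizedExperiment::colData(counts))
  ids <- colnames(counts)
  missing <- setdiff(ids, rownames(covariates))
  if (length(missing))
    stop("individuals missing from covariates: ",
         paste(utils::head(missing, 5), collapse = ", "))
  covariates <- covariates[ids, , drop = FALSE]
  if (!all(c("contaminated", "diabetic") %in% names(covariates)))
    stop("covariates must contain 'contaminated' and 'diabetic' flags")

  meanCov <- .totalColSums(counts) / nrow(counts)
  contaminated <- ids[covariates$contaminated]
  rest <- setdiff(ids, contaminated)
  lowcov <- rest[meanCov[match(rest, ids)] < minMeanCoverage]
  rest <- setdiff(rest, lowcov)
  diabetic <- rest[covariates[rest, "diabetic"]]
  retained <- setdiff(rest, diabetic)

  report <- QCReport(
    unit = "individuals", nInput = length(ids),
    exclusions = list(contamination = contaminated,
                      low_mean_coverage = lowcov,
                      diabetes = diabetic),
    retained = retained
  )
  list(counts = counts[, retained], report = report)
}

#' Define per-position reference and alternative alleles
#'
#' The reference base comes from the supplied genome; the alternative is
#' the non-reference base with the largest read count summed over the
#' cohort, ties broken alphabetically.  Positions whose reference base is
#' not one of A/C/G/T (e.g. the rCRS spacer \code{N}) are flagged as
#' reference gaps (\code{alt = NA}).
#'
#' @param counts an \linkS4class{AlleleCounts} (post individual QC)
#' @param reference \link[Biostrings]{DNAString}, \code{DNAStringSet} of
#'   length one, or path to a FASTA file; its length must reach the
#'   largest position in \code{counts}.
#' @return \link[S4Vectors]{DataFrame} with columns \code{position},
#'   \code{ref}, \code{alt}, \code{refGap}.
#' @export
callAlleles <- function(counts, reference) {
  stopifnot(is(counts, "AlleleCounts"))
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (is(reference, "DNAStringSet")) reference <- reference[[1L]]
  pos <- SummarizedExperiment::rowData(counts)$position
  if (max(pos) > length(reference))
    stop("reference shorter than the largest position (",
         length(reference), " < ", max(pos), ")")
  refBase <- strsplit(as.character(reference), "")[[1L]][pos]
  gap <- !refBase %in% .BASES

  totals <- vapply(.BASES, function(b)
    Matrix::rowSums(SummarizedExperiment::assay(counts, b)),
    numeric(nrow(counts)))
  if (is.null(dim(totals))) totals <- matrix(totals, nrow = 1L,
                                             dimnames = list(NULL, .BASES))
  # mask the reference base, then take the first (alphabetical) maximum
  masked <- totals
  ridx <- match(refBase, .BASES)
  ok <- which(!gap)
  masked[cbind(ok, ridx[ok])] <- -Inf
  alt <- .BASES[max.col(masked, ties.method = "first")]
  alt[gap] <- NA_character_

  S4Vectors::DataFrame(position = as.integer(pos), ref = refBase,
                       alt = alt, refGap = gap,
                       row.names = as.character(pos))
}

#' Filter positions (QC step 1, position side)
#'
#' Removes positions in sequential rule order with disjoint attribution:
#' the PCR primer region (inclusive coordinate range), reference-gap
#' positions (reference base outside A/C/G/T), known phantom mutations,
#' blacklisted sites, positions with cohort mean coverage strictly below
#' \code{minMeanCoverage}, and homoplasmic positions, defined as a
#' maximum minor-allele fraction \code{B/(A+B)} over individuals strictly
#' below \code{homoplasmyThreshold}.  Run after individual exclusions so
#' that position statistics reflect the retained cohort.
#'
#' @param counts an \linkS4class{AlleleCounts} (post individual QC)
#' @param alleles output of \code{\link{callAlleles}} on the same object
#' @param minMeanCoverage depth threshold (strict \code{<}).
#' @param homoplasmyThreshold minor-allele fraction threshold (strict
#'   \code{<}).
#' @param primerRegion inclusive 1-based range to drop; \code{NULL} skips.
#' @param phantom,blacklist fixed position sets to drop.
#' @return list(\code{counts} filtered, \code{alleles} subset,
#'   \code{report} \linkS4class{QCReport}).
#' @export
filterPositions <- function(counts, alleles,
                            minMeanCoverage = 1000,
                            homoplasmyThreshold = 0.007,
                            primerRegion = .PRIMER_REGION,
                            phantom = .PHANTOM_SITES,
                            blacklist = .BLACKLIST_SITES) {
  stopifnot(is(counts, "AlleleCounts"))
  if (ncol(counts) == 0L) stop("empty cohort")
  pos <- SummarizedExperiment::rowData(counts)$position
  if (!identical(as.integer(alleles$position), as.integer(pos)))
    stop("alleles and counts describe different positions")

  remaining <- pos
  take <- function(hit) {
    hit <- intersect(hit, remaining)
    remaining <<- setdiff(remaining, hit)
    hit
  }

  primer <- if (is.null(primerRegion)) integer(0) else
    take(pos[pos >= primerRegion[1] & pos <= primerRegion[2]])
  gaps <- take(alleles$position[alleles$refGap])
  phant <- take(intersect(phantom, pos))
  black <- take(intersect(blacklist, pos))

  idx <- match(remaining, pos)
  meanCov <- .totalRowSums(counts)[idx] / ncol(counts)
  lowcov <- take(remaining[meanCov < minMeanCoverage])

  idx <- match(remaining, pos)
  sub <- counts[idx, ]
  suba <- alleles[idx, ]
  Amat <- .pickBaseMatrix(sub, suba$ref)
  Bmat <- .pickBaseMatrix(sub, suba$alt)
  maxFrac <- .rowMaxMinorFrac(Amat, Bmat)
  homo <- take(remaining[maxFrac < homoplasmyThreshold])

  report <- QCReport(
    unit = "positions", nInput = length(pos),
    exclusions = list(primer_region = primer,
                      reference_gap = gaps,
                      phantom = phant,
                      blacklist = black,
                      low_mean_coverage = lowcov,
                      homoplasmic = homo),
    retained = remaining
  )
  keep <- match(remaining, pos)
  list(counts = counts[keep, ], alleles = alleles[keep, ], report = report)
}

# Assemble the count matrix of a per-position base vector (ref or alt).
# Rows are gathered per base and re-ordered; all-sparse inputs stay
# sparse so whole-genome minor-count matrices never densify here.
.pickBaseMatrix <- function(counts, base) {
  n <- ncol(counts)
  P <- nrow(counts)
  blocks <- list()
  idx_all <- integer(0)
  for (b in .BASES) {
    rows <- which(!is.na(base) & base == b)
    if (!length(rows)) next
    blocks[[length(blocks) + 1L]] <-
      SummarizedExperiment::assay(counts, b)[rows, , drop = FALSE]
    idx_all <- c(idx_all, rows)
  }
  if (!length(blocks)) return(matrix(0, P, n))
  sparse <- all(vapply(blocks, function(m) is(m, "sparseMatrix"), logical(1)))
  missing <- setdiff(seq_len(P), idx_all)
  if (length(missing)) {
    blocks[[length(blocks) + 1L]] <- if (sparse)
      Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                           dims = c(length(missing), n))
    else matrix(0, length(missing), n)
    idx_all <- c(idx_all, missing)
  }
  if (length(blocks) == 1L && identical(idx_all, seq_len(P)))
    return(blocks[[1L]])
  if (!sparse) blocks <- lapply(blocks, as.matrix)
  combined <- do.call(rbind, blocks)
  combined[match(seq_len(P), idx_all), , drop = FALSE]
}
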