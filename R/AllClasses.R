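#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Per-position allele read counts
#'
#' A \linkS4class{SummarizedExperiment} holding one assay per base
#' (\code{A}, \code{C}, \code{G}, \code{T}); rows are mitochondrial genome
#' positions (1-based rCRS coordinates in \code{rowData()$position}),
#' columns are individuals.  Assays may be dense base matrices or
#' \pkg{Matrix} sparse matrices; homoplasmic cohorts are mostly zeros on
#' the non-reference bases, which sparse storage exploits.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("AlleleCounts", contains = "SummarizedExperiment")

setValidity("AlleleCounts", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!setequal(an, c("A", "C", "G", "T")))
    return("assays must be named A, C, G, T")
  pos <- SummarizedExperiment::rowData(object)$position
  if (is.null(pos))
    return("rowData must contain a 'position' column")
  if (any(pos < 1L) || any(pos > 16569L))
    return("positions must lie within [1, 16569] (rCRS)")
  if (anyDuplicated(pos))
    return("duplicated positions")
  for (b in an) {
    if (.assayMin(SummarizedExperiment::assay(object, b)) < 0)
      return(sprintf("negative counts in assay %s", b))
  }
  TRUE
})

#' Construct an AlleleCounts object
#'
#' @param A,C,G,T position-by-individual count matrices (dense or sparse),
#'   identical dimensions.
#' @param positions 1-based rCRS coordinates, one per row.
#' @param colData per-individual covariates (\code{data.frame} or
#'   \code{DataFrame}); rownames are individual identifiers.
#' @param reference optional \link[Biostrings]{DNAString} reference genome,
#'   stored in \code{metadata()$reference}.
#' @return an \linkS4class{AlleleCounts} object.
#' @export
AlleleCounts <- function(A, C, G, T, positions = seq_len(nrow(A)),
                         colData = NULL, reference = NULL) {
  positions <- as.integer(positions)
  rd <- S4Vectors::DataFrame(position = positions)
  rownames(rd) <- as.character(positions)
  args <- list(
    assays = S4Vectors::SimpleList(A = A, C = C, G = G, T = T),
    rowData = rd
  )
  if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  rownames(se) <- as.character(positions)
  obj <- new("AlleleCounts", se)
  if (!is.null(reference)) S4Vectors::metadata(obj)$reference <- reference
  validObject(obj)
  obj
}

#' Metabolite concentration panel
#'
#' A \linkS4class{SummarizedExperiment}: rows are metabolites (with a
#' \code{class} column in \code{rowData()}), columns individuals.  The
#' \code{conc} assay holds positive concentrations with \code{NA} marking
#' missing measurements.  Simulated panels additionally carry a complete,
#' pre-outlier \code{truth} assay.
#'
#' @export
setClass("MetabolitePanel", contains = "SummarizedExperiment")

setValidity("MetabolitePanel", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!"conc" %in% an)
    return("a 'conc' assay is required")
  conc <- SummarizedExperiment::assay(object, "conc")
  if (any(conc[!is.na(conc)] <= 0))
    return("observed concentrations must be strictly positive")
  if (is.null(SummarizedExperiment::rowData(object)$class))
    return("rowData must contain a 'class' column")
  TRUE
})

#' Construct a MetabolitePanel
#'
#' @param conc metabolite-by-individual concentration matrix; \code{NA}
#'   marks missing values.
#' @param class metabolite class label per row (acylcarnitine, amino acid,
#'   glycerophospholipid, sphingolipid, hexose, ...).
#' @param truth optional complete concentration matrix (simulation ground
#'   truth), same dimensions as \code{conc}.
#' @return a \linkS4class{MetabolitePanel}.
#' @export
MetabolitePanel <- function(conc, class = rep("unknown", nrow(conc)),
                            truth = NULL) {
  assays <- S4Vectors::SimpleList(conc = conc)
  if (!is.null(truth)) assays$truth <- truth
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(class = class, row.names = rownames(conc))
  )
  obj <- new("MetabolitePanel", se)
  validObject(obj)
  obj
}

#' QC exclusion ledger
#'
#' Records, for one unit type (individuals, positions or metabolites), the
#' identifiers excluded under each named rule and the identifiers retained.
#' Validity enforces conservation: per-rule exclusions plus retained equal
#' the input total, with rules attributed disjointly in application order.
#'
#' @slot unit what is being filtered ("individuals", "positions", ...).
#' @slot nInput number of units entering the filter.
#' @slot exclusions named list, one character vector of identifiers per rule.
#' @slot retained character vector of retained identifiers.
#' @export
setClass("QCReport", representation(
  unit = "character",
  nInput = "integer",
  exclusions = "list",
  retained = "character"
))

setValidity("QCReport", function(object) {
  ids <- unlist(object@exclusions, use.names = FALSE)
  if (anyDuplicated(c(ids, object@retained)))
    return("exclusion rules must be disjoint and disjoint from retained")
  if (length(ids) + length(object@retained) != object@nInput)
    return("exclusions + retained must equal the input total")
  TRUE
})

QCReport <- function(unit, nInput, exclusions, retained) {
  new("QCReport", unit = unit, nInput = as.integer(nInput),
      exclusions = lapply(exclusions, as.character),
      retained = as.character(retained))
}

#' @describeIn QCReport-class pretty ledger
#' @param object a QCReport
#' @export
setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport for %s: %d in, %d excluded, %d retained\n",
              object@unit, object@nInput,
              object@nInput - length(object@retained),
              length(object@retained)))
  cnt <- vapply(object@exclusions, length, integer(1))
  for (rule in names(cnt))
    cat(sprintf("  %-22s %6d\n", rule, cnt[[rule]]))
})

#' Synthetic cohort configuration
#'
#' Holds every knob of the synthetic-cohort generator.  Defaults mirror
#' the analysed study: 1163 individuals, a 151-metabolite serum panel and
#' mitochondrial sequencing at 3500-fold mean coverage.
#'
#' @slot nIndividuals cohort size.
#' @slot nMetabolites panel size.
#' @slot nPositions number of simulated mtDNA positions.
#' @slot meanCoverage Poisson mean read depth per position (reads).
#' @slot blockCorrelation within-class correlation of log concentrations,
#'   in [0, 1).
#' @slot missingRate fraction of panel cells missing completely at random.
#' @slot outlierRate fraction of panel cells replaced by high outliers
#'   (> 3 SD above the mean).
#' @slot causalEffects data.frame with columns \code{position},
#'   \code{numerator}, \code{denominator}, \code{beta}: positions whose
#'   log2 heteroplasmy odds depend linearly (slope \code{beta}) on the
#'   centred metabolite ratio.
#' @slot baselineLogit cohort-mean log2-odds of the minor allele fraction.
#' @slot noiseSd SD of individual-level noise on the log2-odds scale.
#' @slot batchCount number of sequencing plates.
#' @slot seed master seed; all stage streams derive from it.
#' @export
setClass("SimulationConfig", representation(
  nIndividuals = "integer",
  nMetabolites = "integer",
  nPositions = "integer",
  meanCoverage = "numeric",
  blockCorrelation = "numeric",
  missingRate = "numeric",
  outlierRate = "numeric",
  causalEffects = "data.frame",
  baselineLogit = "numeric",
  noiseSd = "numeric",
  batchCount = "integer",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  if (object@nIndividuals < 1L || object@nMetabolites < 1L ||
      object@nPositions < 1L)
    return("dimensions must be positive")
  if (object@meanCoverage <= 0)
    return("meanCoverage must be > 0")
  rates <- c(object@missingRate, object@outlierRate)
  if (any(rates < 0) || any(rates > 1))
    return("rates must lie in [0, 1]")
  if (object@blockCorrelation < 0 || object@blockCorrelation >= 1)
    return("blockCorrelation must lie in [0, 1)")
  ce <- object@causalEffects
  if (nrow(ce)) {
    need <- c("position", "numerator", "denominator", "beta")
    if (!all(need %in% names(ce)))
      return("causalEffects needs columns position, numerator, denominator, beta")
    if (any(ce$position < 1L) || any(ce$position > object@nPositions))
      return("causal positions must lie within [1, nPositions]")
  }
  if (object@batchCount < 1L) return("batchCount must be >= 1")
  TRUE
})

#' @rdname SimulationConfig-class
#' @param nIndividuals,nMetabolites,nPositions,meanCoverage cohort dimensions
#'   and mean read depth.
#' @param blockCorrelation,missingRate,outlierRate panel structure knobs.
#' @param causalEffects data.frame of planted effects (see slots).
#' @param baselineLogit,noiseSd,batchCount,seed generative parameters.
#' @return a validated \code{SimulationConfig}.
#' @export
SimulationConfig <- function(nIndividuals = 1163L, nMetabolites = 151L,
                             nPositions = 100L, meanCoverage = 3500,
                             blockCorrelation = 0.5, missingRate = 0.02,
                             outlierRate = 0.005,
                             causalEffects = data.frame(
                               position = integer(), numerator = character(),
                               denominator = character(), beta = numeric()),
                             baselineLogit = -4.5, noiseSd = 1,
                             batchCount = 8L, seed = 1L) {
  obj <- new("SimulationConfig",
             nIndividuals = as.integer(nIndividuals),
             nMetabolites = as.integer(nMetabolites),
             nPositions = as.integer(nPositions),
             meanCoverage = as.numeric(meanCoverage),
             blockCorrelation = as.numeric(blockCorrelation),
             missingRate = as.numeric(missingRate),
             outlierRate = as.numeric(outlierRate),
             causalEffects = as.data.frame(causalEffects),
             baselineLogit = as.numeric(baselineLogit),
             noiseSd = as.numeric(noiseSd),
             batchCount = as.integer(batchCount),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d individuals x %d metabolites x %d positions\n",
    object@nIndividuals, object@nMetabolites, object@nPositions))
  cat(sprintf("  coverage %.0f, block rho %.2f, missing %.3f, outlier %.3f\n",
              object@meanCoverage, object@blockCorrelation,
              object@missingRate, object@outlierRate))
  cat(sprintf("  baseline log2-odds %.2f, noise sd %.2f, %d batches, seed %d\n",
              object@baselineLogit, object@noiseSd, object@batchCount,
              object@seed))
  if (nrow(object@causalEffects))
    cat(sprintf("  %d causal (position, ratio) effects\n",
                nrow(object@causalEffects)))
})

#' QC fixture layout
#'
#' Exact counts for an accounting fixture: how many individuals carry each
#' exclusion flag and how many positions are low-coverage or homoplasmic.
#' Flag groups are realised pairwise disjoint; position flags are realised
#' in the count data itself, not as annotations.
#'
#' @slot nTotal,nContaminated,nLowCoverageIndividuals,nDiabetic individual
#'   counts.
#' @slot nLowcovPositions,nHomoplasmicPositions,genomeLength position counts
#'   (genome defaults to the 16,569 bp rCRS).
#' @export
setClass("QCFixtureSpec", representation(
  nTotal = "integer",
  nContaminated = "integer",
  nLowCoverageIndividuals = "integer",
  nDiabetic = "integer",
  nLowcovPositions = "integer",
  nHomoplasmicPositions = "integer",
  genomeLength = "integer"
))

setValidity("QCFixtureSpec", function(object) {
  flags <- c(object@nContaminated, object@nLowCoverageIndividuals,
             object@nDiabetic)
  if (any(flags < 0) || object@nTotal < 1L)
    return("counts must be non-negative, nTotal positive")
  if (sum(flags) > object@nTotal)
    return("flagged individuals exceed the cohort")
  if (object@nLowcovPositions + object@nHomoplasmicPositions >
      object@genomeLength)
    return("flagged positions exceed the genome")
  TRUE
})

#' @rdname QCFixtureSpec-class
#' @param nTotal,nContaminated,nLowCoverageIndividuals,nDiabetic individual
#'   counts (flag groups realised disjointly).
#' @param nLowcovPositions,nHomoplasmicPositions,genomeLength position counts.
#' @return a validated \code{QCFixtureSpec}.
#' @export
QCFixtureSpec <- function(nTotal, nContaminated = 0L,
                          nLowCoverageIndividuals = 0L, nDiabetic = 0L,
                          nLowcovPositions = 0L, nHomoplasmicPositions = 0L,
                          genomeLength = 16569L) {
  obj <- new("QCFixtureSpec",
             nTotal = as.integer(nTotal),
             nContaminated = as.integer(nContaminated),
             nLowCoverageIndividuals = as.integer(nLowCoverageIndividuals),
             nDiabetic = as.integer(nDiabetic),
             nLowcovPositions = as.integer(nLowcovPositions),
             nHomoplasmicPositions = as.integer(nHomoplasmicPositions),
             genomeLength = as.integer(genomeLength))
  validObject(obj)
  obj
}

#' Effective number of independent tests
#'
#' Result of the Li-Ji spectral decomposition: the eigenvalue spectrum of
#' the trait correlation matrix, the effective test count and the corrected
#' significance threshold alpha / Meff.
#'
#' @slot M nominal number of traits.
#' @slot eigenvalues spectrum of their correlation matrix.
#' @slot Meff effective number of independent tests (1 <= Meff <= M).
#' @slot alpha nominal familywise level.
#' @slot threshold alpha / Meff.
#' @export
setClass("MeffResult", representation(
  M = "integer",
  eigenvalues = "numeric",
  Meff = "numeric",
  alpha = "numeric",
  threshold = "numeric"
))

setValidity("MeffResult", function(object) {
  if (object@Meff < 1 - 1e-8 || object@Meff > object@M + 1e-8)
    return("Meff must lie in [1, M]")
  if (object@threshold > object@alpha + 1e-12)
    return("threshold must not exceed alpha")
  TRUE
})

setMethod("show", "MeffResult", function(object) {
  cat(sprintf("MeffResult: M = %d traits, Meff = %.2f\n",
              object@M, object@Meff))
  cat(sprintf("  alpha = %g  ->  threshold = %g\n",
              object@alpha, object@threshold))
})
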