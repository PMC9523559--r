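# Orchestration: QC step 1 -> QC step 2 -> scan -> multiple-testing gate,
# with TSV reports and optional static plots.

#' Pipeline configuration
#'
#' Bundles input locations (file paths or in-memory objects) with every
#' analysis threshold.  Threshold defaults are the study values: minimum
#' mean coverage 1000, homoplasmy call at minor fraction 0.007,
#' metabolite completeness 0.8, outlier mask at 3 SD, familywise alpha
#' 0.05, P-gain critical value equal to the metabolite count.
#'
#' @param counts \linkS4class{AlleleCounts} or counts TSV path.
#' @param panel \linkS4class{MetabolitePanel} or metabolite CSV path.
#' @param covariates data.frame or covariate CSV path.
#' @param reference \link[Biostrings]{DNAString} or FASTA path.
#' @param outDir output directory for reports.
#' @param minMeanCoverage,homoplasmyThreshold,completenessFraction,outlierSd,alpha
#'   analysis thresholds.
#' @param pGainCritical critical P-gain; \code{NULL} uses the number of
#'   metabolites retained after QC.
#' @param log2Ratios scan log2-transformed ratios instead of raw ratios.
#' @param imputeIterations,imputeDonors chained-PMM settings.
#' @param meffScope trait set entering the Meff correlation:
#'   \code{"ratios"} (default) or \code{"all"} (ratios + singles).
#' @param makePlots write Manhattan / QQ PNGs.
#' @param seed master seed (imputation donor draws).
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(counts, panel, covariates = NULL, reference = NULL,
                      outDir = NULL,
                      minMeanCoverage = 1000, homoplasmyThreshold = 0.007,
                      completenessFraction = 0.8, outlierSd = 3,
                      alpha = 0.05, pGainCritical = NULL,
                      log2Ratios = FALSE,
                      imputeIterations = 10, imputeDonors = 5,
                      meffScope = c("ratios", "all"),
                      makePlots = FALSE, seed = 1L) {
  structure(list(
    counts = counts, panel = panel, covariates = covariates,
    reference = reference, outDir = outDir,
    minMeanCoverage = minMeanCoverage,
    homoplasmyThreshold = homoplasmyThreshold,
    completenessFraction = completenessFraction,
    outlierSd = outlierSd, alpha = alpha, pGainCritical = pGainCritical,
    log2Ratios = log2Ratios,
    imputeIterations = imputeIterations, imputeDonors = imputeDonors,
    meffScope = match.arg(meffScope), makePlots = makePlots,
    seed = as.integer(seed)
  ), class = "RunConfig")
}

.resolveInputs <- function(config) {
  counts <- config$counts
  if (is.character(counts))
    counts <- readAlleleCounts(counts)
  panel <- config$panel
  if (is.character(panel)) panel <- readMetabolitePanel(panel)
  covariates <- config$covariates
  if (is.character(covariates)) covariates <- readCovariates(covariates)
  if (is.null(covariates))
    covariates <- as.data.frame(SummarizedExperiment::colData(counts))
  reference <- config$reference
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)[[1L]]
  if (is.null(reference))
    reference <- S4Vectors::metadata(counts)$reference
  if (is.null(reference)) stop("no reference sequence provided")
  list(counts = counts, panel = panel, covariates = covariates,
       reference = reference)
}

#' Run the full inverted-scan pipeline
#'
#' Executes sequencing QC (individual and position filters), metabolite
#' QC (completeness, outlier masking, chained-PMM imputation), the
#' association scan over all pairwise ratios and singles, P-gain, the
#' Li-Ji Meff threshold and the combined significance gate; computes
#' genomic-control lambda per phenotype.  When \code{outDir} is set,
#' writes \code{qc_individuals.tsv}, \code{qc_positions.tsv},
#' \code{qc_metabolites.tsv}, \code{results.tsv} (sorted by p),
#' \code{significant.tsv} (annotated, Table-1 style), \code{meff.tsv},
#' \code{lambda.tsv}, \code{run_info.yaml} and optional plots.
#'
#' @param config a \code{RunConfig} from \code{\link{runConfig}}.
#' @return (invisibly) a list bundle: filtered objects, QC reports, the
#'   result table with gate flags, the \linkS4class{MeffResult}, lambda
#'   summary and the significant-hit table.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  inp <- .resolveInputs(config)

  # --- QC step 1: sequencing side
  step1i <- excludeIndividuals(inp$counts, inp$covariates,
                               minMeanCoverage = config$minMeanCoverage)
  alleles <- callAlleles(step1i$counts, inp$reference)
  step1p <- filterPositions(step1i$counts, alleles,
                            minMeanCoverage = config$minMeanCoverage,
                            homoplasmyThreshold = config$homoplasmyThreshold)
  counts <- step1p$counts
  alleles <- step1p$alleles

  # analysis set: individuals with both mtDNA and metabolite data
  common <- intersect(colnames(counts), colnames(inp$panel))
  counts <- counts[, common]
  panel <- inp$panel[, common]
  covariates <- inp$covariates[common, , drop = FALSE]

  # --- QC step 2: metabolite side
  step2 <- applyCompletenessFilter(panel, config$completenessFraction)
  masked <- maskOutliers(step2$panel, config$outlierSd)
  panel <- imputePMM(masked$panel, nIterations = config$imputeIterations,
                     nDonors = config$imputeDonors, seed = config$seed)

  # --- association scan
  phenotypes <- makeScanPhenotypes(panel, log2Ratios = config$log2Ratios)
  results <- runScan(counts, alleles, phenotypes, covariates)
  results <- computePGain(results)

  # --- multiple testing
  ratioCols <- phenotypes$index$type == "ratio"
  meffValues <- if (config$meffScope == "ratios")
    phenotypes$values[, ratioCols, drop = FALSE]
  else phenotypes$values
  meffRes <- meffFromPhenotypes(meffValues, alpha = config$alpha)
  threshold <- meffThreshold(meffRes)
  critical <- if (is.null(config$pGainCritical))
    pGainCritical(nrow(panel))
  else config$pGainCritical
  results <- applySignificanceGate(results, threshold, critical)
  results <- results[order(results$p), , drop = FALSE]
  rownames(results) <- NULL

  # genomic-control lambda per phenotype across positions
  lam <- vapply(split(results$p, results$phenotype_id), genomicLambda,
                numeric(1))
  lambdaSummary <- data.frame(phenotype_id = names(lam), lambda = unname(lam),
                              row.names = NULL)

  ann <- annotatePosition(results$position)
  results$gene <- ann$gene
  sig <- results[results$significant & results$type == "ratio", , drop = FALSE]
  sigTable <- data.frame(
    gene = sig$gene, position = sig$position,
    alleles = paste(sig$ref, sig$alt, sep = ">"),
    metabolite_ratio = sig$phenotype_id,
    beta = sig$beta, p = sig$p, p_gain = sig$p_gain,
    row.names = NULL
  )

  bundle <- list(
    counts = counts, panel = panel, covariates = covariates,
    alleles = alleles,
    individualReport = step1i$report, positionReport = step1p$report,
    metaboliteReport = step2$report, maskedOutliers = masked$masked,
    results = results, meff = meffRes, threshold = threshold,
    pGainCritical = critical, lambda = lambdaSummary,
    significant = sigTable
  )

  if (!is.null(config$outDir)) .writeReports(bundle, config)
  invisible(bundle)
}

.writeReports <- function(bundle, config) {
  dir <- config$outDir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    data.table::fwrite(df, file.path(dir, name), sep = "\t")
  w(qcLedger(bundle$individualReport), "qc_individuals.tsv")
  w(qcLedger(bundle$positionReport), "qc_positions.tsv")
  w(qcLedger(bundle$metaboliteReport), "qc_metabolites.tsv")
  res <- bundle$results
  res <- res[, c("position", "ref", "alt", "gene", "phenotype_id", "type",
                 "numerator", "denominator", "beta", "se", "z", "p",
                 "p_gain", "significant", "n")]
  w(res, "results.tsv")
  w(bundle$significant, "significant.tsv")
  w(data.frame(M = bundle$meff@M, Meff = meff(bundle$meff),
               alpha = bundle$meff@alpha, threshold = bundle$threshold,
               p_gain_critical = bundle$pGainCritical),
    "meff.tsv")
  w(bundle$lambda, "lambda.tsv")
  yaml::write_yaml(list(
    seed = config$seed,
    thresholds = list(
      min_mean_coverage = config$minMeanCoverage,
      homoplasmy = config$homoplasmyThreshold,
      completeness = config$completenessFraction,
      outlier_sd = config$outlierSd,
      alpha = config$alpha,
      p_gain_critical = bundle$pGainCritical
    ),
    log2_ratios = config$log2Ratios,
    meff_scope = config$meffScope,
    package_version = as.character(utils::packageVersion("mtMetaboScan"))
  ), file.path(dir, "run_info.yaml"))
  if (isTRUE(config$makePlots)) {
    grDevices::png(file.path(dir, "manhattan.png"), width = 1200,
                   height = 500)
    plotManhattan(bundle$results)
    grDevices::dev.off()
    grDevices::png(file.path(dir, "qq.png"), width = 600, height = 600)
    plotQQ(bundle$results$p[bundle$results$type == "ratio"])
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Manhattan-style plot of scan p-values
#'
#' Best (smallest) p per position, as -log10(p) against rCRS coordinate.
#'
#' @param results scan results with \code{position} and \code{p}.
#' @param threshold optional significance threshold drawn as a line.
#' @export
plotManhattan <- function(results, threshold = NULL) {
  best <- tapply(results$p, results$position, min, na.rm = TRUE)
  pos <- as.integer(names(best))
  graphics::plot(pos, -log10(best), pch = 20,
                 xlab = "mtDNA position (rCRS)",
                 ylab = expression(-log[10](p)),
                 main = "Heteroplasmy vs metabolite-ratio scan")
  if (!is.null(threshold))
    graphics::abline(h = -log10(threshold), lty = 2)
  invisible(NULL)
}

#' QQ plot of scan p-values with genomic-control lambda
#'
#' @param p p-values in (0, 1].
#' @export
plotQQ <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  expect <- -log10(ppoints(n))
  graphics::plot(expect, -log10(p), pch = 20,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 main = sprintf("QQ plot (lambda = %.3f)", genomicLambda(p)))
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}
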