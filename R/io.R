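# Plain-text readers/writers for the pipeline's external formats:
# long-format count TSV, metabolite CSV with a metadata sidecar,
# covariate CSV, FASTA reference, YAML config.

#' Write allele counts as long-format TSV
#'
#' Columns \code{individual_id}, \code{position}, \code{base},
#' \code{count}; zero counts are omitted.
#'
#' @param counts an \linkS4class{AlleleCounts}
#' @param path output TSV path.
#' @export
writeAlleleCounts <- function(counts, path) {
  rows <- lapply(.BASES, function(b) {
    m <- as.matrix(SummarizedExperiment::assay(counts, b))
    nz <- which(m != 0, arr.ind = TRUE)
    if (!nrow(nz)) return(NULL)
    data.table::data.table(
      individual_id = colnames(m)[nz[, 2L]],
      position = SummarizedExperiment::rowData(counts)$position[nz[, 1L]],
      base = b,
      count = m[nz]
    )
  })
  dt <- data.table::rbindlist(rows)
  data.table::setorder(dt, individual_id, position, base)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read allele counts from long-format TSV
#'
#' @param path TSV with columns \code{individual_id}, \code{position},
#'   \code{base}, \code{count}; absent cells are zero.
#' @param colData optional per-individual covariates.
#' @param reference optional reference (\link[Biostrings]{DNAString} or
#'   FASTA path).
#' @return an \linkS4class{AlleleCounts}
#' @export
readAlleleCounts <- function(path, colData = NULL, reference = NULL) {
  dt <- data.table::fread(path)
  need <- c("individual_id", "position", "base", "count")
  if (!all(need %in% names(dt)))
    stop("counts file needs columns ", paste(need, collapse = ", "),
         " (", path, ")")
  ids <- sort(unique(dt$individual_id))
  pos <- sort(unique(dt$position))
  assays <- lapply(setNames(.BASES, .BASES), function(b) {
    m <- matrix(0L, length(pos), length(ids),
                dimnames = list(as.character(pos), ids))
    sub <- dt[dt$base == b, ]
    if (nrow(sub))
      m[cbind(match(sub$position, pos), match(sub$individual_id, ids))] <-
        as.integer(sub$count)
    m
  })
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)[[1L]]
  AlleleCounts(A = assays$A, C = assays$C, G = assays$G, T = assays$T,
               positions = pos, colData = colData, reference = reference)
}

#' Write / read a metabolite panel as CSV plus metadata sidecar
#'
#' The main CSV is individuals x metabolites (first column
#' \code{individual_id}); the sidecar lists \code{metabolite} and
#' \code{class}.
#'
#' @param panel a \linkS4class{MetabolitePanel}
#' @param path main CSV path; the sidecar defaults to
#'   \code{<path>.meta.csv}.
#' @param sidecar metadata CSV path.
#' @export
writeMetabolitePanel <- function(panel, path,
                                 sidecar = paste0(path, ".meta.csv")) {
  conc <- t(concentrations(panel))
  dt <- data.table::data.table(individual_id = rownames(conc))
  for (nm in colnames(conc)) dt[[nm]] <- conc[, nm]
  data.table::fwrite(dt, path)
  data.table::fwrite(
    data.table::data.table(metabolite = rownames(panel),
                           class = metaboliteClasses(panel)),
    sidecar)
  invisible(path)
}

#' @rdname writeMetabolitePanel
#' @export
readMetabolitePanel <- function(path, sidecar = paste0(path, ".meta.csv")) {
  dt <- data.table::fread(path)
  if (names(dt)[1L] != "individual_id")
    stop("first column must be individual_id (", path, ")")
  ids <- dt$individual_id
  m <- as.matrix(dt[, -1L])
  rownames(m) <- ids
  cls <- rep("unknown", ncol(m))
  if (file.exists(sidecar)) {
    meta <- data.table::fread(sidecar)
    cls <- meta$class[match(colnames(m), meta$metabolite)]
    cls[is.na(cls)] <- "unknown"
  }
  MetabolitePanel(conc = t(m), class = cls)
}

#' Read a covariate table
#'
#' CSV with first column \code{individual_id} and at least \code{age},
#' \code{sex}, \code{batch}, \code{contaminated}, \code{diabetic}.
#'
#' @param path CSV path
#' @return data.frame with individual ids as rownames, \code{batch} as a
#'   factor.
#' @export
readCovariates <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  if (!"individual_id" %in% names(dt))
    stop("covariates need an individual_id column (", path, ")")
  rownames(dt) <- dt$individual_id
  dt$individual_id <- NULL
  if ("batch" %in% names(dt)) dt$batch <- factor(dt$batch)
  dt
}

#' @rdname readCovariates
#' @param covariates data.frame with rownames as individual ids.
#' @export
writeCovariates <- function(covariates, path) {
  dt <- data.table::data.table(individual_id = rownames(covariates))
  for (nm in names(covariates)) dt[[nm]] <- covariates[[nm]]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Counts TSV, metabolite CSV (+ sidecar), covariate CSV, reference FASTA
#' and the generating configuration as YAML.
#'
#' @param cohort output of \code{\link{simulateCohort}}
#' @param dir output directory (created if needed).
#' @param config the \linkS4class{SimulationConfig} used (written as
#'   YAML).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAlleleCounts(cohort$counts, file.path(dir, "counts.tsv"))
  writeMetabolitePanel(cohort$panel, file.path(dir, "metabolites.csv"))
  writeCovariates(cohort$covariates, file.path(dir, "covariates.csv"))
  ref <- Biostrings::DNAStringSet(cohort$reference)
  names(ref) <- "chrM"
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
  if (!is.null(config)) writeSimulationConfig(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Serialise / deserialise a SimulationConfig as YAML
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param path YAML path
#' @export
writeSimulationConfig <- function(config, path) {
  lst <- list(
    n_individuals = config@nIndividuals,
    n_metabolites = config@nMetabolites,
    n_positions = config@nPositions,
    mean_coverage = config@meanCoverage,
    block_correlation = config@blockCorrelation,
    missing_rate = config@missingRate,
    outlier_rate = config@outlierRate,
    causal_effects = if (nrow(config@causalEffects))
      lapply(seq_len(nrow(config@causalEffects)), function(i)
        as.list(config@causalEffects[i, ]))
    else list(),
    baseline_logit = config@baselineLogit,
    noise_sd = config@noiseSd,
    batch_count = config@batchCount,
    seed = config@seed
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  ce <- if (length(lst$causal_effects))
    do.call(rbind, lapply(lst$causal_effects, as.data.frame))
  else data.frame(position = integer(), numerator = character(),
                  denominator = character(), beta = numeric())
  SimulationConfig(
    nIndividuals = lst$n_individuals, nMetabolites = lst$n_metabolites,
    nPositions = lst$n_positions, meanCoverage = lst$mean_coverage,
    blockCorrelation = lst$block_correlation,
    missingRate = lst$missing_rate, outlierRate = lst$outlier_rate,
    causalEffects = ce, baselineLogit = lst$baseline_logit,
    noiseSd = lst$noise_sd, batchCount = lst$batch_count, seed = lst$seed
  )
}
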