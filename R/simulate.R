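# Synthetic cohort generator: metabolite panels with block correlation,
# covariates, and binomially sampled allele counts whose log2 heteroplasmy
# odds respond linearly to a metabolite ratio at planted causal positions.

# Split a panel of n metabolites into classes with the proportions of a
# 151-trait serum kit (1 hexose, 35 acylcarnitines, 14 amino acids,
# 14 sphingomyelins, 87 glycerophospholipids); contiguous blocks so that
# "within-block" pairs are adjacent.
.assignClasses <- function(n) {
  ref <- c(acylcarnitine = 35, `amino acid` = 14, glycerophospholipid = 87,
           sphingolipid = 14, hexose = 1)
  prop <- ref / sum(ref)
  base <- floor(prop * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- prop * n - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  base <- base[base > 0]
  rep(names(base), base)
}

.metaboliteNames <- function(classes) {
  abbrev <- c(acylcarnitine = "AC", `amino acid` = "AA",
              glycerophospholipid = "PC", sphingolipid = "SM",
              hexose = "H")
  unlist(lapply(split(seq_along(classes), classes)[unique(classes)],
                function(idx) sprintf("%s%03d", abbrev[[classes[idx[1]]]],
                                      seq_along(idx))),
         use.names = FALSE)
}

#' Simulate a metabolite concentration panel
#'
#' Concentrations have log-normal marginals; log concentrations are
#' equicorrelated at \code{blockCorrelation} within each metabolite class
#' and independent across classes.  A fraction \code{outlierRate} of the
#' observed cells is replaced by high outliers (more than three SD above
#' the column mean) and a fraction \code{missingRate} is masked completely
#' at random.  A complete, pre-outlier copy is kept in the \code{truth}
#' assay as simulation ground truth.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a \linkS4class{MetabolitePanel} (metabolites x individuals)
#' @export
simulateMetabolites <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  n <- config@nIndividuals
  N <- config@nMetabolites
  .withSeed(.stageSeed(config@seed, "metabolites"), {
    classes <- .assignClasses(N)
    nm <- .metaboliteNames(classes)
    # common abundance scale: raw ratios are then O(1), matching the
    # same-magnitude ratios (e.g. two acylcarnitines) the analysis targets
    meanlog <- rep(log(50), N)
    sdlog <- 0.25
    Z <- matrix(rnorm(n * N), n, N)
    rho <- config@blockCorrelation
    if (rho > 0) {
      for (cl in unique(classes)) {
        idx <- which(classes == cl)
        k <- length(idx)
        if (k > 1) {
          Sigma <- matrix(rho, k, k)
          diag(Sigma) <- 1
          Z[, idx] <- Z[, idx] %*% chol(Sigma)
        }
      }
    }
    conc <- exp(sweep(Z * sdlog, 2, meanlog, `+`))  # individuals x metabolites
    truth <- conc
    # outliers injected after the correlation structure, high side only
    # (keeps the positivity invariant)
    n_out <- round(config@outlierRate * length(conc))
    if (n_out > 0) {
      cells <- sample.int(length(conc), n_out)
      cols <- (cells - 1L) %/% n + 1L
      mu <- colMeans(conc)[cols]
      sg <- apply(conc, 2, sd)[cols]
      conc[cells] <- mu + runif(n_out, 3.5, 6) * sg
    }
    # missingness is MCAR
    if (config@missingRate > 0) {
      miss <- runif(length(conc)) < config@missingRate
      conc[miss] <- NA_real_
    }
    ids <- sprintf("ind_%05d", seq_len(n))
    rownames(conc) <- rownames(truth) <- ids
    colnames(conc) <- colnames(truth) <- nm
    MetabolitePanel(conc = t(conc), class = classes, truth = t(truth))
  })
}

#' Simulate per-individual covariates
#'
#' Age uniform over 32-81 years, sex coded 0/1, sequencing plate assigned
#' uniformly over \code{batchCount} plates; contamination and diabetes
#' flags default to \code{FALSE} (the QC fixture generator sets them).
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return data.frame with rownames \code{ind_00001, ...} and columns
#'   \code{age}, \code{sex}, \code{batch}, \code{contaminated},
#'   \code{diabetic}.
#' @export
simulateCovariates <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  n <- config@nIndividuals
  .withSeed(.stageSeed(config@seed, "covariates"), {
    data.frame(
      age = sample(32:81, n, replace = TRUE),
      sex = sample(0:1, n, replace = TRUE),
      batch = factor(sample(seq_len(config@batchCount), n, replace = TRUE),
                     levels = seq_len(config@batchCount)),
      contaminated = FALSE,
      diabetic = FALSE,
      row.names = sprintf("ind_%05d", seq_len(n))
    )
  })
}

#' Simulate allele read counts with planted metabolite-ratio effects
#'
#' For each individual k and position i, read depth is
#' Poisson(\code{meanCoverage}).  The minor-allele fraction theta is the
#' inverse log2-odds of a linear predictor: at causal positions
#' \code{baselineLogit + beta * (MR_k - mean(MR))} plus a per-plate shift
#' and individual noise; at null positions the same without the ratio
#' term.  The minor-allele count B is Binomial(depth, theta), the
#' reference count A is depth - B, and the remaining two bases stay zero.
#' Ratios are taken from the panel's complete \code{truth} assay when
#' present, so missingness never perturbs the generative model.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param panel a \linkS4class{MetabolitePanel} for the same individuals
#' @param covariates data.frame from \code{\link{simulateCovariates}}
#' @return list with elements \code{counts} (an
#'   \linkS4class{AlleleCounts} with the covariates as \code{colData} and
#'   the simulated reference in \code{metadata()$reference}), \code{truth}
#'   (list: \code{trueBetas} data.frame, \code{trueTheta}
#'   position-by-individual matrix) and \code{reference}
#'   (\link[Biostrings]{DNAString}).
#' @export
simulateCounts <- function(config, panel, covariates) {
  stopifnot(is(config, "SimulationConfig"), is(panel, "MetabolitePanel"))
  ids <- colnames(panel)
  if (!identical(sort(ids), sort(rownames(covariates))))
    stop("panel and covariates must describe the same individuals")
  covariates <- covariates[ids, , drop = FALSE]
  n <- length(ids)
  P <- config@nPositions
  ce <- config@causalEffects
  vals <- if ("truth" %in% SummarizedExperiment::assayNames(panel))
    SummarizedExperiment::assay(panel, "truth")
  else SummarizedExperiment::assay(panel, "conc")
  if (nrow(ce)) {
    bad <- setdiff(c(ce$numerator, ce$denominator), rownames(panel))
    if (length(bad))
      stop("causal ratio references metabolites not in the panel: ",
           paste(bad, collapse = ", "))
  }
  .withSeed(.stageSeed(config@seed, "counts"), {
    # transition-biased ref/alt pairs on a random reference
    ref <- sample(.BASES, P, replace = TRUE)
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    alt <- unname(transition[ref])
    batchShift <- rnorm(config@batchCount, 0, 0.2)
    bs <- batchShift[as.integer(covariates$batch)]
    depth <- matrix(rpois(P * n, config@meanCoverage), P, n)
    eta <- matrix(config@baselineLogit, P, n)
    eta <- sweep(eta, 2, bs, `+`)
    if (nrow(ce)) {
      for (r in seq_len(nrow(ce))) {
        mr <- vals[ce$numerator[r], ] / vals[ce$denominator[r], ]
        eta[ce$position[r], ] <- eta[ce$position[r], ] +
          ce$beta[r] * (mr - mean(mr))
      }
    }
    eta <- eta + matrix(rnorm(P * n, 0, config@noiseSd), P, n)
    theta <- stats::plogis(eta * log(2))  # inverse log2-odds
    B <- matrix(rbinom(P * n, depth, theta), P, n)
    A <- depth - B
    assays <- lapply(setNames(.BASES, .BASES), function(b) {
      m <- matrix(0L, P, n)
      rb <- which(ref == b)
      ab <- which(alt == b)
      m[rb, ] <- A[rb, , drop = FALSE]
      m[ab, ] <- B[ab, , drop = FALSE]
      m
    })
    for (b in .BASES) {
      rownames(assays[[b]]) <- as.character(seq_len(P))
      colnames(assays[[b]]) <- ids
    }
    reference <- Biostrings::DNAString(paste(ref, collapse = ""))
    ac <- AlleleCounts(A = assays$A, C = assays$C, G = assays$G,
                       T = assays$T, positions = seq_len(P),
                       colData = covariates, reference = reference)
    dimnames(theta) <- list(as.character(seq_len(P)), ids)
    truth <- list(
      trueBetas = ce,
      trueTheta = theta,
      refBase = ref,
      altBase = alt
    )
    list(counts = ac, truth = truth, reference = reference)
  })
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper: metabolites, covariates and counts from one
#' config and one master seed.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list with \code{counts}, \code{panel}, \code{covariates},
#'   \code{truth}, \code{reference}.
#' @export
simulateCohort <- function(config) {
  panel <- simulateMetabolites(config)
  covariates <- simulateCovariates(config)
  sim <- simulateCounts(config, panel, covariates)
  c(sim["counts"], list(panel = panel, covariates = covariates),
    sim[c("truth", "reference")])
}
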