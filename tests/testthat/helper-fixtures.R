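# Shared in-code fixtures: everything is generated at test time.

# Small cohort config for fast tests.
tinyConfig <- function(...) {
  args <- list(nIndividuals = 200L, nMetabolites = 6L, nPositions = 10L,
               missingRate = 0, outlierRate = 0, seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(SimulationConfig, args)
}

# Direct AlleleCounts from a list of per-base matrices (positions x inds).
toyCounts <- function(A, C = NULL, G = NULL, T = NULL, positions = NULL,
                      colData = NULL, reference = NULL) {
  z <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
  if (is.null(C)) C <- z
  if (is.null(G)) G <- z
  if (is.null(T)) T <- z
  if (is.null(positions)) positions <- seq_len(nrow(A))
  AlleleCounts(A = A, C = C, G = G, T = T, positions = positions,
               colData = colData, reference = reference)
}

# Minimal covariate frame for n individuals.
toyCovariates <- function(n, batches = 2L,
                          contaminated = rep(FALSE, n),
                          diabetic = rep(FALSE, n)) {
  data.frame(
    age = seq(40, 70, length.out = n),
    sex = rep(0:1, length.out = n),
    # batches in blocks so plate contrasts are not collinear with sex
    batch = factor(rep(seq_len(batches), each = ceiling(n / batches),
                       length.out = n)),
    contaminated = contaminated,
    diabetic = diabetic,
    row.names = sprintf("ind_%05d", seq_len(n))
  )
}

# All-A reference of a given length.
toyReference <- function(len, gaps = integer(0)) {
  ch <- rep("A", len)
  ch[gaps] <- "N"
  Biostrings::DNAString(paste(ch, collapse = ""))
}
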