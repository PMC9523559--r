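# Internal helpers shared across modules.

#' @importFrom methods is new validObject
#' @importFrom stats rnorm runif rpois rbinom pnorm qchisq median sd
#'   complete.cases model.matrix setNames lm.fit plogis cor ppoints
NULL

# Derive deterministic per-stage seeds from one master seed.  Kept below
# 2^31 - 1 so they are valid R integer seeds.
.stageSeed <- function(seed, stage) {
  offsets <- c(metabolites = 1L, covariates = 2L, counts = 3L, fixture = 4L,
               impute = 5L, pipeline = 6L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + offsets[[stage]] * 7919) %% 2147483647)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Minimum of a dense or sparse assay matrix (zero counts dominate sparse
# storage, so an empty @x slot means the minimum is zero).
.assayMin <- function(m) {
  if (length(m) == 0L) return(0)
  if (is(m, "sparseMatrix")) {
    x <- m@x
    if (length(x) == 0L) 0 else min(0, min(x))
  } else {
    min(m)
  }
}

# OLS with a Wald summary, robust to rank deficiency: redundant columns
# (pivoted out by the QR) are dropped, remaining coefficients keep their
# original column names.
.olsWald <- function(X, y) {
  qr0 <- qr(X)
  r <- qr0$rank
  keep <- qr0$pivot[seq_len(r)]
  Xk <- X[, keep, drop = FALSE]
  qrk <- qr(Xk)
  if (qrk$rank < r) stop("design matrix rank collapsed unexpectedly")
  # qr() may still pivot within the kept columns; map back
  piv <- qrk$pivot
  beta_p <- qr.coef(qrk, y)
  res <- qr.resid(qrk, y)
  n <- length(y)
  df <- n - r
  if (df <= 0) stop("not enough observations for the design (need > ", r, ")")
  sigma2 <- sum(res^2) / df
  Rinv <- chol2inv(qr.R(qrk))
  se_p <- sqrt(sigma2 * diag(Rinv))
  beta <- beta_p
  se <- se_p
  beta[piv] <- beta_p
  se[piv] <- se_p
  names(beta) <- names(se) <- colnames(Xk)
  list(coef = beta, se = se, kept = colnames(Xk), df = df,
       sigma2 = sigma2, n = n)
}

# Row-wise maximum of B/(A+B) computed in column-bound chunks so that a
# sparse minor-count matrix never densifies whole-genome at once.
.rowMaxMinorFrac <- function(A, B, chunk = 1024L) {
  n <- nrow(A)
  out <- numeric(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + chunk - 1L, n)
    a <- as.matrix(A[start:end, , drop = FALSE])
    b <- as.matrix(B[start:end, , drop = FALSE])
    f <- b / (a + b)
    f[!is.finite(f)] <- 0
    out[start:end] <- f[cbind(seq_len(nrow(f)), max.col(f, ties.method = "first"))]
    start <- end + 1L
  }
  out
}

.BASES <- c("A", "C", "G", "T")
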