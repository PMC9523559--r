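#' Accessors
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param x a package object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exclusionCounts", function(x) standardGeneric("exclusionCounts"))

#' @rdname accessors
#' @export
setGeneric("excludedIds", function(x) standardGeneric("excludedIds"))

#' @rdname accessors
#' @export
setGeneric("retainedIds", function(x) standardGeneric("retainedIds"))

#' @rdname accessors
#' @export
setMethod("exclusionCounts", "QCReport", function(x)
  vapply(x@exclusions, length, integer(1)))

#' @rdname accessors
#' @export
setMethod("excludedIds", "QCReport", function(x) x@exclusions)

#' @rdname accessors
#' @export
setMethod("retainedIds", "QCReport", function(x) x@retained)

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setMethod("concentrations", "MetabolitePanel", function(x)
  SummarizedExperiment::assay(x, "conc"))

#' @rdname accessors
#' @export
setGeneric("metaboliteClasses", function(x)
  standardGeneric("metaboliteClasses"))

#' @rdname accessors
#' @export
setMethod("metaboliteClasses", "MetabolitePanel", function(x)
  setNames(SummarizedExperiment::rowData(x)$class, rownames(x)))

#' @rdname accessors
#' @export
setGeneric("meff", function(x) standardGeneric("meff"))

#' @rdname accessors
#' @export
setMethod("meff", "MeffResult", function(x) x@Meff)

#' @rdname accessors
#' @export
setGeneric("meffThreshold", function(x) standardGeneric("meffThreshold"))

#' @rdname accessors
#' @export
setMethod("meffThreshold", "MeffResult", function(x) x@threshold)

#' Convert a QCReport to a ledger table
#'
#' @param report a \linkS4class{QCReport}
#' @return data.frame with one row per rule plus a retained row; columns
#'   \code{unit}, \code{rule}, \code{n}.
#' @export
qcLedger <- function(report) {
  cnt <- exclusionCounts(report)
  data.frame(
    unit = report@unit,
    rule = c(names(cnt), "retained"),
    n = c(unname(cnt), length(report@retained)),
    row.names = NULL
  )
}
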