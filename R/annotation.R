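# rCRS (NC_012920) feature map for the 16,569 bp mitochondrial genome.
# Built in code as a GRanges; lookups are deterministic (first containing
# feature in table order, ties going to the earlier start).

.RCRS_FEATURES <- data.frame(
  gene = c(
    "Control-HVRI+II", "tRNA-Phe", "12SrRNA", "tRNA-Val", "16SrRNA",
    "tRNA-Leu(UUR)", "ND1", "tRNA-Ile", "tRNA-Gln", "tRNA-Met", "ND2",
    "tRNA-Trp", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr", "CO1",
    "tRNA-Ser(UCN)", "tRNA-Asp", "CO2", "tRNA-Lys", "ATP8", "ATP6",
    "CO3", "tRNA-Gly", "ND3", "tRNA-Arg", "ND4L", "ND4", "tRNA-His",
    "tRNA-Ser(AGY)", "tRNA-Leu(CUN)", "ND5", "ND6", "tRNA-Glu", "CYB",
    "tRNA-Thr", "tRNA-Pro", "Control-HVRI"
  ),
  start = c(
    1L, 577L, 648L, 1602L, 1671L,
    3230L, 3307L, 4263L, 4329L, 4402L, 4470L,
    5512L, 5587L, 5657L, 5761L, 5826L, 5904L,
    7446L, 7518L, 7586L, 8295L, 8366L, 8527L,
    9207L, 9991L, 10059L, 10405L, 10470L, 10760L, 12138L,
    12207L, 12266L, 12337L, 14149L, 14674L, 14747L,
    15888L, 15956L, 16024L
  ),
  end = c(
    576L, 647L, 1601L, 1670L, 3229L,
    3304L, 4262L, 4331L, 4400L, 4469L, 5511L,
    5579L, 5655L, 5729L, 5826L, 5891L, 7445L,
    7514L, 7585L, 8269L, 8364L, 8572L, 9207L,
    9990L, 10058L, 10404L, 10469L, 10766L, 12137L, 12206L,
    12265L, 12336L, 14148L, 14673L, 14742L, 15887L,
    15953L, 16023L, 16569L
  ),
  class = c(
    "control", "tRNA", "rRNA", "tRNA", "rRNA",
    "tRNA", "protein", "tRNA", "tRNA", "tRNA", "protein",
    "tRNA", "tRNA", "tRNA", "tRNA", "tRNA", "protein",
    "tRNA", "tRNA", "protein", "tRNA", "protein", "protein",
    "protein", "tRNA", "protein", "tRNA", "protein", "protein", "tRNA",
    "tRNA", "tRNA", "protein", "protein", "tRNA", "protein",
    "tRNA", "tRNA", "control"
  ),
  stringsAsFactors = FALSE
)

#' rCRS gene annotation as a GRanges
#'
#' Standard NC_012920 feature coordinates (1-based, inclusive): the 13
#' protein-coding genes, 2 rRNAs, 22 tRNAs and the two control-region
#' segments.  A handful of features overlap by a few bases (e.g.
#' ATP8/ATP6); \code{\link{annotatePosition}} resolves overlaps
#' deterministically in favour of the feature starting earlier.
#'
#' @return a \link[GenomicRanges]{GRanges} on seqname \code{chrM} with
#'   metadata columns \code{gene} and \code{class}.
#' @export
rCRSAnnotation <- function() {
  GenomicRanges::GRanges(
    seqnames = "chrM",
    ranges = IRanges::IRanges(start = .RCRS_FEATURES$start,
                              end = .RCRS_FEATURES$end),
    gene = .RCRS_FEATURES$gene,
    class = .RCRS_FEATURES$class
  )
}

#' Annotate mtDNA positions with their containing feature
#'
#' @param position vector of 1-based rCRS coordinates in [1, 16569].
#' @param annotation a \link[GenomicRanges]{GRanges} from
#'   \code{\link{rCRSAnnotation}} (or a custom one with \code{gene} and
#'   \code{class} columns).
#' @return data.frame with \code{position}, \code{gene}, \code{class};
#'   positions in none of the features are labelled
#'   \code{non-coding}/\code{control}.
#' @export
annotatePosition <- function(position, annotation = rCRSAnnotation()) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > 16569L))
    stop("positions must lie within [1, 16569]")
  q <- GenomicRanges::GRanges("chrM",
                              IRanges::IRanges(position, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, annotation, select = "first")
  gene <- ifelse(is.na(hits), "non-coding",
                 S4Vectors::mcols(annotation)$gene[hits])
  cls <- ifelse(is.na(hits), "control",
                S4Vectors::mcols(annotation)$class[hits])
  data.frame(position = position, gene = gene, class = cls,
             row.names = NULL)
}
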