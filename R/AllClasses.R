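#' TranscriptModel: a single spliced transcript
#'
#' One BED12 record: the exon structure of a transcript on a reference
#' sequence. Coordinates are 0-based, half-open (BED convention) throughout.
#' Exons are stored in genomic order; transcript (spliced) coordinates always
#' run 5' to 3' of the mRNA, so on the minus strand transcript offset 0 maps
#' to genomic position \code{txEnd - 1}.
#'
#' @slot name transcript identifier.
#' @slot chrom reference sequence name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons an \linkS4class{IRanges} of exon intervals stored 0-based
#'   half-open as \code{IRanges(start = exonStart, end = exonEnd - 1) + ...};
#'   internally kept as start/width on the 0-based scale (start = genomic
#'   start, width = exon length), sorted and disjoint.
#'
#' @seealso [readBed12()], [splicedLength()], [transcriptToGenome()]
#' @export
setClass("TranscriptModel",
  representation(
    name  = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "'strand' must be \"+\" or \"-\"")
  ex <- object@exons
  if (length(ex) == 0L)
    msg <- c(msg, "at least one exon is required")
  if (any(IRanges::width(ex) < 1L))
    msg <- c(msg, "every exon must have end > start")
  if (length(ex) > 1L) {
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    if (is.unsorted(s, strictly = TRUE) || any(s[-1L] < e[-length(e)] + 1L))
      msg <- c(msg, "exons must be sorted and pairwise disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TranscriptModel constructor. `exonStarts`/`exonEnds` are
#'   0-based half-open genomic intervals in ascending order.
#' @param name,chrom,strand,exonStarts,exonEnds see slots.
#' @export
TranscriptModel <- function(name, chrom, strand, exonStarts, exonEnds) {
  stopifnot(length(exonStarts) == length(exonEnds))
  ex <- IRanges::IRanges(start = as.integer(exonStarts),
                         width = as.integer(exonEnds) - as.integer(exonStarts))
  methods::new("TranscriptModel", name = as.character(name),
               chrom = as.character(chrom), strand = as.character(strand),
               exons = ex)
}

#' CoveragePoints: read depth at sampled transcript positions
#'
#' The evaluated positions of one transcript (the k equally spaced grid
#' points plus the exon-exon junction offsets, deduplicated) together with
#' the read depth at each. Offsets are 0-based transcript coordinates,
#' 5' to 3' of the mRNA.
#'
#' @slot transcript transcript identifier.
#' @slot offsets strictly increasing integer transcript offsets.
#' @slot depths non-negative integer read depths, one per offset.
#'
#' @export
setClass("CoveragePoints",
  representation(
    transcript = "character",
    offsets = "integer",
    depths = "integer"
  )
)

setValidity("CoveragePoints", function(object) {
  msg <- character()
  if (length(object@offsets) != length(object@depths))
    msg <- c(msg, "'offsets' and 'depths' must have equal length")
  if (length(object@offsets) && is.unsorted(object@offsets, strictly = TRUE))
    msg <- c(msg, "'offsets' must be strictly increasing")
  if (any(object@offsets < 0L))
    msg <- c(msg, "'offsets' must be non-negative")
  if (any(object@depths < 0L))
    msg <- c(msg, "'depths' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoveragePoints constructor.
#' @param transcript,offsets,depths see slots.
#' @export
CoveragePoints <- function(transcript, offsets, depths) {
  methods::new("CoveragePoints", transcript = as.character(transcript),
               offsets = as.integer(offsets), depths = as.integer(depths))
}

#' ReadFilter: alignment-level filters applied before counting
#'
#' The uniquely-mapped, high-quality filter used across the package: a
#' minimum mapping quality plus exclusion of secondary, supplementary,
#' duplicate-flagged and QC-fail records. The mapq >= 30 default matches the
#' uniqueness criterion used for fragment-size estimation and is applied to
#' coverage extraction as well for consistency.
#'
#' @slot minMapq minimum mapping quality (default 30).
#' @slot dropSecondary,dropSupplementary,dropDuplicates,dropQcFail logicals.
#'
#' @export
setClass("ReadFilter",
  representation(
    minMapq = "integer",
    dropSecondary = "logical",
    dropSupplementary = "logical",
    dropDuplicates = "logical",
    dropQcFail = "logical"
  )
)

setValidity("ReadFilter", function(object) {
  if (length(object@minMapq) != 1L || is.na(object@minMapq) ||
      object@minMapq < 0L)
    "'minMapq' must be a single non-negative integer"
  else TRUE
})

#' @describeIn ReadFilter constructor.
#' @param minMapq,dropSecondary,dropSupplementary,dropDuplicates,dropQcFail
#'   see slots.
#' @export
ReadFilter <- function(minMapq = 30L, dropSecondary = TRUE,
                       dropSupplementary = TRUE, dropDuplicates = TRUE,
                       dropQcFail = TRUE) {
  methods::new("ReadFilter", minMapq = as.integer(minMapq),
               dropSecondary = isTRUE(dropSecondary),
               dropSupplementary = isTRUE(dropSupplementary),
               dropDuplicates = isTRUE(dropDuplicates),
               dropQcFail = isTRUE(dropQcFail))
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@name, " (", object@chrom, object@strand,
      ") ", length(object@exons), " exon(s), spliced length ",
      sum(IRanges::width(object@exons)), " nt\n", sep = "")
})

setMethod("show", "CoveragePoints", function(object) {
  cat("CoveragePoints for ", object@transcript, ": m = ",
      length(object@offsets), " positions, total depth ",
      sum(object@depths), "\n", sep = "")
})

setMethod("show", "ReadFilter", function(object) {
  cat("ReadFilter: mapq >= ", object@minMapq,
      if (object@dropSecondary) ", no secondary",
      if (object@dropSupplementary) ", no supplementary",
      if (object@dropDuplicates) ", no duplicates",
      if (object@dropQcFail) ", no QC-fail", "\n", sep = "")
})
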