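#' @title Accessors and coordinate arithmetic for TranscriptModel
#' @name transcript-coordinates
#' @description
#' Transcript (spliced) coordinates are 0-based offsets running 5' to 3' of
#' the mRNA. On the plus strand offset 0 is the genomic transcript start; on
#' the minus strand offset 0 is genomic position \code{txEnd - 1} and offsets
#' increase towards smaller genomic coordinates.
NULL

#' @rdname transcript-coordinates
#' @param model a \linkS4class{TranscriptModel}.
#' @return \code{txName}, \code{txChrom}, \code{txStrand}: scalars.
#' @export
txName <- function(model) model@name

#' @rdname transcript-coordinates
#' @export
txChrom <- function(model) model@chrom

#' @rdname transcript-coordinates
#' @export
txStrand <- function(model) model@strand

#' @rdname transcript-coordinates
#' @return \code{txStart}, \code{txEnd}: 0-based half-open genomic span.
#' @export
txStart <- function(model) IRanges::start(model@exons)[1L]

#' @rdname transcript-coordinates
#' @export
txEnd <- function(model) {
  ex <- model@exons
  IRanges::start(ex)[length(ex)] + IRanges::width(ex)[length(ex)]
}

#' @rdname transcript-coordinates
#' @return \code{exonTable}: data.frame with 0-based half-open
#'   \code{start}/\code{end} genomic exon intervals in ascending order.
#' @export
exonTable <- function(model) {
  data.frame(start = IRanges::start(model@exons),
             end = IRanges::start(model@exons) + IRanges::width(model@exons))
}

#' @rdname transcript-coordinates
#' @return \code{splicedLength}: total exonic nucleotides.
#' @export
splicedLength <- function(model) sum(IRanges::width(model@exons))

#' @rdname transcript-coordinates
#' @return \code{junctionOffsets}: transcript offsets of the first base 3' of
#'   each exon-exon junction; length = number of exons - 1.
#' @export
junctionOffsets <- function(model) {
  w <- IRanges::width(model@exons)
  if (length(w) < 2L) return(integer(0))
  if (model@strand == "-") w <- rev(w)
  cumsum(w)[-length(w)]
}

## cumulative exon widths in genomic order, with a leading 0
.cumWidths <- function(model) c(0L, cumsum(IRanges::width(model@exons)))

#' @rdname transcript-coordinates
#' @param offsets integer transcript offsets in \code{[0, splicedLength)}.
#' @return \code{transcriptToGenome}: 0-based genomic positions, one per
#'   offset, each inside an exon.
#' @export
transcriptToGenome <- function(model, offsets) {
  offsets <- as.integer(offsets)
  L <- splicedLength(model)
  if (any(offsets < 0L | offsets >= L))
    stop("transcript offsets must lie in [0, splicedLength)")
  ## genomic-left-oriented offset: identical to the transcript offset on '+',
  ## mirrored on '-'
  gofs <- if (model@strand == "-") L - 1L - offsets else offsets
  cw <- .cumWidths(model)
  idx <- findInterval(gofs, cw, rightmost.closed = FALSE, left.open = FALSE)
  IRanges::start(model@exons)[idx] + (gofs - cw[idx])
}

#' @rdname transcript-coordinates
#' @param positions 0-based genomic positions.
#' @return \code{genomeToTranscript}: transcript offsets; NA for positions
#'   outside the exons.
#' @export
genomeToTranscript <- function(model, positions) {
  positions <- as.integer(positions)
  s <- IRanges::start(model@exons)
  w <- IRanges::width(model@exons)
  cw <- .cumWidths(model)
  idx <- findInterval(positions, s)
  ok <- idx >= 1L & positions < (s[pmax(idx, 1L)] + w[pmax(idx, 1L)])
  gofs <- rep(NA_integer_, length(positions))
  gofs[ok] <- cw[idx[ok]] + (positions[ok] - s[idx[ok]])
  if (model@strand == "-") {
    L <- splicedLength(model)
    gofs <- L - 1L - gofs
  }
  gofs
}

## Map a half-open transcript interval [s, e) onto genomic blocks
## (0-based half-open, ascending). Used by the simulator and 3' windows.
.txIntervalToBlocks <- function(model, s, e) {
  L <- splicedLength(model)
  stopifnot(s >= 0L, e <= L, e > s)
  if (model@strand == "-") { tmp <- s; s <- L - e; e <- L - tmp }
  cw <- .cumWidths(model)
  es <- IRanges::start(model@exons)
  i1 <- findInterval(s, cw)
  i2 <- findInterval(e - 1L, cw)
  starts <- integer(0); ends <- integer(0)
  for (i in seq(i1, i2)) {
    bs <- es[i] + max(0L, s - cw[i])
    be <- es[i] + min(cw[i + 1L] - cw[i], e - cw[i])
    starts <- c(starts, bs); ends <- c(ends, be)
  }
  cbind(start = starts, end = ends)
}

#' Genomic region of the 3'-most N spliced nucleotides
#'
#' Returns the genomic intervals covering the 3'-terminal
#' \code{min(N, splicedLength)} transcript nucleotides, the counting window
#' used by 3' tag counting. On the minus strand this is the genomically
#' leftmost part of the transcript.
#'
#' @param model a \linkS4class{TranscriptModel}.
#' @param N window size in transcript nucleotides (>= 1).
#' @return a \linkS4class{GRanges} (1-based, as usual for GRanges) of the
#'   window's genomic intervals.
#' @export
threePrimeRegion <- function(model, N) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("'N' must be >= 1")
  L <- splicedLength(model)
  n <- min(N, L)
  blocks <- .txIntervalToBlocks(model, L - n, L)
  GenomicRanges::GRanges(model@chrom,
    IRanges::IRanges(start = blocks[, "start"] + 1L, end = blocks[, "end"]),
    strand = model@strand)
}

#' Exons of a transcript as a GRanges
#'
#' @param model a \linkS4class{TranscriptModel}.
#' @return a \linkS4class{GRanges} (1-based) of the exon intervals.
#' @export
exonGRanges <- function(model) {
  GenomicRanges::GRanges(model@chrom,
    IRanges::IRanges(start = IRanges::start(model@exons) + 1L,
                     width = IRanges::width(model@exons)),
    strand = model@strand)
}
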