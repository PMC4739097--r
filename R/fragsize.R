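#' Intron-subtracted fragment size of one read pair
#'
#' The fragment covered by a read pair is measured as the genomic distance
#' from the leftmost aligned base of either mate to the rightmost aligned
#' base of the other (half-open span), minus the lengths of all model
#' introns fully contained in that span. A pair confined to one exon thus
#' has size equal to its plain genomic span; a pair bridging an intron has
#' the intron length removed, recovering the spliced (RNA) fragment length.
#'
#' @param model a \linkS4class{TranscriptModel}.
#' @param spanStart,spanEnd 0-based half-open genomic span of the pair
#'   (vectorised).
#' @return integer fragment sizes in nucleotides.
#' @examples
#' m <- TranscriptModel("tx", "chr1", "+", c(0, 1200), c(200, 1400))
#' pairFragmentSize(m, 100, 326)    # single exon: 226
#' pairFragmentSize(m, 100, 1326)   # bridges the 1000 nt intron: 226
#' @export
pairFragmentSize <- function(model, spanStart, spanEnd) {
  spanStart <- as.integer(spanStart); spanEnd <- as.integer(spanEnd)
  stopifnot(length(spanStart) == length(spanEnd))
  size <- spanEnd - spanStart
  ex <- exonTable(model)
  if (nrow(ex) > 1L) {
    istart <- ex$end[-nrow(ex)]
    iend <- ex$start[-1L]
    for (i in seq_along(istart)) {
      inside <- istart[i] >= spanStart & iend[i] <= spanEnd
      size[inside] <- size[inside] - (iend[i] - istart[i])
    }
  }
  size
}

## Accepted-pair sizes for one transcript, with categorized rejections.
## Returns list(sizes=data.frame(qname,size), rejected=named counts).
.acceptedPairSizes <- function(bam, model, minMapq = 30L) {
  .checkIndexed(bam)
  rej <- c(low_mapq = 0L, off_model = 0L, nonpositive = 0L)
  if (!model@chrom %in% .bamContigs(bam))
    return(list(sizes = data.frame(qname = character(0), size = integer(0)),
                rejected = rej))
  which <- GenomicRanges::GRanges(model@chrom,
    IRanges::IRanges(txStart(model) + 1L, txEnd(model)))
  param <- Rsamtools::ScanBamParam(
    which = which, what = "mapq",
    flag = Rsamtools::scanBamFlag(
      isPaired = TRUE, hasUnmappedMate = FALSE,
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE, isNotPassingQualityControls = FALSE))
  gp <- suppressWarnings(GenomicAlignments::readGAlignmentPairs(
    bam, param = param, use.names = TRUE))
  if (length(gp) == 0L)
    return(list(sizes = data.frame(qname = character(0), size = integer(0)),
                rejected = rej))
  f <- GenomicAlignments::first(gp)
  l <- GenomicAlignments::last(gp)
  mq <- pmin(S4Vectors::mcols(f)$mapq, S4Vectors::mcols(l)$mapq)
  okMq <- !is.na(mq) & mq >= minMapq
  rej[["low_mapq"]] <- sum(!okMq)
  gp <- gp[okMq]; f <- f[okMq]; l <- l[okMq]
  if (length(gp) == 0L)
    return(list(sizes = data.frame(qname = character(0), size = integer(0)),
                rejected = rej))
  ## both mates' aligned blocks must lie within the exon structure
  exGR <- GenomicRanges::GRanges(model@chrom,
    IRanges::IRanges(start = IRanges::start(model@exons) + 1L,
                     width = IRanges::width(model@exons)))
  blocks <- GenomicAlignments::grglist(gp)   # splits N gaps
  ub <- unlist(blocks, use.names = FALSE)
  hit <- GenomicRanges::countOverlaps(ub, exGR, type = "within",
                                      ignore.strand = TRUE)
  idx <- rep(seq_along(blocks), S4Vectors::elementNROWS(blocks))
  onModel <- !(seq_along(blocks) %in% idx[hit == 0])
  rej[["off_model"]] <- sum(!onModel)
  gp <- gp[onModel]; f <- f[onModel]; l <- l[onModel]
  if (length(gp) == 0L)
    return(list(sizes = data.frame(qname = character(0), size = integer(0)),
                rejected = rej))
  spanStart <- pmin(GenomicRanges::start(f), GenomicRanges::start(l)) - 1L
  spanEnd <- pmax(GenomicRanges::end(f), GenomicRanges::end(l))
  size <- pairFragmentSize(model, spanStart, spanEnd)
  okSz <- size > 0L
  rej[["nonpositive"]] <- sum(!okSz)
  list(sizes = data.frame(qname = names(gp)[okSz], size = size[okSz],
                          stringsAsFactors = FALSE),
       rejected = rej)
}

#' Transcript-level RNA fragment size
#'
#' Mean fragment size over all accepted read pairs fully contained in one
#' transcript's exon structure. Transcripts with fewer than \code{minPairs}
#' accepted pairs (default 30) yield no estimate, which keeps unreliable
#' low-coverage estimates out of downstream comparisons.
#'
#' @param bam indexed BAM path.
#' @param model a \linkS4class{TranscriptModel}.
#' @param minPairs minimum accepted pairs for an estimate (default 30).
#' @param minMapq minimum mapping quality of both mates (default 30).
#' @param keepSizes retain the individual sizes in the result.
#' @return a list: \code{level = "transcript"}, \code{transcript},
#'   \code{nPairs}, \code{meanSize}, \code{medianSize}, \code{rejected}
#'   (named counts), and \code{sizes} when requested. \code{meanSize} is NA
#'   when \code{nPairs < minPairs}.
#' @export
transcriptFragmentSize <- function(bam, model, minPairs = 30L,
                                   minMapq = 30L, keepSizes = FALSE) {
  if (minPairs < 1L) stop("'minPairs' must be >= 1")
  acc <- .acceptedPairSizes(bam, model, minMapq = minMapq)
  n <- nrow(acc$sizes)
  est <- list(level = "transcript", transcript = txName(model), nPairs = n,
              meanSize = if (n >= minPairs) mean(acc$sizes$size) else NA_real_,
              medianSize = if (n >= minPairs) stats::median(acc$sizes$size)
                           else NA_real_,
              rejected = acc$rejected)
  if (keepSizes) est$sizes <- acc$sizes$size
  est
}

#' Sample-level RNA fragment size
#'
#' Mean fragment size over all accepted read pairs across the supplied
#' transcript models (use [longestIsoformPerGene()] upstream so isoforms do
#' not double-count pairs). Each pair contributes once even if it is
#' contained in several transcripts. Fragment size shrinks as in vitro
#' degradation shortens RNA molecules, so this mean is a direct physical
#' surrogate for sample RNA integrity.
#'
#' @param bam indexed BAM path; must be paired-end (single-end data cannot
#'   yield fragment sizes and raises an error).
#' @param models list of \linkS4class{TranscriptModel}.
#' @param minMapq minimum mapping quality of both mates (default 30).
#' @param keepSizes retain individual sizes.
#' @return a list: \code{level = "sample"}, \code{nPairs}, \code{meanSize},
#'   \code{medianSize}, \code{rejected}, optionally \code{sizes}.
#' @export
sampleFragmentSize <- function(bam, models, minMapq = 30L,
                               keepSizes = FALSE) {
  .checkIndexed(bam)
  if (!suppressMessages(Rsamtools::testPairedEndBam(bam)))
    stop("single-end alignments: fragment size cannot be estimated ",
         "without read pairs")
  all <- lapply(models, function(m)
    .acceptedPairSizes(bam, m, minMapq = minMapq))
  sizes <- do.call(rbind, lapply(all, `[[`, "sizes"))
  rej <- Reduce(`+`, lapply(all, `[[`, "rejected"))
  ## a pair contained in more than one supplied transcript counts once
  sizes <- sizes[!duplicated(sizes$qname), , drop = FALSE]
  if (nrow(sizes) == 0L)
    stop("no accepted read pairs; cannot estimate sample fragment size")
  est <- list(level = "sample", nPairs = nrow(sizes),
              meanSize = mean(sizes$size),
              medianSize = stats::median(sizes$size), rejected = rej)
  if (keepSizes) est$sizes <- sizes$size
  est
}
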