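#' Sample evaluation positions along a transcript
#'
#' Selects k equally spaced transcript positions from the 5' end to the 3'
#' end, adds every exon-exon junction offset, deduplicates and sorts. The
#' grid is rounded to integers (nearest, half-up), so when k exceeds the
#' spliced length it collapses onto all positions.
#'
#' @param model a \linkS4class{TranscriptModel}.
#' @param k number of grid positions (>= 2; default 100).
#' @return sorted, distinct integer transcript offsets.
#' @examples
#' m <- TranscriptModel("tx", "chr1", "+", c(100, 700), c(200, 900))
#' samplePositions(m, k = 2)  # 0, 100 (junction), 299
#' @export
samplePositions <- function(model, k = 100L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2")
  L <- splicedLength(model)
  grid <- as.integer(floor(seq(0, L - 1, length.out = k) + 0.5))
  sort(unique(c(grid, junctionOffsets(model))))
}

## ScanBamParam flag built from a ReadFilter; NA leaves a bit unfiltered.
.filterFlag <- function(filter) {
  Rsamtools::scanBamFlag(
    isSecondaryAlignment = if (filter@dropSecondary) FALSE else NA,
    isSupplementaryAlignment = if (filter@dropSupplementary) FALSE else NA,
    isDuplicate = if (filter@dropDuplicates) FALSE else NA,
    isNotPassingQualityControls = if (filter@dropQcFail) FALSE else NA)
}

.checkIndexed <- function(bam) {
  if (is(bam, "BamFile")) bam <- Rsamtools::path(bam)
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(idx)))
    stop("BAM file ", bam, " has no index; create one with ",
         "Rsamtools::indexBam() or 'samtools index'")
  invisible(bam)
}

.bamContigs <- function(bam) {
  names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
}

## pileup restricted to the given 1-based GRanges; returns data.frame with
## pos (1-based) and count, depth 0 positions absent.
.pileupAt <- function(bam, which, filter) {
  sbp <- Rsamtools::ScanBamParam(which = which, flag = .filterFlag(filter))
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = 0L,
    min_mapq = filter@minMapq, min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, distinguish_nucleotides = FALSE,
    ignore_query_Ns = FALSE,
    include_deletions = FALSE, include_insertions = FALSE)
  Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
}

#' Read depth at sampled transcript positions
#'
#' Counts, at each requested transcript offset, the filter-passing reads
#' whose aligned (M/=/X) bases cover the corresponding genomic position.
#' Deletions and splice gaps in a read contribute no coverage; both mates of
#' a pair contribute independently.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param model a \linkS4class{TranscriptModel}.
#' @param offsets transcript offsets to evaluate (default
#'   \code{samplePositions(model, k)} with k = 100).
#' @param filter a \linkS4class{ReadFilter}.
#' @param k grid size forwarded to [samplePositions()] when \code{offsets}
#'   is missing.
#' @return a \linkS4class{CoveragePoints}. If the transcript's contig is not
#'   in the BAM header a warning is emitted and all depths are 0.
#' @export
depthAt <- function(bam, model, offsets = NULL, filter = ReadFilter(),
                    k = 100L) {
  .checkIndexed(bam)
  if (is.null(offsets)) offsets <- samplePositions(model, k)
  offsets <- sort(unique(as.integer(offsets)))
  if (!model@chrom %in% .bamContigs(bam)) {
    warning("contig ", model@chrom, " absent from BAM; depths set to 0 for ",
            model@name)
    return(CoveragePoints(model@name, offsets, rep(0L, length(offsets))))
  }
  gpos <- transcriptToGenome(model, offsets)        # 0-based
  which <- GenomicRanges::GRanges(model@chrom,
    IRanges::IRanges(min(gpos) + 1L, max(gpos) + 1L))
  p <- .pileupAt(bam, which, filter)
  depths <- integer(length(offsets))
  hit <- match(gpos + 1L, p$pos)
  ok <- !is.na(hit)
  depths[ok] <- p$count[hit[ok]]
  CoveragePoints(model@name, offsets, depths)
}

#' Base-resolution spliced coverage of a transcript
#'
#' Depth at every exonic base, returned in transcript orientation
#' (element 1 = 5' end of the mRNA).
#'
#' @inheritParams depthAt
#' @return integer vector of length \code{splicedLength(model)}.
#' @export
splicedCoverage <- function(bam, model, filter = ReadFilter()) {
  .checkIndexed(bam)
  L <- splicedLength(model)
  cov <- integer(L)
  if (!model@chrom %in% .bamContigs(bam)) {
    warning("contig ", model@chrom, " absent from BAM; coverage 0 for ",
            model@name)
    return(cov)
  }
  ex <- exonTable(model)
  which <- GenomicRanges::GRanges(model@chrom,
    IRanges::IRanges(start = ex$start + 1L, end = ex$end))
  p <- .pileupAt(bam, which, filter)
  if (nrow(p)) {
    ofs <- genomeToTranscript(model, p$pos - 1L)
    ok <- !is.na(ofs)
    ## positions can repeat across which-ranges only if exons overlapped,
    ## which the class forbids
    cov[ofs[ok] + 1L] <- p$count[ok]
  }
  cov
}
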