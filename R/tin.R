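#' Relative coverage
#'
#' Converts per-position read depths C_i into the relative-coverage
#' distribution P_i = C_i / sum(C), the discrete distribution whose evenness
#' the TIN score measures.
#'
#' @param depths non-negative numeric depths, at least one positive.
#' @return numeric vector summing to 1.
#' @export
relativeCoverage <- function(depths) {
  if (any(depths < 0)) stop("depths must be non-negative")
  tot <- sum(depths)
  if (tot == 0) stop("no coverage: all depths are zero")
  depths / tot
}

#' Shannon entropy of a coverage distribution
#'
#' H = -sum(P_i * ln P_i) in nats, with the convention 0 * ln 0 = 0 so
#' uncovered positions contribute nothing. The natural logarithm is used
#' throughout because the uniformity U = exp(H) is then the effective number
#' of equally covered positions (the Hill number of order 1).
#'
#' @param p probabilities summing to 1.
#' @return entropy in nats, in \code{[0, log(length(p))]}.
#' @export
shannonEntropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' TIN score of one transcript
#'
#' The transcript integrity number: TIN = 100 * exp(H) / m, where H is the
#' Shannon entropy of the relative coverage over the m evaluated positions
#' (the equally spaced grid plus junction positions, deduplicated). 100 means
#' perfectly uniform coverage over all evaluated positions; a single covered
#' position gives 100/m.
#'
#' Transcripts whose mean sampled depth is below \code{minMeanDepth} are not
#' scored: they get TIN 0 with entropy and uniformity recorded as NA, and are
#' flagged \code{scored = FALSE} so that sample summaries can exclude them.
#'
#' @param points a \linkS4class{CoveragePoints}, or a bare numeric vector of
#'   depths (then treated as m = length(depths) evaluated positions).
#' @param minMeanDepth minimum mean depth across evaluated positions for the
#'   transcript to be scored (default 10; use 0 to score everything).
#' @return a list with elements \code{transcript}, \code{m},
#'   \code{meanDepth}, \code{entropy}, \code{uniformity}, \code{tin},
#'   \code{scored}.
#' @examples
#' tinScore(c(1, 1, 2), minMeanDepth = 0)$tin  # 100 * 2^1.5 / 3
#' @export
tinScore <- function(points, minMeanDepth = 10) {
  if (is(points, "CoveragePoints")) {
    depths <- points@depths
    id <- points@transcript
  } else {
    depths <- as.numeric(points)
    id <- NA_character_
  }
  m <- length(depths)
  if (m == 0L) stop("no evaluated positions")
  meanDepth <- mean(depths)
  if (meanDepth < minMeanDepth || sum(depths) == 0) {
    return(list(transcript = id, m = m, meanDepth = meanDepth,
                entropy = NA_real_, uniformity = NA_real_,
                tin = 0, scored = FALSE))
  }
  H <- shannonEntropy(relativeCoverage(depths))
  U <- exp(H)
  tin <- min(100, max(0, 100 * U / m))   # clip rounding overshoot
  list(transcript = id, m = m, meanDepth = meanDepth,
       entropy = H, uniformity = U, tin = tin, scored = TRUE)
}

#' Per-transcript TIN table for one BAM
#'
#' Runs position sampling, depth extraction and TIN scoring over a set of
#' transcript models against one alignment file.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param models list of \linkS4class{TranscriptModel} (apply
#'   [longestIsoformPerGene()] upstream for per-gene scores).
#' @param k number of equally spaced positions sampled per transcript
#'   (default 100).
#' @param filter a \linkS4class{ReadFilter}.
#' @param minMeanDepth scoring threshold, see [tinScore()].
#' @return data.frame with one row per transcript: \code{transcript},
#'   \code{chrom}, \code{txStart}, \code{txEnd}, \code{splicedLength},
#'   \code{meanSampledDepth}, \code{entropy}, \code{uniformity}, \code{m},
#'   \code{tin}, \code{scored}.
#' @export
transcriptTIN <- function(bam, models, k = 100L, filter = ReadFilter(),
                          minMeanDepth = 10) {
  rows <- lapply(models, function(m) {
    pts <- depthAt(bam, m, filter = filter, k = k)
    r <- tinScore(pts, minMeanDepth = minMeanDepth)
    data.frame(transcript = txName(m), chrom = txChrom(m),
               txStart = txStart(m), txEnd = txEnd(m),
               splicedLength = splicedLength(m),
               meanSampledDepth = r$meanDepth, entropy = r$entropy,
               uniformity = r$uniformity, m = r$m, tin = r$tin,
               scored = r$scored)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Sample-level TIN summary (medTIN)
#'
#' The median TIN across scored transcripts summarises a whole library's RNA
#' integrity, playing the role of an electrophoresis RIN but computed from
#' the sequencing data itself. Transcripts below the coverage threshold are
#' counted as skipped and, by default, excluded from the summary.
#'
#' @param tins a data.frame from [transcriptTIN()], or a numeric vector of
#'   TIN values (then all treated as scored).
#' @param sample sample identifier stored in the output.
#' @param includeUnscored include unscored (below-threshold, TIN 0)
#'   transcripts in the median/mean/sd (default FALSE).
#' @return data.frame with one row: \code{sample}, \code{nScored},
#'   \code{nSkipped}, \code{medTin}, \code{meanTin}, \code{sdTin}. With an
#'   even number of values the median is the mean of the two central ones.
#' @export
medTin <- function(tins, sample = NA_character_, includeUnscored = FALSE) {
  if (is.data.frame(tins)) {
    scored <- tins$scored
    vals <- tins$tin
  } else {
    vals <- as.numeric(tins)
    scored <- rep(TRUE, length(vals))
  }
  if (!length(vals)) stop("at least one TIN record is required")
  use <- if (includeUnscored) rep(TRUE, length(vals)) else scored
  x <- vals[use]
  if (!length(x)) {
    warning("no scored transcripts; medTIN is NA")
    return(data.frame(sample = sample, nScored = 0L,
                      nSkipped = sum(!scored), medTin = NA_real_,
                      meanTin = NA_real_, sdTin = NA_real_))
  }
  data.frame(sample = sample, nScored = sum(scored),
             nSkipped = sum(!scored),
             medTin = stats::median(x), meanTin = mean(x),
             sdTin = stats::sd(x))
}
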