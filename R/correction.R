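#' Loess correction of gene-level counts against TIN
#'
#' In degraded libraries, apparent expression depends on how intact each
#' gene's transcripts are: log read counts trend with per-gene TIN. This
#' function removes that trend within one sample. Counts are taken to
#' log2(count + 1), a loess curve of log count on TIN is fitted, and each
#' gene keeps its residual from the curve, recentred so the sample's median
#' log count is unchanged:
#'
#'   y'_i = y_i - yhat_i + median(y) - median(y - yhat)
#'
#' The trailing term recentres the loess residuals exactly at the original
#' median; it vanishes when the residuals have zero median, in which case
#' the expression reduces to the plain y_i - yhat_i + median(y) shift.
#' Corrected values are returned on the count scale (2^y' - 1, floored at
#' 0). Genes with zero count or TIN 0 (unscored) are excluded from the fit
#' and passed through unchanged, flagged in the output.
#'
#' @param counts non-negative numeric gene counts for one sample.
#' @param tins matching per-gene TIN scores.
#' @param span loess span in (0, 1] (default 0.75); degree-2 local
#'   polynomial with tricube weights and no robustness iterations.
#' @param minFitGenes minimum genes with count > 0 and TIN > 0 required to
#'   fit (default 30).
#' @param integerize round corrected counts to integers for strict
#'   count-model consumers (default FALSE: 3 decimals).
#' @return a list: \code{corrected} (counts), \code{logCorrected},
#'   \code{fitted} (NA outside the fit set), \code{inFit} (logical),
#'   \code{diagnostics} (data.frame: span, nFit, rPre, rPost — Pearson r
#'   between log count and TIN before/after).
#' @examples
#' set.seed(1)
#' tin <- runif(200, 20, 90)
#' cnt <- round(2^(5 + 0.05 * tin + rnorm(200, 0, 0.3)))
#' res <- loessCorrect(cnt, tin)
#' res$diagnostics   # rPost near 0
#' @export
loessCorrect <- function(counts, tins, span = 0.75, minFitGenes = 30L,
                         integerize = FALSE) {
  stopifnot(length(counts) == length(tins))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  inFit <- !is.na(counts) & !is.na(tins) & counts > 0 & tins > 0
  nFit <- sum(inFit)
  if (nFit < minFitGenes)
    stop("only ", nFit, " genes with count > 0 and TIN > 0; need at least ",
         minFitGenes, " to fit")
  y <- log2(counts + 1)
  t <- tins
  if (stats::var(t[inFit]) < 1e-8) {
    warning("TIN scores are (near-)constant; returning counts unchanged")
    return(list(corrected = counts, logCorrected = y,
                fitted = rep(NA_real_, length(y)), inFit = inFit,
                diagnostics = data.frame(span = span, nFit = nFit,
                                         rPre = NA_real_, rPost = NA_real_)))
  }
  fit <- stats::loess(y[inFit] ~ t[inFit], span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  yhat <- rep(NA_real_, length(y))
  yhat[inFit] <- stats::predict(fit, newdata = t[inFit])
  med <- stats::median(y[inFit])
  resid <- y[inFit] - yhat[inFit]
  ycorr <- y
  ycorr[inFit] <- resid + med - stats::median(resid)
  corrected <- counts
  corrected[inFit] <- pmax(2^ycorr[inFit] - 1, 0)
  corrected[inFit] <- if (integerize) round(corrected[inFit])
                      else round(corrected[inFit], 3)
  diag <- data.frame(
    span = span, nFit = nFit,
    rPre = stats::cor(y[inFit], t[inFit]),
    rPost = stats::cor(ycorr[inFit], t[inFit]))
  list(corrected = corrected, logCorrected = ycorr, fitted = yhat,
       inFit = inFit, diagnostics = diag)
}

#' Correct a genes-by-samples count matrix
#'
#' Applies [loessCorrect()] independently to each sample (column), pairing
#' it with the matching column of a TIN matrix of identical shape.
#'
#' @param counts genes x samples numeric matrix (or data.frame) of raw
#'   counts, with gene rownames.
#' @param tins matrix of identical dimensions and ordering holding
#'   per-(gene, sample) TIN scores.
#' @param ... passed to [loessCorrect()].
#' @return a list: \code{corrected} matrix and \code{diagnostics}
#'   data.frame (one row per sample).
#' @export
correctCounts <- function(counts, tins, ...) {
  counts <- as.matrix(counts); tins <- as.matrix(tins)
  if (!identical(dim(counts), dim(tins)))
    stop("'counts' and 'tins' must have identical dimensions")
  if (!is.null(rownames(counts)) && !is.null(rownames(tins)) &&
      !identical(rownames(counts), rownames(tins)))
    stop("'counts' and 'tins' must have identical gene ordering")
  out <- counts
  diags <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    res <- loessCorrect(counts[, j], tins[, j], ...)
    out[, j] <- res$corrected
    diags[[j]] <- cbind(sample = colnames(counts)[j] %||% as.character(j),
                        res$diagnostics)
  }
  list(corrected = out, diagnostics = do.call(rbind, diags))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 3' tag count of a transcript
#'
#' Counts filter-passing reads whose alignment overlaps the 3'-terminal
#' \code{min(N, splicedLength)} spliced nucleotides of the transcript (see
#' [threePrimeRegion()]). Restricting quantification to a short 3' window
#' makes counts comparable across degradation levels under oligo-dT
#' selection, at the price of discarding most reads.
#'
#' @param bam indexed BAM path.
#' @param model a \linkS4class{TranscriptModel}.
#' @param N window size in transcript nucleotides (default 250).
#' @param filter a \linkS4class{ReadFilter}.
#' @return integer read count; each read counts once however many window
#'   intervals it touches.
#' @export
threePrimeTagCount <- function(bam, model, N = 250L, filter = ReadFilter()) {
  .checkIndexed(bam)
  if (!model@chrom %in% .bamContigs(bam)) return(0L)
  region <- threePrimeRegion(model, N)
  which <- range(GenomicRanges::granges(region), ignore.strand = TRUE)
  param <- Rsamtools::ScanBamParam(which = which, flag = .filterFlag(filter),
                                   mapqFilter = filter@minMapq)
  galn <- GenomicAlignments::readGAlignments(bam, param = param,
                                             use.names = FALSE)
  if (length(galn) == 0L) return(0L)
  sum(GenomicRanges::countOverlaps(galn, region, ignore.strand = TRUE) > 0L)
}
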