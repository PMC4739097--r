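#' Read a BED12 gene model
#'
#' Parses a 12-column BED file into a list of \linkS4class{TranscriptModel}
#' objects, reconstructing exons from \code{chromStart} plus
#' \code{blockStarts}/\code{blockSizes}. Input order is preserved. Lines that
#' are empty, or that start with \code{track}, \code{browser} or \code{#},
#' are ignored.
#'
#' @param path path to a BED12 file (plain text, tab-separated).
#' @param onError \code{"stop"} (default) aborts on the first malformed line
#'   with a message naming the line; \code{"skip"} drops malformed lines with
#'   a warning each.
#' @return a named list of \linkS4class{TranscriptModel}; names are the BED
#'   \code{name} fields.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t900\ttxA\t0\t+\t100\t900\t0\t2\t100,200\t0,600", bed)
#' m <- readBed12(bed)[[1]]
#' splicedLength(m)  # 300
#' @export
readBed12 <- function(path, onError = c("stop", "skip")) {
  onError <- match.arg(onError)
  if (!file.exists(path)) stop("BED12 file not found: ", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || grepl("^(track|browser|#)", ln)) next
    m <- tryCatch(.parseBed12Line(ln, i), error = function(e) e)
    if (inherits(m, "error")) {
      if (onError == "stop") stop(conditionMessage(m), call. = FALSE)
      warning(conditionMessage(m), call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- m
  }
  names(out) <- vapply(out, txName, character(1))
  out
}

.parseBed12Line <- function(ln, lineno) {
  f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 12L)
    stop("line ", lineno, ": expected >= 12 tab-separated fields, got ",
         length(f))
  name <- f[4L]
  chromStart <- suppressWarnings(as.integer(f[2L]))
  chromEnd <- suppressWarnings(as.integer(f[3L]))
  blockCount <- suppressWarnings(as.integer(f[10L]))
  if (anyNA(c(chromStart, chromEnd, blockCount)))
    stop("line ", lineno, " (", name, "): non-numeric coordinate field")
  sizes <- suppressWarnings(as.integer(.splitCsv(f[11L])))
  starts <- suppressWarnings(as.integer(.splitCsv(f[12L])))
  if (length(sizes) != blockCount || length(starts) != blockCount)
    stop("line ", lineno, " (", name, "): blockCount (", blockCount,
         ") does not match blockSizes/blockStarts lengths (",
         length(sizes), "/", length(starts), ")")
  if (anyNA(sizes) || anyNA(starts))
    stop("line ", lineno, " (", name, "): non-numeric block field")
  exonStarts <- chromStart + starts
  exonEnds <- exonStarts + sizes
  if (starts[1L] != 0L || exonEnds[blockCount] != chromEnd)
    stop("line ", lineno, " (", name,
         "): blocks do not span chromStart..chromEnd")
  strand <- f[6L]
  ## strandless records are treated as '+': transcript offsets then coincide
  ## with genomic-left offsets
  if (!strand %in% c("+", "-")) strand <- "+"
  TranscriptModel(name, f[1L], strand, exonStarts, exonEnds)
}

.splitCsv <- function(x) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  parts[nzchar(parts)]
}

#' Write transcript models as BED12
#'
#' Inverse of [readBed12()]: exon structures round-trip exactly. Score 0 and
#' thickStart/thickEnd equal to the transcript span are written; itemRgb 0.
#'
#' @param models a list of \linkS4class{TranscriptModel}.
#' @param path output path.
#' @export
writeBed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    ex <- exonTable(m)
    s <- txStart(m)
    paste(m@chrom, s, txEnd(m), m@name, 0L, m@strand, s, txEnd(m), 0L,
          nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - s, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Keep the longest isoform per gene
#'
#' When a gene has several splicing isoforms, only the longest (by spliced
#' length) is retained, as required for fragment-size estimation and per-gene
#' TIN. Ties are broken by the lexicographically smallest transcript name so
#' the choice is deterministic.
#'
#' @param models a list of \linkS4class{TranscriptModel}.
#' @param geneOf optional named character vector mapping transcript name to
#'   gene id. When absent, each transcript is its own gene unless
#'   \code{separator} is given, in which case the gene id is the transcript
#'   name prefix before the first separator.
#' @param separator optional single character used to derive gene ids from
#'   transcript names (e.g. \code{"."} maps \code{"g1.t2"} to gene
#'   \code{"g1"}).
#' @return the selected models, in input order.
#' @export
longestIsoformPerGene <- function(models, geneOf = NULL, separator = NULL) {
  nm <- vapply(models, txName, character(1))
  genes <- if (!is.null(geneOf)) {
    miss <- setdiff(nm, names(geneOf))
    if (length(miss))
      stop("no gene mapping for transcript(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    unname(geneOf[nm])
  } else if (!is.null(separator)) {
    vapply(strsplit(nm, separator, fixed = TRUE),
           `[[`, character(1), 1L)
  } else nm
  len <- vapply(models, splicedLength, numeric(1))
  ord <- order(genes, -len, nm)
  keep <- ord[!duplicated(genes[ord])]
  models[sort(keep)]
}

#' Read a two-column transcript-to-gene map
#'
#' @param path TSV with columns transcript, gene (no header).
#' @return named character vector: names are transcripts, values genes.
#' @export
readGeneMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("gene map must have two tab-separated columns")
  stats::setNames(df[[2L]], df[[1L]])
}
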