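# Code-built alignment fixtures: every BAM used by the tests is generated
# here from plain SAM text, so the suite ships no binary data.

fixtureContigs <- c(c1 = 5000L)

# Single-exon plus-strand transcript: [100, 700), L = 600.
modelA <- function() TranscriptModel("mA", "c1", "+", 100L, 700L)

# Two-exon plus-strand transcript: [1000,1200) + [1500,1800), L = 500,
# junction offset 200, intron [1200,1500) of 300 nt.
modelB <- function() TranscriptModel("mB", "c1", "+",
                                     c(1000L, 1500L), c(1200L, 1800L))

# Two-exon minus-strand transcript: [2000,2100) + [2300,2400), L = 200,
# intron of 200 nt. Offset 0 is genomic position 2399.
modelC <- function() TranscriptModel("mC", "c1", "-",
                                     c(2000L, 2300L), c(2100L, 2400L))

.cigarReadLen <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  sum(n[grepl("[MI=X]$", ops)])
}

# One aligned read as a SAM line. pos is 1-based.
samRead <- function(qname, flag, chrom, pos, cigar, mapq = 60L,
                    rnext = "*", pnext = 0L, tlen = 0L) {
  n <- .cigarReadLen(cigar)
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen,
        strrep("A", n), strrep("I", n), sep = "\t")
}

# A proper pair (both mates plus-strand geometry: left mate forward).
samPair <- function(qname, chrom, pos1, cigar1, pos2, cigar2, mapq = 60L) {
  c(samRead(qname, 99L, chrom, pos1, cigar1, mapq, "=", pos2, 0L),
    samRead(qname, 147L, chrom, pos2, cigar2, mapq, "=", pos1, 0L))
}

# Write SAM records (character vector) to an indexed BAM; returns its path.
# Records are coordinate-sorted here so callers can list them in any order.
writeFixtureBam <- function(records, contigs = fixtureContigs,
                            dir = tempfile("fixbam")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (length(records)) {
    pos <- as.integer(vapply(strsplit(records, "\t", fixed = TRUE),
                             `[[`, "", 4L))
    chrom <- vapply(strsplit(records, "\t", fixed = TRUE), `[[`, "", 3L)
    records <- records[order(match(chrom, names(contigs)), pos)]
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  sam <- file.path(dir, "fix.sam")
  writeLines(c(header, records), sam)
  bam <- file.path(dir, "fix.bam")
  Rsamtools::asBam(sam, file.path(dir, "fix"), overwrite = TRUE,
                   indexDestination = TRUE)
  bam
}

# Read pairs that tile a transcript interval [s, e) (transcript coords)
# as abutting mates, depth `times`, via the package's own coordinate
# mapping (validated independently in test-gene-models.R).
tilePairs <- function(model, s, e, by = 50L, times = 1L, prefix = "t",
                      mapq = 60L) {
  recs <- character(0)
  k <- 0L
  for (rep in seq_len(times)) {
    starts <- seq(s, e - by, by = by)
    for (a in starts) {
      b <- min(a + by, e)
      mid <- a + (b - a) %/% 2L
      g1 <- .fixtureAln(model, a, mid)
      g2 <- .fixtureAln(model, mid, b)
      k <- k + 1L
      qn <- sprintf("%s%05d", prefix, k)
      left <- if (g1$pos <= g2$pos) g1 else g2
      right <- if (g1$pos <= g2$pos) g2 else g1
      recs <- c(recs,
        samRead(qn, 99L, txChrom(model), left$pos, left$cigar, mapq,
                "=", right$pos, 0L),
        samRead(qn, 147L, txChrom(model), right$pos, right$cigar, mapq,
                "=", left$pos, 0L))
    }
  }
  recs
}

# Genomic 1-based pos + CIGAR (with N gaps) for transcript interval [s, e).
.fixtureAln <- function(model, s, e) {
  blocks <- TINseq:::.txIntervalToBlocks(model, s, e)
  cig <- character(0)
  for (i in seq_len(nrow(blocks))) {
    cig <- c(cig, paste0(blocks[i, "end"] - blocks[i, "start"], "M"))
    if (i < nrow(blocks))
      cig <- c(cig, paste0(blocks[i + 1L, "start"] - blocks[i, "end"], "N"))
  }
  list(pos = blocks[1L, "start"] + 1L, cigar = paste(cig, collapse = ""))
}
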