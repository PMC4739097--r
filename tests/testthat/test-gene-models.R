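test_that("TranscriptModel validity rejects malformed exon structures", {
  expect_error(TranscriptModel("t", "c1", "+", c(100L, 50L), c(200L, 80L)),
               "sorted|ascending|disjoint|overlap")
  expect_error(TranscriptModel("t", "c1", "+", c(100L, 150L), c(200L, 300L)),
               "sorted|ascending|disjoint|overlap")
  expect_error(TranscriptModel("t", "c1", "+", 100L, 100L))
  expect_error(TranscriptModel("t", "c1", "*", 100L, 200L))
})

test_that("accessors report the documented coordinates", {
  m <- modelB()
  expect_identical(txName(m), "mB")
  expect_identical(txChrom(m), "c1")
  expect_identical(txStrand(m), "+")
  expect_identical(txStart(m), 1000L)
  expect_identical(txEnd(m), 1800L)
  expect_identical(splicedLength(m), 500L)
  expect_identical(exonTable(m),
                   data.frame(start = c(1000L, 1500L), end = c(1200L, 1800L)))
})

test_that("junctionOffsets run 5' to 3' on both strands", {
  expect_identical(junctionOffsets(modelA()), integer(0))
  expect_identical(junctionOffsets(modelB()), 200L)
  # minus strand: first exon in transcript order is the genomically right
  # one, [2300, 2400) of width 100
  expect_identical(junctionOffsets(modelC()), 100L)
})

test_that("transcriptToGenome and genomeToTranscript are exact inverses", {
  for (m in list(modelA(), modelB(), modelC())) {
    offs <- seq(0L, splicedLength(m) - 1L)
    gpos <- transcriptToGenome(m, offs)
    expect_identical(genomeToTranscript(m, gpos), offs)
  }
  mB <- modelB()
  # junction: offset 199 is the last base of exon 1, 200 the first of exon 2
  expect_identical(transcriptToGenome(mB, c(0L, 199L, 200L, 499L)),
                   c(1000L, 1199L, 1500L, 1799L))
  mC <- modelC()
  # minus strand: offset 0 = txEnd - 1; offset 100 = first base of left exon
  expect_identical(transcriptToGenome(mC, c(0L, 99L, 100L, 199L)),
                   c(2399L, 2300L, 2099L, 2000L))
  # intronic / outside positions map to NA
  expect_identical(genomeToTranscript(mB, c(1300L, 50L, 1850L)),
                   rep(NA_integer_, 3))
  expect_error(transcriptToGenome(mB, 500L), "\\[0, splicedLength\\)")
  expect_error(transcriptToGenome(mB, -1L), "\\[0, splicedLength\\)")
})

test_that("threePrimeRegion selects the 3'-most spliced window", {
  mB <- modelB()
  r <- threePrimeRegion(mB, 100L)  # last 100 nt of exon 2
  expect_identical(GenomicRanges::start(r), 1701L)
  expect_identical(GenomicRanges::end(r), 1800L)
  r2 <- threePrimeRegion(mB, 400L) # spans the junction
  expect_identical(GenomicRanges::start(r2), c(1101L, 1501L))
  expect_identical(GenomicRanges::end(r2), c(1200L, 1800L))
  # larger than the transcript: capped at full length
  rAll <- threePrimeRegion(mB, 10000L)
  expect_identical(sum(GenomicRanges::width(rAll)), 500L)
  # minus strand: 3' end is genomically left
  mC <- modelC()
  r3 <- threePrimeRegion(mC, 50L)
  expect_identical(GenomicRanges::start(r3), 2001L)
  expect_identical(GenomicRanges::end(r3), 2050L)
  expect_error(threePrimeRegion(mB, 0L), ">= 1")
})

test_that("readBed12 parses exon structure and preserves order", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "# a comment",
    "track name=ignored",
    "c1\t1000\t1800\tmB\t0\t+\t1000\t1800\t0\t2\t200,300,\t0,500,",
    "",
    "c1\t2000\t2400\tmC\t0\t-\t2000\t2400\t0\t2\t100,100,\t0,300,"),
    bed)
  models <- readBed12(bed)
  expect_identical(names(models), c("mB", "mC"))
  expect_identical(exonTable(models$mB), exonTable(modelB()))
  expect_identical(exonTable(models$mC), exonTable(modelC()))
  expect_identical(txStrand(models$mC), "-")
})

test_that("readBed12 error messages name the offending line", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "c1\t100\t700\tok\t0\t+\t100\t700\t0\t1\t600,\t0,",
    "c1\t100\t700\tshort\t0\t+\t100\t700\t0\t1\t600,"),  # 11 fields
    bed)
  expect_error(readBed12(bed), "line 2")
  writeLines(
    "c1\t100\t700\tbadcount\t0\t+\t100\t700\t0\t2\t600,\t0,", bed)
  expect_error(readBed12(bed), "line 1.*badcount.*blockCount")
  writeLines(
    "c1\t100\t700\tbadspan\t0\t+\t100\t700\t0\t1\t500,\t0,", bed)
  expect_error(readBed12(bed), "badspan.*span")
  expect_error(readBed12(tempfile()), "not found")
})

test_that("readBed12 onError = 'skip' drops bad lines with a warning", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "c1\t100\t700\tok\t0\t+\t100\t700\t0\t1\t600,\t0,",
    "c1\tXX\t700\tbad\t0\t+\t100\t700\t0\t1\t600,\t0,",
    "c1\t2000\t2400\tok2\t0\t-\t2000\t2400\t0\t2\t100,100,\t0,300,"),
    bed)
  expect_warning(models <- readBed12(bed, onError = "skip"), "line 2")
  expect_identical(names(models), c("ok", "ok2"))
})

test_that("writeBed12 round-trips byte-identically through readBed12", {
  models <- list(mA = modelA(), mB = modelB(), mC = modelC())
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  writeBed12(models, f1)
  writeBed12(readBed12(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("readBed12 agrees with the rtracklayer import oracle", {
  skip_if_not_installed("rtracklayer")
  bed <- tempfile(fileext = ".bed")
  writeBed12(list(modelB(), modelC()), bed)
  ours <- readBed12(bed)
  theirs <- rtracklayer::import(bed, format = "bed")
  expect_identical(length(theirs), 2L)
  for (i in 1:2) {
    blk <- theirs$blocks[[i]]  # block ranges relative to chromStart, 1-based
    ex <- exonTable(ours[[i]])
    expect_identical(GenomicRanges::start(theirs)[i] - 1L +
                       IRanges::start(blk) - 1L, ex$start)
    expect_identical(GenomicRanges::start(theirs)[i] - 1L +
                       IRanges::end(blk), ex$end)
  }
})

test_that("longestIsoformPerGene keeps the longest, ties lexicographic", {
  g1a <- TranscriptModel("g1.t2", "c1", "+", 0L, 500L)
  g1b <- TranscriptModel("g1.t1", "c1", "+", 0L, 300L)
  g2a <- TranscriptModel("g2.tB", "c1", "+", 0L, 400L)
  g2b <- TranscriptModel("g2.tA", "c1", "+", 600L, 1000L)  # tie on length
  models <- list(g1a, g1b, g2a, g2b)
  # separator mode
  kept <- longestIsoformPerGene(models, separator = ".")
  expect_identical(vapply(kept, txName, ""), c("g1.t2", "g2.tA"))
  # explicit map
  map <- c(g1.t2 = "G1", g1.t1 = "G1", g2.tB = "G2", g2.tA = "G2")
  kept2 <- longestIsoformPerGene(models, geneOf = map)
  expect_identical(vapply(kept2, txName, ""), c("g1.t2", "g2.tA"))
  expect_error(longestIsoformPerGene(models, geneOf = map[1:2]),
               "no gene mapping")
  # default: every transcript its own gene
  expect_identical(longestIsoformPerGene(models), models)
})

test_that("readGeneMap reads transcript-to-gene pairs", {
  f <- tempfile()
  writeLines(c("tx1\tgA", "tx2\tgA", "tx3\tgB"), f)
  map <- readGeneMap(f)
  expect_identical(map, c(tx1 = "gA", tx2 = "gA", tx3 = "gB"))
})
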