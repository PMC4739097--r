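# Small configurations keep these tests fast; the full-size study lives in
# test-acceptance.R.
smallConfig <- function(...) {
  args <- list(nGenes = 12L, nReadPairs = 4000L, seed = 7L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

test_that("simConfig validates its parameters", {
  expect_error(simConfig(lambda = -1), "lambda")
  expect_error(simConfig(nGenes = 0L), "nGenes")
  expect_error(simConfig(fragMean = 0), "fragment")
  expect_error(simConfig(exonCountRange = c(5L, 2L)), "exonCountRange")
  expect_silent(methods::validObject(simConfig()))
})

test_that("expectedSurvival follows the memoryless decay law", {
  expect_equal(expectedSurvival(c(0, 50, 99), 100, 0), rep(1, 3))
  lam <- 2e-3; L <- 1000
  offs <- c(0, 500, 999)
  expect_equal(expectedSurvival(offs, L, lam), exp(-lam * (L - 1 - offs)))
  # 3' terminal base always survives
  expect_equal(expectedSurvival(L - 1, L, 5e-2), 1)
  # survival increases towards the 3' end
  s <- expectedSurvival(0:(L - 1), L, lam)
  expect_false(is.unsorted(s))
})

test_that("simulateLibrary writes a consistent BED/BAM/truth trio", {
  dir <- tempfile("simlib")
  lib <- simulateLibrary(smallConfig(), dir)
  expect_true(file.exists(lib$bed))
  expect_true(file.exists(lib$bam))
  expect_true(file.exists(paste0(lib$bam, ".bai")))
  expect_true(file.exists(lib$truth))
  models <- readBed12(lib$bed)
  expect_length(models, 12L)
  tr <- lib$truthTable
  expect_identical(tr$transcript, unname(vapply(models, txName, "")))
  expect_identical(tr$splicedLength,
                   unname(vapply(models, splicedLength, integer(1))))
  expect_true(all(tr$expectedRetainedFraction == 1))  # lambda = 0
  expect_identical(sum(tr$nPairs), lib$nPairsEmitted)
  expect_lte(lib$nPairsEmitted, 4000L)
  # BAM agrees with the truth pair counts
  expect_identical(
    Rsamtools::countBam(lib$bam)$records, 2L * lib$nPairsEmitted)
})

test_that("identical seeds give byte-identical libraries", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  l1 <- simulateLibrary(smallConfig(), d1)
  l2 <- simulateLibrary(smallConfig(), d2)
  l3 <- simulateLibrary(smallConfig(seed = 8L), d3)
  expect_identical(unname(tools::md5sum(l1$bam)), unname(tools::md5sum(l2$bam)))
  expect_identical(readLines(l1$bed), readLines(l2$bed))
  expect_identical(readLines(l1$truth), readLines(l2$truth))
  expect_false(unname(tools::md5sum(l1$bam)) == unname(tools::md5sum(l3$bam)))
})

test_that("simulateLibrary leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulateLibrary(smallConfig(), tempfile()))
  expect_identical(.Random.seed, before)
})

test_that("every emitted alignment lies within its transcript's exons", {
  lib <- simulateLibrary(smallConfig(lambda = 1e-3), tempfile())
  models <- readBed12(lib$bed)
  galn <- GenomicAlignments::readGAlignments(lib$bam)
  blocks <- unlist(GenomicAlignments::grglist(galn), use.names = FALSE)
  exons <- unlist(GenomicRanges::GRangesList(lapply(models, exonGRanges)),
                  use.names = FALSE)
  hit <- GenomicRanges::countOverlaps(blocks, exons, type = "within",
                                      ignore.strand = TRUE)
  expect_true(all(hit >= 1L))
})

test_that("lambda = 0 coverage is flat and fragment sizes are on target", {
  lib <- simulateLibrary(simConfig(nGenes = 6L, nReadPairs = 20000L,
                                   seed = 21L), tempfile())
  models <- readBed12(lib$bed)
  ss <- sampleFragmentSize(lib$bam, models, keepSizes = TRUE)
  se <- sd(ss$sizes) / sqrt(ss$nPairs)
  expect_lt(abs(ss$meanSize - 250), 4 * se + 0.5)
  tt <- transcriptTIN(lib$bam, models)
  expect_gt(medTin(tt)$medTin, 90)
})

test_that("degradation skews coverage 3' and shortens fragments", {
  intact <- simulateLibrary(simConfig(nGenes = 10L, nReadPairs = 15000L,
                                      seed = 31L), tempfile())
  degraded <- simulateLibrary(simConfig(nGenes = 10L, nReadPairs = 15000L,
                                        seed = 31L, lambda = 3e-3),
                              tempfile())
  models <- readBed12(intact$bed)
  modelsD <- readBed12(degraded$bed)
  skewI <- profileSkew(geneBodyProfile(intact$bam, models))
  skewD <- profileSkew(geneBodyProfile(degraded$bam, modelsD))
  expect_gt(skewD, skewI)
  medI <- medTin(transcriptTIN(intact$bam, models))$medTin
  medD <- medTin(transcriptTIN(degraded$bam, modelsD))$medTin
  expect_gt(medI, medD)
  fI <- sampleFragmentSize(intact$bam, models)$meanSize
  fD <- sampleFragmentSize(degraded$bam, modelsD)$meanSize
  expect_gt(fI, fD)
  # truth table reflects the analytic retained fraction
  tr <- degraded$truthTable
  expect_equal(tr$expectedRetainedFraction,
               (1 - exp(-3e-3 * tr$splicedLength)) / (3e-3 * tr$splicedLength),
               tolerance = 1e-12)
})

test_that("the realized survival matches expectedSurvival", {
  lib <- simulateLibrary(simConfig(nGenes = 8L, nReadPairs = 30000L,
                                   seed = 41L, lambda = 2e-3),
                         tempfile(), keepSurvival = TRUE)
  surv <- lib$survival
  expect_true(is.matrix(surv))
  expect_identical(rownames(surv), lib$truthTable$transcript)
  tr <- lib$truthTable
  ok <- which(tr$nPairs >= 500L)
  expect_gte(length(ok), 3L)
  for (i in ok) {
    L <- tr$splicedLength[i]
    at <- round(seq(0, L - 1, length.out = 10L))
    expected <- expectedSurvival(at, L, 2e-3)
    # realized (pair-weighted) survival tracks the analytic per-base law:
    # rising towards the 3' end, complete at the 3' terminus
    expect_false(is.unsorted(surv[i, ]))
    expect_gte(surv[i, 10L], 0.99)
    expect_gt(cor(surv[i, ], expected), 0.9)
  }
})
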