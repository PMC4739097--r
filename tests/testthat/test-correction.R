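test_that("loessCorrect removes a synthetic count-TIN trend", {
  set.seed(11)
  n <- 300
  tin <- runif(n, 20, 95)
  y <- 6 + 0.05 * tin + rnorm(n, 0, 0.4)
  counts <- round(2 ^ y - 1)
  res <- loessCorrect(counts, tin)
  expect_gt(res$diagnostics$rPre, 0.5)
  expect_lt(abs(res$diagnostics$rPost), 0.1)
  # the sample median of log2(count + 1) is preserved
  inFit <- res$inFit
  expect_equal(median(res$logCorrected[inFit]),
               median(log2(counts + 1)[inFit]), tolerance = 1e-9)
  expect_true(all(res$corrected >= 0))
  expect_identical(res$diagnostics$nFit, sum(inFit))
})

test_that("genes with zero count or TIN 0 pass through unchanged", {
  set.seed(12)
  tin <- c(runif(100, 30, 90), 0, 50)
  counts <- c(round(runif(100, 10, 1000)), 400, 0)
  res <- loessCorrect(counts, tin)
  expect_false(res$inFit[101])             # TIN 0
  expect_false(res$inFit[102])             # count 0
  expect_identical(res$corrected[101], 400)
  expect_identical(res$corrected[102], 0)
  expect_true(is.na(res$fitted[101]))
})

test_that("loessCorrect validates input and degenerate TIN", {
  expect_error(loessCorrect(c(-1, 2, 3), c(10, 20, 30)), "non-negative")
  expect_error(loessCorrect(1:50, runif(50, 10, 90), span = 0), "span")
  expect_error(loessCorrect(1:10, runif(10, 10, 90)), "at least")
  set.seed(13)
  counts <- round(runif(50, 10, 100))
  expect_warning(res <- loessCorrect(counts, rep(80, 50)), "constant")
  expect_identical(res$corrected, counts)
})

test_that("integerize returns integer-valued corrected counts", {
  set.seed(14)
  tin <- runif(60, 20, 90)
  counts <- round(2 ^ (5 + 0.04 * tin + rnorm(60, 0, 0.3)))
  res <- loessCorrect(counts, tin, integerize = TRUE)
  expect_true(all(res$corrected == round(res$corrected)))
})

test_that("correctCounts applies the correction per sample column", {
  set.seed(15)
  n <- 100
  tin <- cbind(s1 = runif(n, 20, 90), s2 = runif(n, 20, 90))
  counts <- round(2 ^ (5 + 0.05 * tin + rnorm(2 * n, 0, 0.3)))
  rownames(counts) <- rownames(tin) <- sprintf("g%03d", 1:n)
  colnames(counts) <- colnames(tin)
  res <- correctCounts(counts, tin)
  expect_identical(dim(res$corrected), dim(counts))
  expect_identical(nrow(res$diagnostics), 2L)
  one <- loessCorrect(counts[, 1], tin[, 1])
  expect_equal(unname(res$corrected[, 1]), unname(one$corrected))
  expect_error(correctCounts(counts, tin[1:50, ]), "dimensions")
  bad <- tin; rownames(bad) <- rev(rownames(tin))
  expect_error(correctCounts(counts, bad), "ordering")
})

test_that("threePrimeTagCount counts reads touching the 3' window", {
  mB <- modelB()   # L = 500
  # 5 pairs at the 3' terminus ([400, 500)), 5 pairs at the 5' end ([0, 100))
  recs <- c(tilePairs(mB, 400L, 500L, by = 100L, times = 5L, prefix = "e"),
            tilePairs(mB, 0L, 100L, by = 100L, times = 5L, prefix = "s"))
  bam <- writeFixtureBam(recs)
  # window 100: only the ten 3' mates (2 reads per pair)
  expect_identical(threePrimeTagCount(bam, mB, N = 100L), 10L)
  # window 250: unchanged (no reads in (250, 100] zone from the 3' end)
  expect_identical(threePrimeTagCount(bam, mB, N = 250L), 10L)
  # window 450 covers offsets [50, 500): the 5' pairs' second mates
  # ([50, 100)) overlap it, their first mates ([0, 50)) do not
  expect_identical(threePrimeTagCount(bam, mB, N = 450L), 15L)
  # N above the transcript length is capped, not an error
  expect_identical(threePrimeTagCount(bam, mB, N = 5000L), 20L)
  # absent contig -> 0
  expect_identical(
    threePrimeTagCount(bam, TranscriptModel("x", "nope", "+", 0L, 100L)), 0L)
})

test_that("threePrimeTagCount is monotone in N and junction-aware", {
  mC <- modelC()   # minus strand, 3' end genomically left
  recs <- tilePairs(mC, 0L, 200L, by = 50L, times = 3L)
  bam <- writeFixtureBam(recs)
  counts <- vapply(c(10L, 60L, 110L, 160L, 200L), function(N)
    threePrimeTagCount(bam, mC, N = N), integer(1))
  expect_false(is.unsorted(counts))
  expect_identical(counts[[5]], 24L)   # all 12 pairs = 24 reads
  # a read that straddles the junction counts once even if the window
  # contains it in two blocks
  one <- samPair("j1", "c1", 2081L, "20M200N20M", 2341L, "20M")
  bamJ <- writeFixtureBam(one)
  # window of 150 tx nt covers [2000,2100) and [2300,2350): both mates hit
  expect_identical(threePrimeTagCount(bamJ, mC, N = 150L), 2L)
})
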