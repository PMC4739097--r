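#' SimConfig: parameters of the degraded-library simulator
#'
#' Describes a synthetic transcriptome and sequencing experiment: gene and
#' exon structure distributions, a log-normal expression profile, a
#' degradation process of intensity \code{lambda} (cut events per
#' nucleotide laid down as a Poisson process along each molecule), optional
#' oligo-dT (3'-anchored) selection, fragmentation to a Gaussian
#' fragment-length target, and paired-end read emission. Under oligo-dT
#' only the piece carrying the polyA terminus survives selection, so the
#' retained 3'-anchored piece has Exponential(lambda) length (capped at the
#' transcript length): longer transcripts lose a larger fraction, which is
#' what makes them more degradation-susceptible.
#'
#' @slot nGenes number of genes (one transcript each, one contig each).
#' @slot exonCountRange integer length-2: exons per transcript sampled
#'   uniformly from this range.
#' @slot exonMeanlog,exonSdlog,minExonLength log-normal exon length
#'   parameters (nucleotides) and lower clamp.
#' @slot intronMeanlog,intronSdlog,minIntronLength same for introns.
#' @slot exprMeanlog,exprSdlog log-normal expression weight parameters.
#' @slot lambda degradation intensity, cuts per nucleotide (>= 0; 0 = intact
#'   RNA).
#' @slot oligoDt if TRUE (default) only the 3'-anchored piece of each
#'   degraded molecule is sequenced, as under polyA selection; if FALSE the
#'   piece on either side of the cut is retained with equal probability.
#' @slot fragMean,fragSd fragment length target (nucleotides). Fragments
#'   shorter than \code{fragMean / 2} are removed by size selection; each
#'   surviving fragment is emitted as two abutting mates that jointly span
#'   it exactly (the merged/adapter-trimmed pair idealization), so read
#'   coverage equals fragment coverage and an intact molecule is covered
#'   end to end with no mate-overlap or mid-fragment gap artifacts.
#' @slot nReadPairs read pairs to attempt (accepted pairs can be fewer when
#'   molecules degrade below the sequenceable size).
#' @slot seed RNG seed; a fixed seed makes the output byte-identical.
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer", exonCountRange = "integer",
    exonMeanlog = "numeric", exonSdlog = "numeric",
    minExonLength = "integer",
    intronMeanlog = "numeric", intronSdlog = "numeric",
    minIntronLength = "integer",
    exprMeanlog = "numeric", exprSdlog = "numeric",
    lambda = "numeric", oligoDt = "logical",
    fragMean = "numeric", fragSd = "numeric",
    nReadPairs = "integer", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "'nGenes' must be >= 1")
  if (length(object@exonCountRange) != 2L ||
      any(object@exonCountRange < 1L) ||
      object@exonCountRange[1L] > object@exonCountRange[2L])
    msg <- c(msg, "'exonCountRange' must be an increasing pair of positive integers")
  if (object@lambda < 0) msg <- c(msg, "'lambda' must be >= 0")
  if (object@fragMean <= 0 || object@fragSd < 0)
    msg <- c(msg, "fragment length parameters must be positive")
  if (object@nReadPairs < 1L) msg <- c(msg, "'nReadPairs' must be >= 1")
  if (object@minExonLength < 1L || object@minIntronLength < 1L)
    msg <- c(msg, "length clamps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig constructor with defaults emulating a compact
#'   mammalian mRNA-seq library: multi-exon transcripts around 1-2 kb
#'   spliced, 250 +/- 50 nt fragments emitted as pairs of abutting mates.
#' @param nGenes,exonCountRange,exonMeanlog,exonSdlog,minExonLength see slots.
#' @param intronMeanlog,intronSdlog,minIntronLength see slots.
#' @param exprMeanlog,exprSdlog,lambda,oligoDt,fragMean,fragSd see slots.
#' @param nReadPairs,seed see slots.
#' @export
simConfig <- function(nGenes = 200L, exonCountRange = c(3L, 12L),
                      exonMeanlog = log(200), exonSdlog = 0.5,
                      minExonLength = 80L,
                      intronMeanlog = log(800), intronSdlog = 0.7,
                      minIntronLength = 60L,
                      exprMeanlog = 0, exprSdlog = 1,
                      lambda = 0, oligoDt = TRUE,
                      fragMean = 250, fragSd = 50,
                      nReadPairs = 200000L, seed = 1L) {
  methods::new("SimConfig", nGenes = as.integer(nGenes),
    exonCountRange = as.integer(exonCountRange),
    exonMeanlog = exonMeanlog, exonSdlog = exonSdlog,
    minExonLength = as.integer(minExonLength),
    intronMeanlog = intronMeanlog, intronSdlog = intronSdlog,
    minIntronLength = as.integer(minIntronLength),
    exprMeanlog = exprMeanlog, exprSdlog = exprSdlog,
    lambda = lambda, oligoDt = isTRUE(oligoDt),
    fragMean = fragMean, fragSd = fragSd,
    nReadPairs = as.integer(nReadPairs), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nGenes, " genes, lambda = ", object@lambda,
      " cuts/nt, oligo-dT = ", object@oligoDt, ", fragments ",
      object@fragMean, " +/- ", object@fragSd, " nt, ", object@nReadPairs,
      " read pairs, seed ", object@seed, "\n", sep = "")
})

#' Expected per-base survival under degradation with oligo-dT selection
#'
#' Probability that transcript position x (0-based, from the 5' end) of an
#' L-nt molecule is retained in the sequenced 3'-anchored piece: no cut may
#' fall between x and the 3' terminus, so P = exp(-lambda * (L - 1 - x)).
#' With lambda = 0 every base survives.
#'
#' @param offsets transcript offsets from the 5' end.
#' @param length spliced transcript length L.
#' @param lambda decay intensity (cuts per nucleotide).
#' @export
expectedSurvival <- function(offsets, length, lambda) {
  if (lambda == 0) rep(1, base::length(offsets))
  else exp(-lambda * (length - 1 - offsets))
}

## expected retained length fraction of an L-nt molecule:
## E[min(Exp(lambda), L)] / L
.expectedRetainedFraction <- function(L, lambda) {
  if (lambda == 0) rep(1, length(L))
  else (1 - exp(-lambda * L)) / (lambda * L)
}

## run expr with the simulator's own RNG stream, restoring global state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

## Build nGenes transcript models, one per contig. Returns list(models,
## contigLengths (named), weights).
.simTranscriptome <- function(config) {
  models <- vector("list", config@nGenes)
  contigLen <- integer(config@nGenes)
  contigs <- sprintf("sim%04d", seq_len(config@nGenes))
  for (i in seq_len(config@nGenes)) {
    nEx <- sample(seq(config@exonCountRange[1L], config@exonCountRange[2L]),
                  1L)
    exLen <- pmax(config@minExonLength,
                  as.integer(round(stats::rlnorm(nEx, config@exonMeanlog,
                                                 config@exonSdlog))))
    inLen <- if (nEx > 1L)
      pmax(config@minIntronLength,
           as.integer(round(stats::rlnorm(nEx - 1L, config@intronMeanlog,
                                          config@intronSdlog))))
      else integer(0)
    starts <- integer(nEx); ends <- integer(nEx)
    pos <- 100L
    for (e in seq_len(nEx)) {
      starts[e] <- pos; ends[e] <- pos + exLen[e]
      pos <- ends[e] + if (e < nEx) inLen[e] else 0L
    }
    strand <- sample(c("+", "-"), 1L)
    models[[i]] <- TranscriptModel(sprintf("tx%04d", i), contigs[i], strand,
                                   starts, ends)
    contigLen[i] <- ends[nEx] + 100L
  }
  weights <- stats::rlnorm(config@nGenes, config@exprMeanlog,
                           config@exprSdlog)
  list(models = models, contigLengths = stats::setNames(contigLen, contigs),
       weights = weights / sum(weights))
}

## Stationary residual of the fragment-length law: the distance from an
## arbitrary origin to the next breakpoint of a stationary renewal process
## with interval distribution max(minLen, round(Normal(mu, sigma))).
## Sampled as U * X~ with X~ size-biased (density x f(x) / mu), by
## rejection against f with acceptance probability x / cap.
.rResidualLength <- function(n, mu, sigma, minLen) {
  if (n == 0L) return(integer(0))
  cap <- mu + 8 * max(sigma, 1)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 2.5) + 8L
    x <- pmax(minLen, round(stats::rnorm(m, mu, sigma)))
    x <- x[stats::runif(m) < x / cap]
    out <- c(out, stats::runif(length(x)) * x)
  }
  as.integer(round(out[seq_len(n)]))
}

## Fragment all molecules of one batch by a complete partition of each
## retained piece [0, R). Breakpoints form a stationary renewal process:
## the first cut falls at a residual-distributed distance from the piece
## start and subsequent cut spacings are drawn from the configured Normal,
## clamped below at minLen (the lower size-selection bound). Both terminal
## remainders obey the same rule: a remainder of at least minLen is
## sequenced as its own fragment; a shorter one is absorbed into one
## randomly chosen fragment of the same molecule. Molecule ends are thus
## not breakpoint-privileged, per-molecule coverage is exactly uniform
## (complete partition), and by stationarity E[#cuts in (0, R)] = R / mu
## exactly, so the pooled emitted fragment-length mean is unbiased for
## fragMean at every R (minLen = fragMean / 2 balances the stub
## probability against the residual mean). Returns data.frame(mol, a, b):
## 0-based half-open fragment intervals within each piece.
.tileMolecules <- function(R, fragMean, fragSd, minLen) {
  n <- length(R)
  ok <- R >= minLen
  molL <- list(); lenL <- list()
  absMol <- integer(0); absRem <- numeric(0)
  ## stationary phase: distance from the piece start to the first cut
  first <- pmin(.rResidualLength(n, fragMean, fragSd, minLen), R)
  lead <- ok & first >= minLen
  molL[[1L]] <- which(lead)
  lenL[[1L]] <- first[lead]
  pend <- ok & first > 0 & first < minLen
  absMol <- which(pend); absRem <- first[pend]
  cur <- as.numeric(first)
  active <- ok & cur < R
  round <- 1L
  while (any(active)) {
    round <- round + 1L
    idx <- which(active)
    l <- pmax(minLen, round(stats::rnorm(length(idx), fragMean, fragSd)))
    rem <- R[idx] - cur[idx]
    fin <- l >= rem
    stub <- fin & rem >= minLen
    molL[[round]] <- c(idx[!fin], idx[stub])
    lenL[[round]] <- c(l[!fin], rem[stub])
    absorb <- fin & rem > 0 & rem < minLen
    absMol <- c(absMol, idx[absorb])
    absRem <- c(absRem, rem[absorb])
    cur[idx[!fin]] <- cur[idx[!fin]] + l[!fin]
    active[idx[fin]] <- FALSE
  }
  mol <- unlist(molL, use.names = FALSE)
  len <- unlist(lenL, use.names = FALSE)
  ## molecules that ended up with no emitted piece (both remainders short)
  ## are sequenced whole; their pending absorbs are dropped
  k <- tabulate(mol, n)
  orphan <- which(ok & k == 0L)
  if (length(orphan)) {
    mol <- c(mol, orphan)
    len <- c(len, R[orphan])
    k[orphan] <- 1L
    keep <- !(absMol %in% orphan)
    absMol <- absMol[keep]; absRem <- absRem[keep]
  }
  if (!length(mol))
    return(data.frame(mol = integer(0), a = integer(0), b = integer(0)))
  ord <- order(mol)            # stable: keeps sequential order per molecule
  mol <- mol[ord]; len <- len[ord]
  firstIdx <- cumsum(k) - k + 1L
  if (length(absMol)) {
    pick <- firstIdx[absMol] +
      floor(stats::runif(length(absMol)) * k[absMol])
    agg <- rowsum(absRem, pick)          # a piece can absorb both remainders
    tgt <- as.integer(rownames(agg))
    len[tgt] <- len[tgt] + agg[, 1L]
  }
  cs <- cumsum(len)
  base <- cs - len
  offs <- numeric(n)
  u <- which(k > 0L)
  offs[u] <- base[firstIdx[u]]
  a <- base - offs[mol]
  data.frame(mol = mol, a = as.integer(a), b = as.integer(a + len))
}

## Draw accepted fragments: data.frame(tx, fs, fe, rs) in 0-based half-open
## transcript coordinates (rs = start of the retained piece, kept for the
## realized survival diagnostics).
.simFragments <- function(config, lengths, weights) {
  target <- config@nReadPairs
  minLen <- max(2L, as.integer(config@fragMean %/% 2L))
  ## batch sizing: expected fragments per molecule
  meanL <- sum(weights * lengths)
  meanKeep <- if (config@lambda > 0)
    min(1 / config@lambda, meanL) else meanL
  epm <- max(0.25, meanKeep / config@fragMean)
  acc <- list(); total <- 0L; tries <- 0L
  while (total < target && tries < 100L) {
    tries <- tries + 1L
    nMol <- ceiling((target - total) / epm * 1.1) + 10L
    tx <- sample.int(length(lengths), nMol, replace = TRUE, prob = weights)
    L <- lengths[tx]
    ## length of the 3'-anchored piece delimited by the most-3' cut
    keep <- if (config@lambda > 0)
      pmin(pmax(1, ceiling(stats::rexp(nMol, config@lambda))), L) else L
    if (config@oligoDt) {
      rs <- L - keep; re <- L
    } else {
      ## no polyA selection: either side of the most-3' cut is sequenceable
      side <- stats::runif(nMol) < 0.5
      rs <- ifelse(side, L - keep, 0)
      re <- ifelse(side, L, L - keep)
    }
    R <- re - rs
    tiles <- .tileMolecules(R, config@fragMean, config@fragSd, minLen)
    if (nrow(tiles)) {
      acc[[tries]] <- data.frame(tx = tx[tiles$mol],
                                 fs = as.integer(rs[tiles$mol] + tiles$a),
                                 fe = as.integer(rs[tiles$mol] + tiles$b),
                                 rs = as.integer(rs[tiles$mol]))
      total <- total + nrow(tiles)
      epm <- max(epm, nrow(tiles) / nMol)
    }
  }
  if (total == 0L)
    stop("no retained fragments: lambda = ", config@lambda,
         " and fragMean = ", config@fragMean,
         " leave nothing sequenceable")
  frags <- do.call(rbind, acc)
  if (nrow(frags) > target)
    frags <- frags[sort(sample.int(nrow(frags), target)), , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

## CIGAR + 1-based POS for transcript intervals [s, e) on one model.
## Returns data.frame(pos, end, cigar) in genomic coordinates.
.intervalAlignments <- function(model, s, e) {
  L <- splicedLength(model)
  if (model@strand == "-") { tmp <- s; s <- L - e; e <- L - tmp }
  cw <- .cumWidths(model)
  es <- IRanges::start(model@exons)
  i1 <- findInterval(s, cw)
  i2 <- findInterval(e - 1, cw)
  pos <- es[i1] + (s - cw[i1]) + 1L          # 1-based genomic start
  gend <- es[i2] + (e - 1 - cw[i2]) + 1L     # 1-based genomic last base
  cigar <- character(length(s))
  single <- i1 == i2
  cigar[single] <- paste0(e[single] - s[single], "M")
  if (any(!single)) {
    intronW <- es[-1L] - (es[-length(es)] +
                          IRanges::width(model@exons)[-length(es)])
    idx <- which(!single)
    for (r in idx) {
      segs <- character(0)
      for (i in seq(i1[r], i2[r])) {
        mlen <- min(cw[i + 1L], e[r]) - max(cw[i], s[r])
        segs <- c(segs, paste0(mlen, "M"))
        if (i < i2[r]) segs <- c(segs, paste0(intronW[i], "N"))
      }
      cigar[r] <- paste(segs, collapse = "")
    }
  }
  data.frame(pos = as.integer(pos), end = as.integer(gend), cigar = cigar)
}

#' Simulate a degraded paired-end RNA-seq library
#'
#' Generates a synthetic transcriptome (one transcript per gene, one contig
#' per gene), applies 5'-to-3' degradation, optional oligo-dT selection,
#' fragmentation and size selection, and emits spliced-aware proper read
#' pairs directly as a coordinate-sorted, indexed BAM (no aligner involved,
#' so coverage truth is exact). A BED12 gene model and a per-transcript
#' ground-truth table accompany the alignments.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default "sim").
#' @param writeFasta also write the synthetic genome FASTA (random bases).
#' @param keepSurvival return the realized per-transcript mean survival
#'   (fraction of sequenced molecules whose retained piece includes each of
#'   10 equally spaced transcript positions); costs memory, default FALSE.
#' @return a list with \code{bed}, \code{bam}, \code{truth} (file paths),
#'   \code{models}, \code{truthTable} (data.frame: transcript, chrom,
#'   strand, splicedLength, expressionWeight, lambda,
#'   expectedRetainedFraction, nPairs), \code{nPairsEmitted}, and optionally
#'   \code{fasta}, \code{survival}.
#' @export
simulateLibrary <- function(config, dir, prefix = "sim", writeFasta = FALSE,
                            keepSurvival = FALSE) {
  methods::validObject(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .withSeed(config@seed, {
    txome <- .simTranscriptome(config)
    models <- txome$models
    lengths <- vapply(models, splicedLength, numeric(1))
    frags <- .simFragments(config, lengths, txome$weights)

    ## per-gene SAM record construction; each fragment becomes two abutting
    ## mates that split it at the midpoint
    recs <- vector("list", length(models))
    recContig <- vector("list", length(models))
    recPos <- vector("list", length(models))
    nPairsPerTx <- tabulate(frags$tx, length(models))
    pairId <- seq_len(nrow(frags))
    for (g in which(nPairsPerTx > 0L)) {
      m <- models[[g]]
      sel <- frags$tx == g
      f <- frags[sel, , drop = FALSE]
      mid <- f$fs + (f$fe - f$fs) %/% 2L
      a1 <- .intervalAlignments(m, f$fs, mid)            # 5' mate of fragment
      a2 <- .intervalAlignments(m, mid, f$fe)            # 3' mate
      w1 <- mid - f$fs; w2 <- f$fe - mid
      if (m@strand == "+") {
        ## first-in-pair is the genomically left, forward mate
        flag1 <- 99L; flag2 <- 147L
      } else {
        ## 5' of the mRNA is genomically right: swap so a1 = left mate,
        ## which is the forward second-in-pair read
        tmp <- a1; a1 <- a2; a2 <- tmp
        tmpw <- w1; w1 <- w2; w2 <- tmpw
        flag1 <- 163L; flag2 <- 83L
      }
      tlen <- pmax(a1$end, a2$end) - pmin(a1$pos, a2$pos) + 1L
      qn <- sprintf("p%07d", pairId[sel])
      recs[[g]] <- c(
        paste(qn, flag1, m@chrom, a1$pos, 60L, a1$cigar, "=", a2$pos,
              tlen, strrep("A", w1), strrep("I", w1), sep = "\t"),
        paste(qn, flag2, m@chrom, a2$pos, 60L, a2$cigar, "=", a1$pos,
              -tlen, strrep("A", w2), strrep("I", w2), sep = "\t"))
      recContig[[g]] <- rep(m@chrom, 2L * nrow(f))
      recPos[[g]] <- c(a1$pos, a2$pos)
    }
    sam <- unlist(recs, use.names = FALSE)
    contig <- unlist(recContig, use.names = FALSE)
    posn <- unlist(recPos, use.names = FALSE)
    ## coordinate sort: contig in header order, then POS
    ord <- order(match(contig, names(txome$contigLengths)), posn)
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(txome$contigLengths),
                        txome$contigLengths))
    samPath <- file.path(dir, paste0(prefix, ".sam"))
    writeLines(c(header, sam[ord]), samPath)
    bamPath <- file.path(dir, paste0(prefix, ".bam"))
    Rsamtools::asBam(samPath, sub("\\.bam$", "", bamPath), overwrite = TRUE,
                     indexDestination = TRUE)
    unlink(samPath)

    bedPath <- file.path(dir, paste0(prefix, ".bed"))
    writeBed12(models, bedPath)

    truth <- data.frame(
      transcript = vapply(models, txName, character(1)),
      chrom = vapply(models, txChrom, character(1)),
      strand = vapply(models, txStrand, character(1)),
      splicedLength = as.integer(lengths),
      expressionWeight = txome$weights,
      lambda = config@lambda,
      expectedRetainedFraction = .expectedRetainedFraction(lengths,
                                                           config@lambda),
      nPairs = nPairsPerTx)
    truthPath <- file.path(dir, paste0(prefix, ".truth.tsv"))
    writeTsv(truth, truthPath)

    out <- list(bed = bedPath, bam = bamPath, truth = truthPath,
                models = models, truthTable = truth,
                nPairsEmitted = nrow(frags))
    if (keepSurvival) {
      surv <- t(vapply(seq_along(models), function(g) {
        f <- frags[frags$tx == g, , drop = FALSE]
        if (!nrow(f)) return(rep(NA_real_, 10L))
        at <- round(seq(0, lengths[g] - 1, length.out = 10L))
        vapply(at, function(x) mean(f$rs <= x), numeric(1))
      }, numeric(10L)))
      rownames(surv) <- truth$transcript
      out$survival <- surv
    }
    if (writeFasta) {
      fa <- Biostrings::DNAStringSet(vapply(txome$contigLengths,
        function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = ""), character(1)))
      faPath <- file.path(dir, paste0(prefix, ".fa"))
      Biostrings::writeXStringSet(fa, faPath)
      out$fasta <- faPath
    }
    out
  })
}
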