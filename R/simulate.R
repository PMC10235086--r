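#' Simulation configuration for the synthetic mock/auxin experiment
#'
#' Bundles and validates every parameter of the synthetic fragment
#' generator. Defaults encode the study conditions the analysis assumes:
#' sixteen chromosomes with one 117 +/- 2 bp point-centromere core each,
#' 500 bp pericentromeric windows, 22 window-intersecting ORFs none closer
#' than 200 bp to a core, a 1:1 short:long centromeric mixture with
#' log-normal span lengths (medians 231 / 4458 nt), noncoding
#' pericentromeric spans (median 225 nt) at 390x the centromeric count,
#' coding pericentromeric fragments at 10x the noncoding count,
#' plus-strand dominance on 10 of 16 chromosomes, a 0.79 probability of
#' initiating outside the core, and depletion multipliers (net 2.3x
#' centromeric carried entirely by the short class, 1.9x noncoding
#' pericentromeric, 1.0x long centromeric and coding).
#'
#' @param seed base seed; replicate/condition streams are derived from it.
#' @param nChromosomes,chromosomeLength genome geometry.
#' @param coreWidthBand inclusive band core widths are drawn from.
#' @param windowBp pericentromeric window width (bp).
#' @param cde1Len,cde3Len CDE layout (bp).
#' @param nOrfs number of window-intersecting ORFs to place.
#' @param orfCoreClearanceBp minimum ORF distance from any core (bp).
#' @param scale multiplier applied to the published per-condition counts
#'   so Monte-Carlo error stays small at desk scale.
#' @param cenTotal,noncodingTotal published mock per-condition counts
#'   (scaled by \code{scale}).
#' @param codingMultiplier coding:noncoding pericentromeric count ratio.
#' @param backgroundFragments library-depth filler fragments per sample,
#'   placed outside all windows (the CPM denominator stands on these).
#' @param shortWeight mock short fraction of centromeric fragments.
#' @param shortCenMedian,shortCenSdlog,longCenMedian,longCenSdlog,
#'   pericenMedian,pericenSdlog,codingMedian,codingSdlog,
#'   backgroundMedian,backgroundSdlog log-normal span-length parameters
#'   (median in nt, sd on the log scale).
#' @param termCompMock,termCompAuxin termination-class compositions
#'   (FULL_CEN, CDEI, CDEII, CDEIII); renormalised to sum to one.
#' @param pericenInitP probability a centromeric fragment initiates
#'   outside the core.
#' @param plusDominantChromosomes number of chromosomes (taken in genome
#'   order) with plus-strand-dominant transcription.
#' @param plusBiasStrong,plusBiasWeak plus-strand probability on dominant
#'   and remaining chromosomes.
#' @param auxinCenFold net centromeric fold under depletion (carried by
#'   the short class), \code{auxinLongCenFold} the long-class fold.
#' @param auxinNoncodingFold,auxinCodingFold depletion folds for the
#'   pericentromeric classes.
#' @param replicates replicates per condition.
#' @param lengthThreshold SHORT/LONG boundary (nt).
#' @return a validated \code{SimulationConfig} (a classed list).
#' @export
simulationConfig <- function(seed = 1L,
                             nChromosomes = 16L,
                             chromosomeLength = 100000L,
                             coreWidthBand = c(115L, 119L),
                             windowBp = 500L,
                             cde1Len = 8L, cde3Len = 25L,
                             nOrfs = 22L,
                             orfCoreClearanceBp = 200L,
                             scale = 10,
                             cenTotal = 42,
                             noncodingTotal = 16369,
                             codingMultiplier = 10,
                             backgroundFragments = 1e6,
                             shortWeight = 0.5,
                             shortCenMedian = 231, shortCenSdlog = 0.45,
                             longCenMedian = 4458, longCenSdlog = 0.35,
                             pericenMedian = 225, pericenSdlog = 0.45,
                             codingMedian = 1250, codingSdlog = 0.4,
                             backgroundMedian = 300, backgroundSdlog = 0.5,
                             termCompMock = c(FULL_CEN = 0.48, CDEI = 0.12,
                                              CDEII = 0.24, CDEIII = 0.17),
                             termCompAuxin = c(FULL_CEN = 0.32, CDEI = 0.23,
                                               CDEII = 0.26, CDEIII = 0.19),
                             pericenInitP = 0.79,
                             plusDominantChromosomes = 10L,
                             plusBiasStrong = 0.7,
                             plusBiasWeak = 0.3,
                             auxinCenFold = 2.3,
                             auxinNoncodingFold = 1.9,
                             auxinLongCenFold = 1.0,
                             auxinCodingFold = 1.0,
                             replicates = 3L,
                             lengthThreshold = 1000L) {
  cfg <- as.list(environment())
  probs <- c(cfg$shortWeight, cfg$pericenInitP,
             cfg$plusBiasStrong, cfg$plusBiasWeak)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  for (nm in c("termCompMock", "termCompAuxin")) {
    comp <- cfg[[nm]]
    if (length(comp) != 4L ||
        !identical(names(comp), c("FULL_CEN", "CDEI", "CDEII", "CDEIII")) ||
        any(comp < 0) || sum(comp) == 0)
      stop("'", nm, "' must be a non-negative composition named ",
           "FULL_CEN, CDEI, CDEII, CDEIII", call. = FALSE)
    cfg[[nm]] <- comp / sum(comp)
  }
  medians <- c(cfg$shortCenMedian, cfg$longCenMedian, cfg$pericenMedian,
               cfg$codingMedian, cfg$backgroundMedian)
  if (any(medians <= 0)) stop("medians must be > 0", call. = FALSE)
  if (cfg$shortCenMedian >= cfg$lengthThreshold ||
      cfg$longCenMedian < cfg$lengthThreshold)
    stop("short/long medians must respect the length threshold",
         call. = FALSE)
  if (cfg$coreWidthBand[1] <= cfg$cde1Len + cfg$cde3Len)
    stop("core width band leaves no room for CDEII", call. = FALSE)
  if (cfg$chromosomeLength <
      4L * (cfg$windowBp + max(cfg$coreWidthBand)))
    stop("chromosome too short for the pericentromeric windows",
         call. = FALSE)
  if (cfg$windowBp <= cfg$orfCoreClearanceBp + 20L)
    stop("windowBp must exceed orfCoreClearanceBp by at least 20 bp so ",
         "ORFs can intersect the windows", call. = FALSE)
  if (cfg$plusDominantChromosomes > cfg$nChromosomes)
    stop("plusDominantChromosomes exceeds nChromosomes", call. = FALSE)
  if (cfg$auxinCenFold * 1 < (1 - cfg$shortWeight) * cfg$auxinLongCenFold)
    stop("auxin folds imply a negative short-class count", call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig: ", x$nChromosomes, " chromosomes x ",
      x$chromosomeLength, " bp, window ", x$windowBp, " bp\n", sep = "")
  cat("  mock per condition: CEN ", x$cenTotal * x$scale,
      ", noncoding periCEN ", round(x$noncodingTotal * x$scale),
      ", coding x", x$codingMultiplier,
      "; background/sample ", x$backgroundFragments, "\n", sep = "")
  cat("  auxin folds: CEN ", x$auxinCenFold, " (short-borne), noncoding ",
      x$auxinNoncodingFold, "\n", sep = "")
  invisible(x)
}

## evaluate expr under a given seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

.streamSeed <- function(seed, condition, replicate, stage = 0L) {
  as.integer(seed) + 7919L * as.integer(replicate) +
    104729L * (condition == "auxin") + 15485863L * as.integer(stage)
}

## truncated log-normal parameterised by median: meanlog = log(median)
.rlnormTrunc <- function(n, median, sdlog, lo = 2, hi = Inf) {
  x <- round(stats::rlnorm(n, meanlog = log(median), sdlog = sdlog))
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- round(stats::rlnorm(length(bad), meanlog = log(median),
                                  sdlog = sdlog))
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
    if (guard > 1000L)
      stop("length truncation band [", lo, ", ", hi,
           "] is incompatible with the configured median", call. = FALSE)
  }
  as.integer(x)
}

#' Simulate a genome model
#'
#' Places one CEN core per chromosome (widths drawn from the configured
#' band, positions near mid-chromosome), derives the CDE layout and
#' pericentromeric windows, and scatters the configured number of ORFs so
#' that each intersects a window while keeping the configured clearance
#' from every core (no coding feature within 200 bp of a core by
#' default).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed override for \code{config$seed}.
#' @return a \code{\link{CenGenomeModel}}.
#' @export
simulateGenome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(seed, {
    n <- config$nChromosomes
    L <- as.integer(config$chromosomeLength)
    chroms <- paste0("chr", utils::as.roman(seq_len(n)))
    seqinfo <- GenomeInfoDb::Seqinfo(chroms, seqlengths = rep(L, n))
    cw <- sample(seq(config$coreWidthBand[1], config$coreWidthBand[2]),
                 n, replace = TRUE)
    cs <- as.integer(floor(stats::runif(n, 0.4 * L, 0.6 * L)))
    cores <- GenomicRanges::GRanges(chroms,
               IRanges::IRanges(cs, width = cw), seqinfo = seqinfo)
    ## ORFs: one per sampled (chromosome, side) slot, intersecting the
    ## window but >= clearance bp away from the core
    W <- config$windowBp
    clr <- config$orfCoreClearanceBp
    nOrf <- config$nOrfs
    slots <- sample(2L * n, nOrf, replace = nOrf > 2L * n)
    slotChrom <- ((slots - 1L) %/% 2L) + 1L
    slotUp <- (slots %% 2L) == 1L
    orfLen <- sample(300:1500, nOrf, replace = TRUE)
    coreS <- cs[slotChrom]
    coreE <- cs[slotChrom] + cw[slotChrom] - 1L
    oS <- oE <- integer(nOrf)
    up <- which(slotUp)
    if (length(up)) {
      oE[up] <- as.integer(floor(stats::runif(length(up),
                 coreS[up] - W + 20L, coreS[up] - clr - 1L + 1L)))
      oS[up] <- pmax(1L, oE[up] - orfLen[up] + 1L)
    }
    dn <- which(!slotUp)
    if (length(dn)) {
      oS[dn] <- as.integer(floor(stats::runif(length(dn),
                 coreE[dn] + clr + 1L, coreE[dn] + W - 20L + 1L)))
      oE[dn] <- pmin(L, oS[dn] + orfLen[dn] - 1L)
    }
    orfs <- GenomicRanges::GRanges(chroms[slotChrom],
              IRanges::IRanges(oS, oE),
              strand = sample(c("+", "-"), nOrf, replace = TRUE),
              seqinfo = seqinfo)
    orfs$id <- sprintf("ORF%03d", seq_len(nOrf))
    CenGenomeModel(seqinfo, cores, orfs = orfs, windowBp = W,
                   cde1Len = config$cde1Len, cde3Len = config$cde3Len,
                   coreWidthBand = config$coreWidthBand)
  })
}

#' Expected per-condition class counts
#'
#' The mock condition carries the configured totals; under depletion the
#' long centromeric class scales by \code{auxinLongCenFold} while the
#' short class absorbs the remainder of the net \code{auxinCenFold}, the
#' noncoding pericentromeric class scales by \code{auxinNoncodingFold} and
#' the coding class by \code{auxinCodingFold}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param condition \code{"mock"} or \code{"auxin"}.
#' @return named numeric: shortCen, longCen, noncoding, coding.
#' @export
conditionClassCounts <- function(config, condition = c("mock", "auxin")) {
  condition <- match.arg(condition)
  cen <- config$cenTotal * config$scale
  nc <- config$noncodingTotal * config$scale
  shortCen <- config$shortWeight * cen
  longCen <- (1 - config$shortWeight) * cen
  coding <- config$codingMultiplier * nc
  if (condition == "auxin") {
    longCen <- longCen * config$auxinLongCenFold
    shortCen <- config$auxinCenFold * cen - longCen
    nc <- nc * config$auxinNoncodingFold
    coding <- coding * config$auxinCodingFold
  }
  c(shortCen = shortCen, longCen = longCen, noncoding = nc,
    coding = coding)
}

.coreGeom <- function(model) {
  cores <- cenCores(model)
  cdes <- cdeElements(model)
  chr <- as.character(GenomeInfoDb::seqnames(cores))
  list(chr = chr,
       cs = BiocGenerics::start(cores),
       ce = BiocGenerics::end(cores),
       c1e = BiocGenerics::end(cdes)[cdes$cde == "CDEI"],
       c2e = BiocGenerics::end(cdes)[cdes$cde == "CDEII"],
       L = as.integer(chromSizes(model)[chr]))
}

.plusProb <- function(config, chromIdx) {
  ifelse(chromIdx <= config$plusDominantChromosomes,
         config$plusBiasStrong, config$plusBiasWeak)
}

.runifInt <- function(lo, hi) {
  ## uniform integer in [lo, hi] elementwise; caller guarantees lo <= hi
  lo + as.integer(floor(stats::runif(length(lo)) * (hi - lo + 1)))
}

## centromeric fragments with prescribed termination class and initiation
## origin; placement solves the boundary constraints directly, lengths are
## redrawn when a draw cannot realise its case
.simCenBatch <- function(n, model, config, comp, median, sdlog, lenLo,
                         lenHi) {
  if (n == 0L) return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(cenCores(model))))
  g <- .coreGeom(model)
  nChr <- length(g$chr)
  ci <- sample.int(nChr, n, replace = TRUE)
  strand <- ifelse(stats::runif(n) < .plusProb(config, ci), "+", "-")
  term <- sample(names(comp), n, replace = TRUE, prob = comp)
  init <- stats::runif(n) < config$pericenInitP
  len <- .rlnormTrunc(n, median, sdlog, lenLo, lenHi)
  cs <- g$cs[ci]; ce <- g$ce[ci]; c1e <- g$c1e[ci]; c2e <- g$c2e[ci]
  L <- g$L[ci]
  cw <- ce - cs + 1L
  ## element boundaries on the reference strand
  xs <- ifelse(term == "CDEI", cs,
        ifelse(term == "CDEII", c1e + 1L, c2e + 1L))
  xe <- ifelse(term == "CDEI", c1e,
        ifelse(term == "CDEII", c2e, ce))
  fs <- fe <- integer(n)
  guard <- 0L
  todo <- seq_len(n)
  repeat {
    i <- todo
    full <- term[i] == "FULL_CEN"
    plus <- strand[i] == "+"
    lo <- hi <- integer(length(i))   # bounds for the free coordinate
    anchorIsEnd <- logical(length(i))

    sel <- full & init[i] & plus     # free: fs in [ce-len+1, cs-1]
    lo[sel] <- pmax(1L, (ce[i] - len[i] + 1L)[sel])
    hi[sel] <- pmin(cs[i] - 1L, L[i] - len[i] + 1L)[sel]
    sel <- full & !init[i] & plus    # fs = cs, needs len >= cw
    lo[sel] <- cs[i][sel]; hi[sel] <- cs[i][sel]
    hi[sel][len[i][sel] < cw[i][sel] |
              (cs[i] + len[i] - 1L > L[i])[sel]] <- -1L
    sel <- full & init[i] & !plus    # free: fe in [ce+1, cs+len-1]
    anchorIsEnd[sel] <- TRUE
    lo[sel] <- (ce[i] + 1L)[sel]
    hi[sel] <- pmin(L[i], cs[i] + len[i] - 1L)[sel]
    sel <- full & !init[i] & !plus   # fe = ce, needs len >= cw
    anchorIsEnd[sel] <- TRUE
    lo[sel] <- ce[i][sel]; hi[sel] <- ce[i][sel]
    hi[sel][len[i][sel] < cw[i][sel] |
              (ce[i] - len[i] + 1L < 1L)[sel]] <- -1L

    part <- !full
    ## element boundaries shrunk where they touch a core edge, so a
    ## partial fragment can never satisfy the FULL containment test
    xsIn <- pmax(xs[i], cs[i] + 1L)   # for a 3' start / 5' start boundary
    xeIn <- pmin(xe[i], ce[i] - 1L)   # for a 3' end / 5' end boundary
    ## + & initiated upstream: 3' end lands in the element
    sel <- part & init[i] & plus
    anchorIsEnd[sel] <- TRUE
    lo[sel] <- pmax(xs[i], len[i])[sel]
    hi[sel] <- pmin(xeIn, cs[i] + len[i] - 2L)[sel]
    ## + & initiated inside the core: 5' start in the element, runs past
    ## the core end (start must stay > core start to avoid FULL)
    sel <- part & !init[i] & plus
    lo[sel] <- pmax(xsIn, ce[i] + 2L - len[i])[sel]
    hi[sel] <- pmin(xe[i], L[i] - len[i] + 1L)[sel]
    ## - & initiated downstream: 3' start lands in the element
    sel <- part & init[i] & !plus
    lo[sel] <- pmax(xsIn, ce[i] + 2L - len[i])[sel]
    hi[sel] <- pmin(xe[i], L[i] - len[i] + 1L)[sel]
    ## - & initiated inside the core: 5' end in the element, runs past the
    ## core start (end must stay < core end to avoid FULL)
    sel <- part & !init[i] & !plus
    anchorIsEnd[sel] <- TRUE
    lo[sel] <- pmax(xs[i], len[i])[sel]
    hi[sel] <- pmin(xeIn, cs[i] + len[i] - 2L)[sel]

    ok <- lo <= hi
    if (any(ok)) {
      j <- i[ok]
      pos <- .runifInt(lo[ok], hi[ok])
      fs[j] <- ifelse(anchorIsEnd[ok], pos - len[j] + 1L, pos)
      fe[j] <- ifelse(anchorIsEnd[ok], pos, pos + len[j] - 1L)
    }
    todo <- i[!ok]
    if (!length(todo)) break
    guard <- guard + 1L
    if (guard > 200L)
      stop("infeasible centromeric composition: cannot realise ",
           "termination classes with the configured length distribution",
           call. = FALSE)
    len[todo] <- .rlnormTrunc(length(todo), median, sdlog, lenLo, lenHi)
  }
  gr <- GenomicRanges::GRanges(g$chr[ci], IRanges::IRanges(fs, fe),
          strand = strand, seqinfo = GenomeInfoDb::seqinfo(cenCores(model)))
  ## self-consistency: placement must realise the drawn annotation exactly
  chk <- classifyFragments(gr, model,
                           lengthThreshold = config$lengthThreshold)
  if (!all(chk$tclass == "CEN") || !identical(chk$termClass, term) ||
      !identical(as.logical(chk$initiatedInPericen), as.logical(init)))
    stop("internal error: simulated centromeric fragment does not ",
         "re-classify to its intended annotation", call. = FALSE)
  gr
}

## noncoding pericentromeric fragments: overlap one window, never the
## core, never a window-intersecting ORF
.simPericenBatch <- function(n, model, config) {
  si <- GenomeInfoDb::seqinfo(cenCores(model))
  if (n == 0L) return(GenomicRanges::GRanges(seqinfo = si))
  g <- .coreGeom(model)
  W <- periWindowBp(model)
  orfs <- periOrfs(model)
  ci <- sample.int(length(g$chr), n, replace = TRUE)
  strand <- ifelse(stats::runif(n) < .plusProb(config, ci), "+", "-")
  up <- stats::runif(n) < 0.5
  len <- .rlnormTrunc(n, config$pericenMedian, config$pericenSdlog, 2)
  fs <- fe <- integer(n)
  todo <- seq_len(n)
  guard <- 0L
  repeat {
    i <- todo
    isUp <- up[i]
    cs <- g$cs[ci[i]]; ce <- g$ce[ci[i]]; L <- g$L[ci[i]]
    nfs <- nfe <- integer(length(i))
    nfe[isUp] <- .runifInt((cs - W)[isUp], (cs - 1L)[isUp])
    nfs[isUp] <- pmax(1L, (nfe - len[i] + 1L)[isUp])
    nfs[!isUp] <- .runifInt((ce + 1L)[!isUp], (ce + W)[!isUp])
    nfe[!isUp] <- pmin(L[!isUp], (nfs + len[i] - 1L)[!isUp])
    fs[i] <- nfs
    fe[i] <- nfe
    cand <- GenomicRanges::GRanges(g$chr[ci[i]],
              IRanges::IRanges(nfs, nfe), seqinfo = si)
    bad <- IRanges::overlapsAny(cand, orfs, ignore.strand = TRUE)
    todo <- i[bad]
    if (!length(todo)) break
    guard <- guard + 1L
    if (guard > 500L)
      stop("cannot place noncoding pericentromeric fragments clear of ",
           "ORFs; windows are saturated with coding features",
         call. = FALSE)
    ## a long ORF can make one (chromosome, side) slot infeasible for the
    ## drawn length, so reject the whole placement, not just the position
    ci[todo] <- sample.int(length(g$chr), length(todo), replace = TRUE)
    strand[todo] <- ifelse(
      stats::runif(length(todo)) < .plusProb(config, ci[todo]), "+", "-")
    up[todo] <- stats::runif(length(todo)) < 0.5
  }
  gr <- GenomicRanges::GRanges(g$chr[ci], IRanges::IRanges(fs, fe),
                               strand = strand, seqinfo = si)
  gr
}

## coding pericentromeric fragments: cover a position shared by an ORF and
## a window, never the core; strand follows the ORF
.simCodingBatch <- function(n, model, config) {
  si <- GenomeInfoDb::seqinfo(cenCores(model))
  if (n == 0L) return(GenomicRanges::GRanges(seqinfo = si))
  orfs <- periOrfs(model)
  if (!length(orfs))
    stop("model has no window-intersecting ORFs; cannot simulate coding ",
         "pericentromeric fragments", call. = FALSE)
  win <- periWindows(model)
  hits <- GenomicRanges::findOverlaps(orfs, win, ignore.strand = TRUE)
  ov <- IRanges::pintersect(orfs[S4Vectors::queryHits(hits)],
                            win[S4Vectors::subjectHits(hits)],
                            ignore.strand = TRUE)
  ovSide <- win$side[S4Vectors::subjectHits(hits)]
  g <- .coreGeom(model)
  pick <- sample.int(length(ov), n, replace = TRUE)
  chr <- as.character(GenomeInfoDb::seqnames(ov))[pick]
  ci <- match(chr, g$chr)
  isUp <- ovSide[pick] == "UP"
  strand <- as.character(BiocGenerics::strand(
    orfs[S4Vectors::queryHits(hits)]))[pick]
  len <- .rlnormTrunc(n, config$codingMedian, config$codingSdlog, 30)
  p <- .runifInt(BiocGenerics::start(ov)[pick], BiocGenerics::end(ov)[pick])
  fs <- fe <- integer(n)
  fe[isUp] <- .runifInt(p[isUp], pmin(p + len - 1L, g$cs[ci] - 1L)[isUp])
  fs[isUp] <- pmax(1L, (fe - len + 1L)[isUp])
  fs[!isUp] <- .runifInt(pmax(p - len + 1L, g$ce[ci] + 1L)[!isUp],
                         p[!isUp])
  fe[!isUp] <- pmin(g$L[ci], fs + len - 1L)[!isUp]
  GenomicRanges::GRanges(chr, IRanges::IRanges(fs, fe), strand = strand,
                         seqinfo = si)
}

## library-depth filler placed clear of every window
.simBackgroundBatch <- function(n, model, config) {
  si <- GenomeInfoDb::seqinfo(cenCores(model))
  if (n == 0L) return(GenomicRanges::GRanges(seqinfo = si))
  g <- .coreGeom(model)
  W <- periWindowBp(model)
  ci <- sample.int(length(g$chr), n, replace = TRUE)
  len <- .rlnormTrunc(n, config$backgroundMedian, config$backgroundSdlog,
                      30)
  leftHi <- g$cs[ci] - W - len - 1L       # fe stays left of the window
  rightLo <- g$ce[ci] + W + 1L
  rightHi <- g$L[ci] - len + 1L
  leftSize <- pmax(0L, leftHi)
  rightSize <- pmax(0L, rightHi - rightLo + 1L)
  pickLeft <- stats::runif(n) < leftSize / (leftSize + rightSize)
  fs <- integer(n)
  fs[pickLeft] <- .runifInt(rep(1L, sum(pickLeft)), leftHi[pickLeft])
  fs[!pickLeft] <- .runifInt(rightLo[!pickLeft], rightHi[!pickLeft])
  GenomicRanges::GRanges(g$chr[ci], IRanges::IRanges(fs, width = len),
    strand = sample(c("+", "-"), n, replace = TRUE), seqinfo = si)
}

#' Simulate one sample's fragments
#'
#' Draws per-class counts (Poisson around the per-replicate expectation
#' for the condition), realises each fragment so that re-classification
#' recovers the intended class, termination class and initiation origin
#' (verified internally), adds background filler outside all windows, and
#' returns the fragments together with the sample-sheet row carrying the
#' library total.
#'
#' @param model a \code{\link{CenGenomeModel}} (from
#'   \code{\link{simulateGenome}} with the same config).
#' @param config a \code{\link{simulationConfig}}.
#' @param condition \code{"mock"} or \code{"auxin"}.
#' @param replicate replicate index (drives the derived RNG stream, so
#'   replicates differ but runs reproduce).
#' @param seed override for \code{config$seed}.
#' @return list with \code{fragments} (GRanges, sorted, with
#'   \code{sample} metadata column) and \code{sheetRow} (data.frame).
#' @export
simulateFragments <- function(model, config,
                              condition = c("mock", "auxin"),
                              replicate = 1L, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  condition <- match.arg(condition)
  sampleName <- sprintf("%s_rep%d", condition, replicate)
  expect <- conditionClassCounts(config, condition) / config$replicates
  comp <- if (condition == "mock") config$termCompMock
          else config$termCompAuxin
  thr <- config$lengthThreshold
  gr <- .withSeed(.streamSeed(seed, condition, replicate), {
    nShort <- stats::rpois(1L, expect[["shortCen"]])
    nLong <- stats::rpois(1L, expect[["longCen"]])
    nNc <- stats::rpois(1L, expect[["noncoding"]])
    nCod <- stats::rpois(1L, expect[["coding"]])
    nBg <- if (config$backgroundFragments > 0)
      stats::rpois(1L, config$backgroundFragments) else 0L
    parts <- list(
      .simCenBatch(nShort, model, config, comp, config$shortCenMedian,
                   config$shortCenSdlog, 2, thr - 1L),
      .simCenBatch(nLong, model, config, comp, config$longCenMedian,
                   config$longCenSdlog, thr, Inf),
      .simPericenBatch(nNc, model, config),
      .simCodingBatch(nCod, model, config),
      .simBackgroundBatch(nBg, model, config)
    )
    intended <- c(rep("CEN", nShort + nLong),
                  rep("PERICEN_NONCODING", nNc),
                  rep("PERICEN_CODING", nCod),
                  rep("OTHER", nBg))
    for (p in seq_along(parts)) S4Vectors::mcols(parts[[p]]) <- NULL
    all <- do.call(c, parts)
    ## self-consistency: every emitted fragment re-classifies as intended
    chk <- classifyFragments(all, model, lengthThreshold = thr)
    if (!identical(chk$tclass, intended))
      stop("internal error: simulated fragment classifies as ",
           chk$tclass[which(chk$tclass != intended)[1L]],
           " instead of ",
           intended[which(chk$tclass != intended)[1L]], call. = FALSE)
    all
  })
  ord <- order(as.factor(GenomeInfoDb::seqnames(gr)),
               BiocGenerics::start(gr), BiocGenerics::end(gr),
               as.factor(BiocGenerics::strand(gr)))
  gr <- gr[ord]
  gr$name <- sprintf("%s_f%07d", sampleName, seq_along(gr))
  gr$sample <- rep(sampleName, length(gr))
  list(fragments = gr,
       sheetRow = data.frame(sample = sampleName, condition = condition,
                             replicate = as.integer(replicate),
                             totalFragments = as.numeric(length(gr)),
                             stringsAsFactors = FALSE))
}

#' Simulate a complete mock/auxin experiment
#'
#' Generates the genome model, all replicate fragment sets for both
#' conditions, the sample sheet, and a reference-gene table whose counts
#' are drawn consistently with the configured copies-per-cell values (so
#' absolute calibration is exercised end to end). Optionally writes
#' everything to a directory consumable by \code{\link{runPipeline}}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir optional output directory; refuses to reuse a non-empty
#'   directory unless \code{overwrite = TRUE}.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param seed override for \code{config$seed}.
#' @param refReadsPerBpPerCopy sequencing depth factor for the simulated
#'   reference-gene counts (reads per bp per molecule-per-cell).
#' @return list with \code{model}, \code{fragments} (named list of
#'   GRanges per sample), \code{sheet}, \code{refGenes}, and \code{paths}
#'   (NULL when \code{dir} is NULL).
#' @export
simulateExperiment <- function(config = simulationConfig(), dir = NULL,
                               overwrite = FALSE, seed = config$seed,
                               refReadsPerBpPerCopy = 0.02) {
  stopifnot(inherits(config, "SimulationConfig"))
  .assertFlag(overwrite, "overwrite")
  if (!is.null(dir) && dir.exists(dir) &&
      length(list.files(dir)) && !overwrite)
    stop("output directory '", dir, "' exists and is not empty; use ",
         "overwrite = TRUE", call. = FALSE)
  model <- simulateGenome(config, seed = seed)
  runs <- list()
  sheet <- NULL
  for (cond in c("mock", "auxin")) {
    for (rep in seq_len(config$replicates)) {
      r <- simulateFragments(model, config, cond, rep, seed = seed)
      runs[[r$sheetRow$sample]] <- r$fragments
      sheet <- rbind(sheet, r$sheetRow)
    }
  }
  validateSampleSheet(sheet)
  refGenes <- .withSeed(.streamSeed(seed, "mock", 0L, stage = 1L), {
    refs <- data.frame(
      id = c("DOA1", "KAP104", "POL1", "PDR5"),
      chrom = paste0("chr", utils::as.roman(1:4)),
      start = 5001L,
      end = 5000L + c(2148L, 2757L, 4404L, 4536L),
      copiesPerCell = c(2.6, 5.0, 3.1, 13.4),
      stringsAsFactors = FALSE)
    refs$length <- refs$end - refs$start + 1L
    refs$count <- stats::rpois(nrow(refs), refReadsPerBpPerCopy *
                                 refs$copiesPerCell * refs$length)
    refs
  })
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- writeGenomeModel(model, file.path(dir, "genome"))
    fragDir <- file.path(dir, "fragments")
    dir.create(fragDir, showWarnings = FALSE)
    for (nm in names(runs)) {
      p <- file.path(fragDir, paste0(nm, ".bed"))
      writeFragmentsBed(runs[[nm]], p)
      paths <- c(paths, stats::setNames(p, nm))
    }
    sheetPath <- file.path(dir, "samples.tsv")
    writeSampleSheet(sheet, sheetPath)
    refPath <- file.path(dir, "reference_genes.tsv")
    data.table::fwrite(refGenes, refPath, sep = "\t")
    paths <- c(paths, sample_sheet = sheetPath, reference_genes = refPath)
  }
  list(model = model, fragments = runs, sheet = sheet,
       refGenes = refGenes, paths = paths)
}
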