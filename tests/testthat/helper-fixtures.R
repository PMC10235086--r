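# Fixture builders and the independent classification oracle.

# one-chromosome model used across tests: chrT, core 1001-1117 (117 bp),
# default CDE layout 8/84/25, 500 bp windows
toyModel <- function(chromLen = 10000L, coreStart = 1001L,
                     coreWidth = 117L, windowBp = 500L, orfs = NULL,
                     cde1Len = 8L, cde3Len = 25L,
                     coreWidthBand = c(10L, 200L), chrom = "chrT") {
  cores <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(coreStart, width = coreWidth))
  CenGenomeModel(stats::setNames(as.integer(chromLen), chrom), cores,
                 orfs = orfs %||% GenomicRanges::GRanges(),
                 windowBp = windowBp, cde1Len = cde1Len,
                 cde3Len = cde3Len, coreWidthBand = coreWidthBand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frag <- function(start, end, strand = "+", chrom = "chrT",
                 sample = "s1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  gr$sample <- rep(sample, length(gr))
  gr
}

oneSampleSheet <- function(sample = "s1", condition = "mock",
                           total = 1e6) {
  sampleSheet(sample, condition, seq_along(sample), total)
}

# Brute-force oracle: classifies a single fragment by explicit position-set
# membership, sharing no interval arithmetic with the package code path.
# geom: list(cs, ce, cde1, cde2, cde3 (position vectors), up, dn (position
# vectors), orfPos (positions covered by window-intersecting ORFs))
oracleGeom <- function(model, chrom = "chrT") {
  cores <- cenCores(model)
  core <- cores[as.character(GenomeInfoDb::seqnames(cores)) == chrom]
  cdes <- cdeElements(model)
  cdes <- cdes[as.character(GenomeInfoDb::seqnames(cdes)) == chrom]
  win <- periWindows(model)
  win <- win[as.character(GenomeInfoDb::seqnames(win)) == chrom]
  posOf <- function(gr) if (length(gr) == 0L) integer(0) else
    unlist(lapply(seq_along(gr), function(i)
      seq(BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i])))
  orfs <- periOrfs(model)
  orfs <- orfs[as.character(GenomeInfoDb::seqnames(orfs)) == chrom]
  list(
    core = seq(BiocGenerics::start(core), BiocGenerics::end(core)),
    cde1 = posOf(cdes[cdes$cde == "CDEI"]),
    cde2 = posOf(cdes[cdes$cde == "CDEII"]),
    cde3 = posOf(cdes[cdes$cde == "CDEIII"]),
    up = posOf(win[win$side == "UP"]),
    dn = posOf(win[win$side == "DOWN"]),
    orf = posOf(orfs)
  )
}

oracleClassifyOne <- function(fs, fe, strand, g) {
  pos <- seq(fs, fe)
  inCore <- any(pos %in% g$core)
  upHit <- any(pos %in% g$up)
  dnHit <- any(pos %in% g$dn)
  orfHit <- any(pos %in% g$orf)
  side <- if (upHit && dnHit) "BOTH" else if (upHit) "UP" else
    if (dnHit) "DOWN" else "NONE"
  if (!inCore) {
    tclass <- if (upHit || dnHit) {
      if (orfHit) "PERICEN_CODING" else "PERICEN_NONCODING"
    } else "OTHER"
    return(list(tclass = tclass, term = "NONE", init = NA, side = side))
  }
  elementOf <- function(b) {
    if (b %in% g$cde1) "CDEI" else if (b %in% g$cde2) "CDEII" else "CDEIII"
  }
  if (all(g$core %in% pos)) {
    term <- "FULL_CEN"
  } else {
    sIn <- fs %in% g$core
    eIn <- fe %in% g$core
    b <- if (sIn && eIn) {
      if (strand == "+") fe else fs
    } else if (sIn) fs else fe
    term <- elementOf(b)
  }
  p5 <- if (strand == "+") fs else fe
  list(tclass = "CEN", term = term, init = !(p5 %in% g$core), side = side)
}

# vectorised oracle wrapper returning a data.frame
oracleClassify <- function(fs, fe, strand, g) {
  res <- mapply(oracleClassifyOne, fs, fe, strand,
                MoreArgs = list(g = g), SIMPLIFY = FALSE)
  data.frame(tclass = vapply(res, `[[`, "", "tclass"),
             termClass = vapply(res, `[[`, "", "term"),
             initiatedInPericen = vapply(res, function(r)
               as.logical(r$init), NA),
             side = vapply(res, `[[`, "", "side"))
}

# minimal SAM text for paired-end span inference tests
writeSamFixture <- function(path, records,
                            header = c("@HD\tVN:1.6\tSO:unsorted",
                                       "@SQ\tSN:chrT\tLN:10000",
                                       "@SQ\tSN:chrU\tLN:10000")) {
  writeLines(c(header, records), path)
  path
}

samPair <- function(qname, chrom, pos1, pos2, len = 100L,
                    read1Reverse = FALSE, chrom2 = chrom,
                    proper = TRUE) {
  f1 <- 1L + 64L + (if (proper) 2L else 0L) +
    (if (read1Reverse) 16L else 32L)
  f2 <- 1L + 128L + (if (proper) 2L else 0L) +
    (if (read1Reverse) 32L else 16L)
  cig <- paste0(len, "M")
  rn <- if (chrom2 == chrom) "=" else chrom2
  c(paste(qname, f1, chrom, pos1, 60, cig, rn, pos2, 0, "*", "*",
          sep = "\t"),
    paste(qname, f2, chrom2, pos2, 60, cig, rn, pos1, 0, "*", "*",
          sep = "\t"))
}
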