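#' Genome model for point-centromere transcript classification
#'
#' A \code{CenGenomeModel} holds the genomic geometry every downstream stage
#' depends on: chromosome sizes, one CEN core per chromosome, the ordered
#' CDEI/CDEII/CDEIII partition of each core, the pericentromeric windows
#' flanking each core, and the ORFs that intersect those windows.
#'
#' All ranges are stored as \link[GenomicRanges]{GRanges} in the usual
#' Bioconductor 1-based closed convention; BED files on disk keep their
#' 0-based half-open convention through \pkg{rtracklayer}.
#'
#' @slot seqinfo a \link[GenomeInfoDb]{Seqinfo} with chromosome lengths.
#' @slot cores GRanges, exactly one CEN core per chromosome.
#' @slot cdes GRanges, three ranges per core, metadata column
#'   \code{cde} in \code{CDEI, CDEII, CDEIII}; the three elements
#'   partition the core exactly, ordered left to right on the reference
#'   strand.
#' @slot windows GRanges, the up/downstream pericentromeric windows,
#'   metadata column \code{side} in \code{UP, DOWN}; clipped at chromosome
#'   boundaries and adjacent to the core.
#' @slot orfs GRanges of annotated ORFs (metadata column \code{id}); only
#'   ORFs intersecting a pericentromeric window take part in classification.
#' @slot windowBp integer, window width in bp (default 500).
#'
#' @aliases CenGenomeModel
#' @exportClass CenGenomeModel
setClass("CenGenomeModel",
  representation(
    seqinfo  = "Seqinfo",
    cores    = "GRanges",
    cdes     = "GRanges",
    windows  = "GRanges",
    orfs     = "GRanges",
    windowBp = "integer"
  )
)

setValidity("CenGenomeModel", function(object) {
  msgs <- character()
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  cores <- object@cores
  if (any(is.na(sl)) || any(sl <= 0))
    msgs <- c(msgs, "all chromosome lengths must be known and > 0")
  if (anyDuplicated(GenomeInfoDb::seqnames(object@seqinfo)))
    msgs <- c(msgs, "chromosome names must be unique")
  if (anyDuplicated(as.character(GenomeInfoDb::seqnames(cores))))
    msgs <- c(msgs, "more than one CEN core on a chromosome")
  if (length(cores)) {
    csl <- sl[as.character(GenomeInfoDb::seqnames(cores))]
    if (any(BiocGenerics::start(cores) < 1L) ||
        any(BiocGenerics::end(cores) > csl))
      msgs <- c(msgs, "CEN core outside chromosome bounds")
  }
  ## CDE partition: cde1 | cde2 | cde3 == core, disjoint, ordered
  if (length(object@cdes) != 3L * length(cores)) {
    msgs <- c(msgs, "expected exactly three CDE elements per core")
  } else if (length(cores)) {
    cd <- object@cdes
    ok <- vapply(seq_along(cores), function(i) {
      ci <- cores[i]
      el <- cd[as.character(GenomeInfoDb::seqnames(cd)) ==
                 as.character(GenomeInfoDb::seqnames(ci))]
      el <- el[order(BiocGenerics::start(el))]
      length(el) == 3L &&
        identical(el$cde, c("CDEI", "CDEII", "CDEIII")) &&
        BiocGenerics::start(el)[1] == BiocGenerics::start(ci) &&
        BiocGenerics::end(el)[3] == BiocGenerics::end(ci) &&
        all(BiocGenerics::start(el)[2:3] == BiocGenerics::end(el)[1:2] + 1L)
    }, logical(1))
    if (!all(ok))
      msgs <- c(msgs, "CDE elements do not partition the core exactly")
  }
  ## window adjacency after clipping
  w <- object@windows
  if (length(w) && length(cores)) {
    cs <- BiocGenerics::start(cores)
    ce <- BiocGenerics::end(cores)
    names(cs) <- names(ce) <- as.character(GenomeInfoDb::seqnames(cores))
    wchr <- as.character(GenomeInfoDb::seqnames(w))
    up <- w$side == "UP"
    if (any(BiocGenerics::end(w)[up] != cs[wchr[up]] - 1L))
      msgs <- c(msgs, "UP window not adjacent to its core")
    if (any(BiocGenerics::start(w)[!up] != ce[wchr[!up]] + 1L))
      msgs <- c(msgs, "DOWN window not adjacent to its core")
  }
  if (length(object@windowBp) != 1L || object@windowBp <= 0L)
    msgs <- c(msgs, "windowBp must be a single positive integer")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CenGenomeModel chromosome sizes as a named integer vector.
#' @param object,x a \code{CenGenomeModel}.
#' @export
chromSizes <- function(object) GenomeInfoDb::seqlengths(object@seqinfo)

#' @describeIn CenGenomeModel the CEN core ranges (one per chromosome).
#' @export
cenCores <- function(object) object@cores

#' @describeIn CenGenomeModel the CDE element ranges (three per core).
#' @export
cdeElements <- function(object) object@cdes

#' @describeIn CenGenomeModel the pericentromeric windows.
#' @export
periWindows <- function(object) object@windows

#' @describeIn CenGenomeModel ORFs intersecting the pericentromeric windows.
#' @export
periOrfs <- function(object) {
  hit <- IRanges::overlapsAny(object@orfs, object@windows,
                              ignore.strand = TRUE)
  object@orfs[hit]
}

#' @describeIn CenGenomeModel all annotated ORFs (including any outside the
#'   windows, which are kept but ignored by classification).
#' @export
allOrfs <- function(object) object@orfs

#' @describeIn CenGenomeModel the pericentromeric window width in bp.
#' @export
periWindowBp <- function(object) object@windowBp

setMethod("show", "CenGenomeModel", function(object) {
  cat("CenGenomeModel with", length(object@cores), "CEN cores on",
      length(GenomeInfoDb::seqnames(object@seqinfo)), "chromosomes\n")
  cat("  core widths:", paste(range(BiocGenerics::width(object@cores)),
                              collapse = "-"), "bp\n")
  cat("  periCEN window:", object@windowBp, "bp;",
      length(periOrfs(object)), "window-intersecting ORFs\n")
})

#' Derive the CDEI/CDEII/CDEIII layout of a CEN core
#'
#' The S. cerevisiae point centromere is composed of three ordered elements:
#' a short conserved CDEI box, an AT-rich CDEII spacer, and the essential
#' CDEIII box. When no element annotation is supplied, the canonical layout
#' is derived from the core: the first \code{cde1Len} bp are CDEI, the last
#' \code{cde3Len} bp are CDEIII, and the remainder is CDEII.
#'
#' @param core a GRanges of CEN cores (any length).
#' @param cde1Len,cde3Len element sizes in bp (defaults 8 and 25).
#' @return GRanges with three ranges per input core and metadata column
#'   \code{cde}; the elements exactly partition each core.
#' @export
#' @examples
#' core <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 1117))
#' deriveCdeLayout(core)
deriveCdeLayout <- function(core, cde1Len = 8L, cde3Len = 25L) {
  cde1Len <- .assertCount(cde1Len, "cde1Len", positive = TRUE)
  cde3Len <- .assertCount(cde3Len, "cde3Len", positive = TRUE)
  w <- BiocGenerics::width(core)
  if (any(w < cde1Len + cde3Len + 1L))
    stop("CEN core too short for CDE layout (need >= ",
         cde1Len + cde3Len + 1L, " bp)", call. = FALSE)
  s <- BiocGenerics::start(core)
  e <- BiocGenerics::end(core)
  out <- GenomicRanges::GRanges(
    rep(GenomeInfoDb::seqnames(core), each = 3L),
    IRanges::IRanges(
      start = as.vector(rbind(s, s + cde1Len, e - cde3Len + 1L)),
      end   = as.vector(rbind(s + cde1Len - 1L, e - cde3Len, e))
    ),
    seqinfo = GenomeInfoDb::seqinfo(core)
  )
  out$cde <- rep(c("CDEI", "CDEII", "CDEIII"), length(core))
  out
}

.makePeriWindows <- function(cores, windowBp, seqinfo) {
  sl <- GenomeInfoDb::seqlengths(seqinfo)
  chr <- as.character(GenomeInfoDb::seqnames(cores))
  cs <- BiocGenerics::start(cores)
  ce <- BiocGenerics::end(cores)
  upStart <- pmax(1L, cs - windowBp)
  upEnd <- cs - 1L
  dnStart <- ce + 1L
  dnEnd <- pmin(as.integer(sl[chr]), ce + windowBp)
  keepUp <- upEnd >= upStart
  keepDn <- dnEnd >= dnStart
  up <- GenomicRanges::GRanges(chr[keepUp],
          IRanges::IRanges(upStart[keepUp], upEnd[keepUp]), seqinfo = seqinfo)
  dn <- GenomicRanges::GRanges(chr[keepDn],
          IRanges::IRanges(dnStart[keepDn], dnEnd[keepDn]), seqinfo = seqinfo)
  up$side <- rep("UP", length(up))
  dn$side <- rep("DOWN", length(dn))
  BiocGenerics::sort(c(up, dn))
}

#' Construct a CenGenomeModel from in-memory annotation
#'
#' @param seqinfo a \link[GenomeInfoDb]{Seqinfo} (or named lengths vector).
#' @param cores GRanges of CEN cores, exactly one per chromosome.
#' @param orfs optional GRanges of ORFs with a \code{id} metadata column.
#' @param cdes optional GRanges of CDE elements (metadata column
#'   \code{cde}); derived with \code{\link{deriveCdeLayout}} if absent.
#' @param windowBp pericentromeric window width, bp.
#' @param cde1Len,cde3Len CDE layout parameters when \code{cdes} is absent.
#' @param coreWidthBand length-2 numeric, accepted core width range in bp
#'   (the point-centromere core is 117 +/- 2 bp; the default band 113-121
#'   leaves validation slack). \code{NULL} disables the check.
#' @return a validated \code{CenGenomeModel}.
#' @export
CenGenomeModel <- function(seqinfo, cores, orfs = GenomicRanges::GRanges(),
                           cdes = NULL, windowBp = 500L,
                           cde1Len = 8L, cde3Len = 25L,
                           coreWidthBand = c(113L, 121L)) {
  if (!methods::is(seqinfo, "Seqinfo")) {
    if (is.null(names(seqinfo)))
      stop("'seqinfo' must be a Seqinfo or a named vector of lengths")
    seqinfo <- GenomeInfoDb::Seqinfo(names(seqinfo),
                                     seqlengths = as.integer(seqinfo))
  }
  windowBp <- .assertCount(windowBp, "windowBp", positive = TRUE)
  chrOrder <- GenomeInfoDb::seqnames(seqinfo)
  coreChr <- as.character(GenomeInfoDb::seqnames(cores))
  if (anyDuplicated(coreChr))
    stop("duplicate CEN core on chromosome(s): ",
         paste(unique(coreChr[duplicated(coreChr)]), collapse = ", "),
         call. = FALSE)
  if (!all(coreChr %in% chrOrder))
    stop("CEN core on unknown chromosome(s): ",
         paste(setdiff(coreChr, chrOrder), collapse = ", "), call. = FALSE)
  sl <- GenomeInfoDb::seqlengths(seqinfo)
  if (any(BiocGenerics::start(cores) < 1L) ||
      any(BiocGenerics::end(cores) > sl[coreChr]))
    stop("CEN core outside chromosome bounds", call. = FALSE)
  if (!is.null(coreWidthBand)) {
    w <- BiocGenerics::width(cores)
    if (any(w < coreWidthBand[1] | w > coreWidthBand[2]))
      stop(sprintf("CEN core width outside accepted band [%d, %d] bp",
                   as.integer(coreWidthBand[1]),
                   as.integer(coreWidthBand[2])), call. = FALSE)
  }
  cores <- GenomicRanges::GRanges(coreChr, IRanges::ranges(cores),
                                  seqinfo = seqinfo)
  S4Vectors::mcols(cores) <- NULL
  cores <- BiocGenerics::sort(cores)
  if (is.null(cdes)) {
    cdes <- deriveCdeLayout(cores, cde1Len = cde1Len, cde3Len = cde3Len)
  } else {
    cdes <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(cdes)), IRanges::ranges(cdes),
      cde = cdes$cde, seqinfo = seqinfo)
    cdes <- cdes[order(as.factor(GenomeInfoDb::seqnames(cdes)),
                       BiocGenerics::start(cdes))]
  }
  if (length(orfs)) {
    orfChr <- as.character(GenomeInfoDb::seqnames(orfs))
    unknown <- setdiff(orfChr, chrOrder)
    if (length(unknown))
      stop("ORF on unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    noCen <- setdiff(unique(orfChr), coreChr)
    if (length(noCen))
      warning("ORF(s) on chromosome(s) without a CEN core: ",
              paste(noCen, collapse = ", "), " (kept, never classified)",
              call. = FALSE)
    if (is.null(orfs$id)) orfs$id <- paste0("ORF", seq_along(orfs))
    orfs <- GenomicRanges::GRanges(orfChr, IRanges::ranges(orfs),
                                   strand = BiocGenerics::strand(orfs),
                                   id = orfs$id, seqinfo = seqinfo)
    orfs <- BiocGenerics::sort(orfs, ignore.strand = TRUE)
  } else {
    orfs <- GenomicRanges::GRanges(seqinfo = seqinfo)
    orfs$id <- character(0)
  }
  methods::new("CenGenomeModel",
               seqinfo = seqinfo, cores = cores, cdes = cdes,
               windows = .makePeriWindows(cores, windowBp, seqinfo),
               orfs = orfs, windowBp = windowBp)
}

.readChromSizes <- function(path) {
  tab <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("name", "length"))
  if (anyDuplicated(tab$name))
    stop("duplicate chromosome name in ", path, call. = FALSE)
  stats::setNames(as.integer(tab$length), tab$name)
}

.importBed <- function(path, seqinfo) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(seqinfo)
  GenomeInfoDb::seqinfo(gr) <- seqinfo
  gr
}

#' Load a genome model from annotation files
#'
#' Reads chromosome sizes (two-column tab-separated), CEN cores (BED),
#' optional window-proximal ORFs (BED6; strand kept) and optional CDE
#' element annotation (BED with the element name in the BED name field).
#' When \code{cdeBed} is absent the CDE layout is derived with
#' \code{\link{deriveCdeLayout}}.
#'
#' @param chromSizesFile path to a two-column (name, length) file.
#' @param cenBed path to the CEN core BED (at most one record/chromosome).
#' @param orfBed optional path to an ORF BED6.
#' @param cdeBed optional path to a CDE element BED (names CDEI/CDEII/CDEIII).
#' @inheritParams CenGenomeModel
#' @return a validated \code{CenGenomeModel}.
#' @export
loadGenomeModel <- function(chromSizesFile, cenBed, orfBed = NULL,
                            cdeBed = NULL, windowBp = 500L,
                            cde1Len = 8L, cde3Len = 25L,
                            coreWidthBand = c(113L, 121L)) {
  sizes <- .readChromSizes(chromSizesFile)
  seqinfo <- GenomeInfoDb::Seqinfo(names(sizes), seqlengths = sizes)
  cores <- .importBed(cenBed, seqinfo)
  orfs <- if (!is.null(orfBed)) {
    o <- .importBed(orfBed, seqinfo)
    if (!is.null(o$name)) o$id <- o$name
    o
  } else GenomicRanges::GRanges()
  cdes <- if (!is.null(cdeBed)) {
    cd <- .importBed(cdeBed, seqinfo)
    if (is.null(cd$name) || !all(cd$name %in% c("CDEI", "CDEII", "CDEIII")))
      stop("cdeBed must carry element names CDEI/CDEII/CDEIII in the name ",
           "field", call. = FALSE)
    cd$cde <- cd$name
    cd
  } else NULL
  CenGenomeModel(seqinfo, cores, orfs = orfs, cdes = cdes,
                 windowBp = windowBp, cde1Len = cde1Len,
                 cde3Len = cde3Len, coreWidthBand = coreWidthBand)
}

#' Write a genome model back to annotation files
#'
#' Emits chrom.sizes, CEN core BED, CDE element BED and ORF BED into
#' \code{dir}; \code{\link{loadGenomeModel}} on these files reproduces the
#' model.
#'
#' @param model a \code{CenGenomeModel}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the written paths.
#' @export
writeGenomeModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- chromSizes(model)
  paths <- c(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    cen = file.path(dir, "cen_cores.bed"),
    cde = file.path(dir, "cde_elements.bed"),
    orf = file.path(dir, "pericen_orfs.bed")
  )
  data.table::fwrite(data.table::data.table(names(sizes), unname(sizes)),
                     paths[["chrom_sizes"]], sep = "\t", col.names = FALSE)
  rtracklayer::export(cenCores(model), paths[["cen"]], format = "BED")
  cd <- cdeElements(model)
  cd$name <- cd$cde
  rtracklayer::export(cd, paths[["cde"]], format = "BED")
  orfs <- allOrfs(model)
  if (length(orfs)) {
    orfs$name <- orfs$id
    rtracklayer::export(orfs, paths[["orf"]], format = "BED")
  } else {
    file.create(paths[["orf"]])
  }
  invisible(paths)
}
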