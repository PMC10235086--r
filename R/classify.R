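#' Classify fragment spans against the centromere annotation
#'
#' Every fragment is assigned exactly one transcript class:
#' \describe{
#'   \item{CEN}{overlaps the CEN core by at least 1 bp ("containing the
#'     core sequence or a part of it").}
#'   \item{PERICEN_CODING / PERICEN_NONCODING}{does not touch the core but
#'     overlaps a pericentromeric window by at least 1 bp (subtraction
#'     semantics: window hits minus core hits); CODING when it also
#'     overlaps an ORF that intersects a pericentromeric window.}
#'   \item{OTHER}{everything else.}
#' }
#'
#' CEN fragments additionally receive:
#' \describe{
#'   \item{termClass}{\code{FULL_CEN} when the fragment covers the whole
#'     core; otherwise the CDE element holding the fragment boundary that
#'     falls inside the core. When both boundaries fall inside the core,
#'     the 3' boundary (with respect to the fragment strand) decides.}
#'   \item{lengthClass}{\code{SHORT} when span length < the threshold
#'     (default 1000 nt), else \code{LONG}; a span of exactly 1000 nt is
#'     \code{LONG}.}
#'   \item{initiatedInPericen}{whether the strand-aware 5' end lies outside
#'     the core.}
#'   \item{side}{which pericentromeric window is touched
#'     (\code{UP}/\code{DOWN}/\code{BOTH}/\code{NONE}).}
#' }
#'
#' @param fragments GRanges of fragment records (see
#'   \code{\link{readFragmentsBed}}).
#' @param model a \code{\link{CenGenomeModel}}.
#' @param lengthThreshold SHORT/LONG boundary in nt (default 1000).
#' @param codingStrandMatched if \code{TRUE}, a fragment counts as coding
#'   only when the overlapping ORF lies on the same strand; default
#'   \code{FALSE} (pure coordinate intersection).
#' @return the input GRanges with added metadata columns \code{length},
#'   \code{tclass}, \code{termClass}, \code{lengthClass},
#'   \code{initiatedInPericen} (NA outside CEN), and \code{side}.
#' @export
#' @examples
#' model <- CenGenomeModel(c(chrT = 10000L),
#'   GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 1117)))
#' f <- GenomicRanges::GRanges("chrT", IRanges::IRanges(901, 1050), "+")
#' classifyFragments(f, model)
classifyFragments <- function(fragments, model, lengthThreshold = 1000L,
                              codingStrandMatched = FALSE) {
  .assertFlag(codingStrandMatched, "codingStrandMatched")
  n <- length(fragments)
  chr <- as.character(GenomeInfoDb::seqnames(fragments))
  known <- names(chromSizes(model))
  badChr <- which(!chr %in% known)
  if (length(badChr)) {
    b <- badChr[1L]
    stop(sprintf("fragment %s:%d-%d on chromosome absent from the model",
                 chr[b], BiocGenerics::start(fragments)[b],
                 BiocGenerics::end(fragments)[b]), call. = FALSE)
  }
  fs <- BiocGenerics::start(fragments)
  fe <- BiocGenerics::end(fragments)
  str <- as.character(BiocGenerics::strand(fragments))
  if (any(!str %in% c("+", "-")))
    stop("all fragments must carry '+' or '-' strand", call. = FALSE)

  cores <- cenCores(model)
  coreChr <- as.character(GenomeInfoDb::seqnames(cores))
  ci <- match(chr, coreChr)
  cs <- BiocGenerics::start(cores)[ci]
  ce <- BiocGenerics::end(cores)[ci]
  hasCore <- !is.na(ci)

  overCore <- hasCore & fs <= ce & fe >= cs

  win <- periWindows(model)
  upHit <- IRanges::overlapsAny(fragments, win[win$side == "UP"],
                                ignore.strand = TRUE)
  dnHit <- IRanges::overlapsAny(fragments, win[win$side == "DOWN"],
                                ignore.strand = TRUE)
  side <- rep("NONE", n)
  side[upHit] <- "UP"
  side[dnHit] <- "DOWN"
  side[upHit & dnHit] <- "BOTH"

  orfs <- periOrfs(model)
  orfHit <- IRanges::overlapsAny(fragments, orfs,
                                 ignore.strand = !codingStrandMatched)

  tclass <- rep("OTHER", n)
  tclass[(upHit | dnHit) & !overCore] <-
    ifelse(orfHit[(upHit | dnHit) & !overCore],
           "PERICEN_CODING", "PERICEN_NONCODING")
  tclass[overCore] <- "CEN"

  ## CEN annotation: termination class, 5' origin, length class
  termClass <- rep("NONE", n)
  initiated <- rep(NA, n)
  lenClass <- rep("NONE", n)
  if (any(overCore)) {
    i <- which(overCore)
    full <- fs[i] <= cs[i] & fe[i] >= ce[i]
    insideStart <- fs[i] >= cs[i] & fs[i] <= ce[i] & !full
    insideEnd <- fe[i] >= cs[i] & fe[i] <= ce[i] & !full
    boundary <- rep(NA_integer_, length(i))
    both <- insideStart & insideEnd
    boundary[both] <- ifelse(str[i][both] == "+", fe[i][both], fs[i][both])
    boundary[insideStart & !both] <- fs[i][insideStart & !both]
    boundary[insideEnd & !both] <- fe[i][insideEnd & !both]

    cdes <- cdeElements(model)
    cdeChr <- as.character(GenomeInfoDb::seqnames(cdes))
    cde1End <- BiocGenerics::end(cdes)[cdes$cde == "CDEI"]
    cde2End <- BiocGenerics::end(cdes)[cdes$cde == "CDEII"]
    names(cde1End) <- cdeChr[cdes$cde == "CDEI"]
    names(cde2End) <- cdeChr[cdes$cde == "CDEII"]
    c1 <- cde1End[chr[i]]
    c2 <- cde2End[chr[i]]
    el <- ifelse(boundary <= c1, "CDEI",
                 ifelse(boundary <= c2, "CDEII", "CDEIII"))
    termClass[i] <- ifelse(full, "FULL_CEN", el)

    fp <- ifelse(str[i] == "-", fe[i], fs[i])
    initiated[i] <- fp < cs[i] | fp > ce[i]
    lenClass[i] <- lengthClass(fe[i] - fs[i] + 1L, lengthThreshold)
  }

  out <- fragments
  out$length <- fe - fs + 1L
  out$tclass <- tclass
  out$termClass <- termClass
  out$lengthClass <- lenClass
  out$initiatedInPericen <- initiated
  out$side <- side
  out
}

#' Short/long length classification
#'
#' Fragments shorter than the threshold are SHORT, all others LONG; the
#' boundary value itself (a span of exactly \code{threshold} nt) is LONG.
#'
#' @param length integer vector of span lengths (nt), or a GRanges whose
#'   widths are used.
#' @param threshold boundary in nt (default 1000).
#' @return character vector of \code{"SHORT"}/\code{"LONG"}.
#' @export
lengthClass <- function(length, threshold = 1000L) {
  if (methods::is(length, "GRanges")) length <- BiocGenerics::width(length)
  ifelse(length < threshold, "SHORT", "LONG")
}

#' Tally classified fragments
#'
#' Exact multiset counting of classified fragments per (sample, condition,
#' chromosome, class, strand, length class, termination class);
#' deterministic and independent of input order. The count marginal equals
#' the number of classified fragments.
#'
#' @param classified GRanges from \code{\link{classifyFragments}}.
#' @param sheet sample sheet (see \code{\link{sampleSheet}}); every sample
#'   present in \code{classified} must appear in it.
#' @return a \code{data.frame} with columns sample, condition, chrom,
#'   tclass, strand, lengthClass, termClass, count.
#' @export
tallyFragments <- function(classified, sheet) {
  validateSampleSheet(sheet)
  samp <- classified$sample
  if (is.null(samp))
    stop("classified fragments lack a 'sample' column", call. = FALSE)
  unknown <- setdiff(unique(samp), sheet$sample)
  if (length(unknown))
    stop("sample(s) not in sheet: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dt <- data.table::data.table(
    sample = samp,
    chrom = as.character(GenomeInfoDb::seqnames(classified)),
    tclass = classified$tclass,
    strand = as.character(BiocGenerics::strand(classified)),
    lengthClass = classified$lengthClass,
    termClass = classified$termClass
  )
  count <- NULL # NSE
  tal <- dt[, list(count = .N),
            by = c("sample", "chrom", "tclass", "strand",
                   "lengthClass", "termClass")]
  tal <- merge(tal, data.table::as.data.table(
    sheet[, c("sample", "condition")]), by = "sample")
  data.table::setcolorder(tal, c("sample", "condition", "chrom", "tclass",
                                 "strand", "lengthClass", "termClass",
                                 "count"))
  data.table::setorderv(tal, c("sample", "chrom", "tclass", "strand",
                               "lengthClass", "termClass"))
  as.data.frame(tal)
}

#' Termination-class distribution of CEN fragments
#'
#' Fractions of CEN fragments over the termination classes (FULL_CEN,
#' CDEI, CDEII, CDEIII) split by strand, for one condition; the eight
#' fractions sum to one (the per-strand split mirrors the filled/open pie
#' slices of the published figure).
#'
#' @param tally output of \code{\link{tallyFragments}}.
#' @param condition \code{"mock"} or \code{"auxin"}.
#' @return data.frame with columns termClass, strand, count, fraction.
#' @export
termClassDistribution <- function(tally, condition) {
  sel <- tally[tally$tclass == "CEN" & tally$condition == condition, ,
               drop = FALSE]
  if (nrow(sel) == 0L || sum(sel$count) == 0L)
    stop("no CEN fragments for condition '", condition, "'", call. = FALSE)
  agg <- stats::aggregate(count ~ termClass + strand, data = sel, FUN = sum)
  grid <- expand.grid(termClass = c("FULL_CEN", "CDEI", "CDEII", "CDEIII"),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  out <- merge(grid, agg, all.x = TRUE)
  out$count[is.na(out$count)] <- 0L
  out$fraction <- out$count / sum(out$count)
  out <- out[order(match(out$termClass,
                         c("FULL_CEN", "CDEI", "CDEII", "CDEIII")),
                   out$strand), ]
  rownames(out) <- NULL
  out
}

#' Write classified fragments as extended BED
#'
#' BED6 plus four annotation columns (tclass, termClass, lengthClass,
#' side).
#'
#' @param classified GRanges from \code{\link{classifyFragments}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeClassifiedFragments <- function(classified, path) {
  n <- length(classified)
  tab <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(classified)),
    start = BiocGenerics::start(classified) - 1L,
    end = BiocGenerics::end(classified),
    name = classified$name %||% paste0("f", seq_len(n)),
    score = 0L,
    strand = as.character(BiocGenerics::strand(classified)),
    tclass = classified$tclass,
    termClass = classified$termClass,
    lengthClass = classified$lengthClass,
    side = classified$side
  )
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
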