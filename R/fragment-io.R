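#' Read strand-aware fragment records from a BED6 file
#'
#' A fragment record is the full genomic span of a sequenced cDNA fragment
#' (read-pair span) on the strand of the transcript it derives from. Input
#' must be BED6 with an explicit \code{+}/\code{-} strand; strandless
#' records are rejected because every downstream statistic (5' start sites,
#' per-strand profiles) is strand-aware.
#'
#' @param path BED6 file path.
#' @param sample sample identifier attached to every record.
#' @return GRanges with metadata columns \code{name} and \code{sample};
#'   input order is preserved.
#' @export
readFragmentsBed <- function(path, sample) {
  stopifnot(is.character(sample), length(sample) == 1L)
  tab <- if (file.size(path) == 0L) data.table::data.table() else
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1L))
  if (nrow(tab) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$name <- character(0)
    gr$sample <- character(0)
    return(gr)
  }
  if (ncol(tab) < 6L)
    stop("'", path, "' is not BED6 (found ", ncol(tab), " columns)",
         call. = FALSE)
  start0 <- suppressWarnings(as.integer(tab[[2L]]))
  end <- suppressWarnings(as.integer(tab[[3L]]))
  bad <- which(is.na(start0) | is.na(end) | start0 < 0L | end <= start0)
  if (length(bad))
    stop("malformed BED record at line ", bad[1L], " of ", path,
         call. = FALSE)
  strand <- as.character(tab[[6L]])
  badStrand <- which(!strand %in% c("+", "-"))
  if (length(badStrand))
    stop("fragment strand must be '+' or '-' (line ", badStrand[1L],
         " of ", path, " has '", strand[badStrand[1L]], "')", call. = FALSE)
  gr <- GenomicRanges::GRanges(tab[[1L]],
                               IRanges::IRanges(start0 + 1L, end),
                               strand = strand)
  gr$name <- as.character(tab[[4L]])
  gr$sample <- rep(sample, length(gr))
  gr
}

#' Write fragment records to a BED6 file
#'
#' Inverse of \code{\link{readFragmentsBed}}: records round-trip losslessly.
#' Records are written verbatim (chromosome validation happens at
#' classification, not here).
#'
#' @param fragments GRanges of fragment records.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFragmentsBed <- function(fragments, path) {
  n <- length(fragments)
  name <- fragments$name %||% paste0("f", seq_len(n))
  if (n == 0L) {
    file.create(path)
    return(invisible(path))
  }
  tab <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(fragments)),
    start = BiocGenerics::start(fragments) - 1L,
    end = BiocGenerics::end(fragments),
    name = name,
    score = 0L,
    strand = as.character(BiocGenerics::strand(fragments))
  )
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Infer fragment spans from paired-end alignments
#'
#' Collapses each properly paired, primary alignment pair into one fragment
#' record spanning from the leftmost to the rightmost aligned base of
#' either mate. The transcript strand follows the library protocol: with
#' the dUTP (\code{fr-firststrand}) convention the second mate carries the
#' transcript sense, with \code{fr-secondstrand} the first mate does.
#' Pairs whose mates map to different chromosomes are skipped and counted.
#'
#' @param path SAM or BAM path (SAM is converted internally).
#' @param sample sample identifier.
#' @param library \code{"fr-firststrand"} (default, dUTP) or
#'   \code{"fr-secondstrand"}.
#' @return GRanges of fragment spans with metadata columns \code{name}
#'   (read name) and \code{sample}, and attribute \code{"skipped"} holding
#'   the number of discarded pairs.
#' @export
fragmentsFromSam <- function(path, sample,
                             library = c("fr-firststrand",
                                         "fr-secondstrand")) {
  library <- match.arg(library)
  isSam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (isSam) {
    dest <- tempfile(fileext = "")
    tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE),
      error = function(e) stop(
        "could not convert SAM to BAM (", conditionMessage(e),
        "); sort the file by coordinate with 'samtools sort' and retry",
        call. = FALSE)
    )
  } else path
  strandMode <- if (library == "fr-firststrand") 2L else 1L
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  gp <- GenomicAlignments::readGAlignmentPairs(
    Rsamtools::BamFile(bam, asMates = TRUE), strandMode = strandMode,
    param = Rsamtools::ScanBamParam(flag = flag), use.names = TRUE)
  nPairs <- length(gp)
  sameChr <- as.character(GenomeInfoDb::seqnames(
    GenomicAlignments::first(gp))) ==
    as.character(GenomeInfoDb::seqnames(GenomicAlignments::last(gp)))
  gp <- gp[sameChr]
  gr <- GenomicRanges::granges(gp)
  gr$name <- names(gp)
  names(gr) <- NULL
  gr$sample <- rep(sample, length(gr))
  attr(gr, "skipped") <- nPairs - length(gr)
  gr
}

#' Build and validate a sample sheet
#'
#' The sample sheet maps each sample to its condition and replicate and
#' records \code{totalFragments}, the total number of mapped fragments in
#' the library. That total is the counts-per-million denominator, i.e. the
#' library depth, not the number of (peri)centromeric fragments.
#'
#' @param sample character, unique sample identifiers.
#' @param condition character, one of \code{"mock"} or \code{"auxin"}.
#' @param replicate integer replicate index within condition.
#' @param totalFragments numeric, mapped fragments per sample (> 0).
#' @return a validated \code{data.frame} with those four columns.
#' @export
sampleSheet <- function(sample, condition, replicate, totalFragments) {
  df <- data.frame(sample = as.character(sample),
                   condition = as.character(condition),
                   replicate = as.integer(replicate),
                   totalFragments = as.numeric(totalFragments),
                   stringsAsFactors = FALSE)
  validateSampleSheet(df)
  df
}

#' @rdname sampleSheet
#' @param sheet a candidate sample-sheet \code{data.frame}.
#' @export
validateSampleSheet <- function(sheet) {
  need <- c("sample", "condition", "replicate", "totalFragments")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheet$sample))
    stop("sample identifiers must be unique", call. = FALSE)
  if (!all(sheet$condition %in% c("mock", "auxin")))
    stop("condition must be 'mock' or 'auxin'", call. = FALSE)
  if (anyDuplicated(sheet[, c("condition", "replicate")]))
    stop("(condition, replicate) pairs must be unique", call. = FALSE)
  if (any(!is.finite(sheet$totalFragments) | sheet$totalFragments < 0))
    stop("totalFragments must be finite and non-negative", call. = FALSE)
  invisible(sheet)
}

#' @rdname sampleSheet
#' @param path tab-separated sample sheet path (with header).
#' @export
readSampleSheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  df$replicate <- as.integer(df$replicate)
  df$totalFragments <- as.numeric(df$totalFragments)
  validateSampleSheet(df)
  df
}

#' @rdname sampleSheet
#' @export
writeSampleSheet <- function(sheet, path) {
  validateSampleSheet(sheet)
  data.table::fwrite(sheet, path, sep = "\t")
  invisible(path)
}
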