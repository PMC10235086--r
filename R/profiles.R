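#' Per-nucleotide, CEN-anchored profiles
#'
#' A \code{NucleotideProfile} holds per-position, per-strand counts in
#' CEN-anchored coordinates: offset 0 is the first base of the CEN core,
#' negative offsets run into the upstream window, and offsets beyond the
#' core width run into the downstream window. Anchoring on the core start
#' makes profiles from all chromosomes superposable even though core
#' widths differ by a few bp.
#'
#' @slot values data.frame; for RAW profiles columns (offset, strand,
#'   sample, value), for CPM profiles (offset, strand, condition, value).
#' @slot mode \code{"COVERAGE"} (each fragment increments every position
#'   it covers) or \code{"START_SITES"} (only the strand-aware 5' end).
#' @slot normalisation \code{"RAW"} or \code{"CPM"}.
#' @slot windowBp window width used, must equal the model's.
#' @slot classes transcript classes included.
#'
#' @aliases NucleotideProfile
#' @exportClass NucleotideProfile
setClass("NucleotideProfile",
  representation(values = "data.frame", mode = "character",
                 normalisation = "character", windowBp = "integer",
                 classes = "character"))

setValidity("NucleotideProfile", function(object) {
  msgs <- character()
  if (!object@mode %in% c("COVERAGE", "START_SITES"))
    msgs <- c(msgs, "mode must be COVERAGE or START_SITES")
  if (!object@normalisation %in% c("RAW", "CPM"))
    msgs <- c(msgs, "normalisation must be RAW or CPM")
  if (any(object@values$value < 0))
    msgs <- c(msgs, "profile values must be non-negative")
  if (object@normalisation == "RAW" &&
      any(object@values$value != floor(object@values$value)))
    msgs <- c(msgs, "RAW profile values must be integers")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn NucleotideProfile the tidy values table.
#' @param object a \code{NucleotideProfile}.
#' @export
profileValues <- function(object) object@values

#' @describeIn NucleotideProfile profile mode.
#' @export
profileMode <- function(object) object@mode

#' @describeIn NucleotideProfile normalisation state.
#' @export
profileNormalisation <- function(object) object@normalisation

setMethod("show", "NucleotideProfile", function(object) {
  cat("NucleotideProfile:", object@mode, "/", object@normalisation, "\n")
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  cat("  window:", object@windowBp, "bp; offsets",
      paste(range(object@values$offset), collapse = ".."),
      ";", nrow(object@values), "rows; total mass",
      format(sum(object@values$value)), "\n")
})

.profileFragments <- function(classified, model, classes) {
  if (is.null(classified$sample))
    stop("classified fragments lack a 'sample' column", call. = FALSE)
  keep <- classified$tclass %in% classes
  classified[keep]
}

.checkProfileGeometry <- function(model, windowBp) {
  if (as.integer(windowBp) != periWindowBp(model))
    stop("windowBp (", windowBp, ") differs from the model's window (",
         periWindowBp(model), "); profiles must match the classification ",
         "geometry", call. = FALSE)
}

.denseGrid <- function(counts, offsets, samples) {
  ## counts: data.table(offset, strand, sample, value) possibly sparse;
  ## expand to the dense (offset x strand x sample) grid with zeros
  grid <- data.table::CJ(offset = offsets, strand = c("+", "-"),
                         sample = samples)
  out <- merge(grid, counts, by = c("offset", "strand", "sample"),
               all.x = TRUE)
  out$value[is.na(out$value)] <- 0
  data.table::setorderv(out, c("sample", "strand", "offset"))
  as.data.frame(out)
}

#' CEN-anchored per-nucleotide coverage profile
#'
#' For every offset in the profiled region (core plus \code{windowBp} on
#' each side), counts the fragments of the selected classes covering that
#' position, per strand and sample. The sum over all offsets equals the
#' summed per-fragment overlap lengths with the profiled region.
#'
#' @param classified GRanges from \code{\link{classifyFragments}}.
#' @param model a \code{\link{CenGenomeModel}}.
#' @param sheet sample sheet; all profiled samples must appear in it.
#' @param windowBp must equal \code{periWindowBp(model)} (guards against
#'   profiling with a different geometry than the classification).
#' @param classes transcript classes to profile (default CEN and
#'   noncoding pericentromeric, as in the published per-nucleotide plots).
#' @return a RAW \code{NucleotideProfile} in COVERAGE mode.
#' @export
coverageProfile <- function(classified, model, sheet,
                            windowBp = periWindowBp(model),
                            classes = c("CEN", "PERICEN_NONCODING")) {
  .checkProfileGeometry(model, windowBp)
  validateSampleSheet(sheet)
  fr <- .profileFragments(classified, model, classes)
  W <- periWindowBp(model)
  cores <- cenCores(model)
  coreChr <- as.character(GenomeInfoDb::seqnames(cores))
  maxCW <- if (length(cores)) max(BiocGenerics::width(cores)) else 1L
  offsets <- seq(-W, maxCW - 1L + W)
  samples <- sort(unique(sheet$sample))

  counts <- data.table::data.table(offset = integer(0),
                                   strand = character(0),
                                   sample = character(0), value = numeric(0))
  if (length(fr)) {
    chr <- as.character(GenomeInfoDb::seqnames(fr))
    ci <- match(chr, coreChr)
    cs <- BiocGenerics::start(cores)[ci]
    ce <- BiocGenerics::end(cores)[ci]
    lo <- pmax(BiocGenerics::start(fr), cs - W)
    hi <- pmin(BiocGenerics::end(fr), ce + W)
    ok <- !is.na(ci) & lo <= hi
    dt <- data.table::data.table(
      sample = fr$sample[ok],
      strand = as.character(BiocGenerics::strand(fr))[ok],
      from = lo[ok] - cs[ok], to = hi[ok] - cs[ok])
    if (nrow(dt)) {
      grp <- dt[, list(rs = list(
        IRanges::IRanges(from + W + 1L, to + W + 1L))),
        by = c("sample", "strand")]
      value <- NULL # NSE
      counts <- grp[, {
        cov <- IRanges::coverage(rs[[1L]], width = length(offsets))
        v <- as.integer(cov)
        list(offset = offsets[v > 0L], value = as.numeric(v[v > 0L]))
      }, by = c("sample", "strand")]
    }
  }
  methods::new("NucleotideProfile",
               values = .denseGrid(counts, offsets, samples),
               mode = "COVERAGE", normalisation = "RAW",
               windowBp = W, classes = classes)
}

#' CEN-anchored start-site profile
#'
#' Increments only the strand-aware 5'-end position of each fragment (the
#' rightmost base for minus-strand fragments). The RAW profile mass equals
#' the number of profiled fragments whose 5' end lies inside the profiled
#' region.
#'
#' @inheritParams coverageProfile
#' @return a RAW \code{NucleotideProfile} in START_SITES mode.
#' @export
startSiteProfile <- function(classified, model, sheet,
                             windowBp = periWindowBp(model),
                             classes = c("CEN", "PERICEN_NONCODING")) {
  .checkProfileGeometry(model, windowBp)
  validateSampleSheet(sheet)
  fr <- .profileFragments(classified, model, classes)
  W <- periWindowBp(model)
  cores <- cenCores(model)
  coreChr <- as.character(GenomeInfoDb::seqnames(cores))
  maxCW <- if (length(cores)) max(BiocGenerics::width(cores)) else 1L
  offsets <- seq(-W, maxCW - 1L + W)
  samples <- sort(unique(sheet$sample))

  counts <- data.table::data.table(offset = integer(0),
                                   strand = character(0),
                                   sample = character(0), value = numeric(0))
  if (length(fr)) {
    chr <- as.character(GenomeInfoDb::seqnames(fr))
    ci <- match(chr, coreChr)
    cs <- BiocGenerics::start(cores)[ci]
    ce <- BiocGenerics::end(cores)[ci]
    p5 <- .fivePrime(fr)
    off <- p5 - cs
    inWin <- !is.na(ci) & p5 >= cs - W & p5 <= ce + W
    dt <- data.table::data.table(
      offset = off[inWin],
      strand = as.character(BiocGenerics::strand(fr))[inWin],
      sample = fr$sample[inWin])
    if (nrow(dt))
      counts <- dt[, list(value = as.numeric(.N)),
                   by = c("offset", "strand", "sample")]
  }
  methods::new("NucleotideProfile",
               values = .denseGrid(counts, offsets, samples),
               mode = "START_SITES", normalisation = "RAW",
               windowBp = W, classes = classes)
}

#' CPM-normalise a raw profile and aggregate by condition
#'
#' Each sample's contribution is scaled by \code{1e6 / totalFragments}
#' (counts per million mapped fragments, the library-depth normalisation)
#' before the samples of a condition are combined by sum (default, as for
#' tallies) or mean (as in the published figures).
#'
#' @param profile a RAW \code{NucleotideProfile}.
#' @param sheet sample sheet supplying per-sample totals and conditions.
#' @param aggregate \code{"sum"} or \code{"mean"} across the samples of a
#'   condition.
#' @return a CPM \code{NucleotideProfile} with per-condition values.
#'   Normalising an already-CPM profile is an error (the operation is not
#'   idempotent and a second pass would be meaningless).
#' @export
cpmNormalise <- function(profile, sheet, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (profileNormalisation(profile) == "CPM")
    stop("profile is already CPM-normalised", call. = FALSE)
  validateSampleSheet(sheet)
  vals <- data.table::as.data.table(profileValues(profile))
  sheetDt <- data.table::as.data.table(
    sheet[, c("sample", "condition", "totalFragments")])
  unknown <- setdiff(unique(vals$sample), sheetDt$sample)
  if (length(unknown))
    stop("sample(s) missing from sheet: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  used <- sheetDt[sheetDt$sample %in% unique(vals$sample)]
  if (any(used$totalFragments == 0))
    stop("totalFragments is zero for sample(s): ",
         paste(used$sample[used$totalFragments == 0], collapse = ", "),
         call. = FALSE)
  m <- merge(vals, used, by = "sample")
  m$value <- m$value * 1e6 / m$totalFragments
  value <- NULL # NSE
  agg <- m[, list(value = if (aggregate == "sum") sum(value)
                  else mean(value)),
           by = c("offset", "strand", "condition")]
  data.table::setorderv(agg, c("condition", "strand", "offset"))
  methods::new("NucleotideProfile",
               values = as.data.frame(agg),
               mode = profileMode(profile), normalisation = "CPM",
               windowBp = profile@windowBp, classes = profile@classes)
}

#' Count fragment start sites in a region
#'
#' Returns both the number of distinct genomic positions carrying at least
#' one strand-aware fragment 5' end inside \code{region}, and the total
#' number of such 5' ends. The distinct-position count is the readout used
#' to detect de novo initiation (new start sites) rather than increased
#' firing of existing ones.
#'
#' @param classified GRanges of (classified) fragments.
#' @param region GRanges region(s) to count in.
#' @return list with elements \code{distinct} and \code{total}.
#' @export
startSiteCount <- function(classified, region) {
  if (length(classified) == 0L) return(list(distinct = 0L, total = 0L))
  p5 <- .fivePrime(classified)
  chr <- as.character(GenomeInfoDb::seqnames(classified))
  str <- as.character(BiocGenerics::strand(classified))
  pts <- GenomicRanges::GRanges(chr, IRanges::IRanges(p5, p5), strand = str)
  hit <- IRanges::overlapsAny(pts, region, ignore.strand = TRUE)
  key <- paste(chr[hit], p5[hit], str[hit])
  list(distinct = length(unique(key)), total = sum(hit))
}

#' Export a raw profile plus its CPM rendering as a tidy table
#'
#' Writes columns (offset, strand, condition, raw, cpm); raw values are
#' summed over the samples of each condition, cpm values follow
#' \code{\link{cpmNormalise}}.
#'
#' @param profile a RAW \code{NucleotideProfile}.
#' @param sheet sample sheet.
#' @param path output TSV path.
#' @param aggregate passed to \code{\link{cpmNormalise}}.
#' @return invisibly, the exported data.frame.
#' @export
exportProfile <- function(profile, sheet, path,
                          aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (profileNormalisation(profile) != "RAW")
    stop("export starts from a RAW profile", call. = FALSE)
  vals <- data.table::as.data.table(profileValues(profile))
  sheetDt <- data.table::as.data.table(sheet[, c("sample", "condition")])
  m <- merge(vals, sheetDt, by = "sample")
  value <- NULL # NSE
  raw <- m[, list(raw = sum(value)), by = c("offset", "strand", "condition")]
  cpm <- data.table::as.data.table(
    profileValues(cpmNormalise(profile, sheet, aggregate = aggregate)))
  data.table::setnames(cpm, "value", "cpm")
  out <- merge(raw, cpm, by = c("offset", "strand", "condition"))
  data.table::setorderv(out, c("condition", "strand", "offset"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(as.data.frame(out))
}
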