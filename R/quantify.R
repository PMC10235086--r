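#' Fold ratio of two counts
#'
#' Exact quotient, with the conventional two-significant-figure display
#' value alongside (98/42 prints as 2.3, 16369/42 as 390).
#'
#' @param numerator,denominator non-negative counts; the denominator must
#'   be positive.
#' @return named list with \code{value} (full precision) and
#'   \code{display} (2 significant figures).
#' @export
#' @examples
#' foldRatio(98, 42)$display    # 2.3
#' foldRatio(16369, 42)$display # 390
foldRatio <- function(numerator, denominator) {
  if (!is.numeric(numerator) || !is.numeric(denominator) ||
      length(numerator) != 1L || length(denominator) != 1L)
    stop("numerator and denominator must be single numbers", call. = FALSE)
  if (!is.finite(denominator) || denominator <= 0)
    stop("denominator must be > 0", call. = FALSE)
  v <- numerator / denominator
  list(value = v, display = signif2(v))
}

#' Per-condition abundance table from a tally
#'
#' Sums fragment counts per (condition, class) and per (condition, class,
#' length class).
#'
#' @param tally output of \code{\link{tallyFragments}}.
#' @return data.frame with columns condition, tclass, lengthClass
#'   (\code{"ALL"} for the class marginal), count.
#' @export
abundanceTable <- function(tally) {
  dt <- data.table::as.data.table(tally)
  count <- NULL # NSE
  byClass <- dt[, list(count = sum(count)), by = c("condition", "tclass")]
  byClass$lengthClass <- "ALL"
  byLen <- dt[dt$lengthClass != "NONE",
              list(count = sum(count)),
              by = c("condition", "tclass", "lengthClass")]
  out <- rbind(byClass[, c("condition", "tclass", "lengthClass", "count")],
               byLen[, c("condition", "tclass", "lengthClass", "count")])
  data.table::setorderv(out, c("condition", "tclass", "lengthClass"))
  as.data.frame(out)
}

.lookupCount <- function(ab, condition, tclass, lengthClass = "ALL") {
  i <- ab$condition == condition & ab$tclass == tclass &
    ab$lengthClass == lengthClass
  if (!any(i)) NA_real_ else sum(ab$count[i])
}

#' Headline class-ratio and fold report
#'
#' From per-condition class counts, emits the noncoding-pericentromeric to
#' centromeric ratio per condition, the coding to noncoding ratio per
#' condition, the auxin/mock fold per class, and the relative change of
#' the noncoding:CEN ratio between conditions. With the published counts
#' (mock CEN 42, noncoding 16,369; auxin CEN 98, noncoding 30,346) the
#' displayed values are 390 and 310 (ratios), 2.3 and 1.9 (folds).
#'
#' @param ab output of \code{\link{abundanceTable}} (or a tally, which is
#'   converted).
#' @return data.frame with columns statistic, condition, value, display;
#'   rows with a missing class are omitted with a warning.
#' @export
classRatioReport <- function(ab) {
  if (all(c("termClass", "count") %in% names(ab)) && "sample" %in% names(ab))
    ab <- abundanceTable(ab)
  rows <- list()
  add <- function(statistic, condition, value) {
    if (is.na(value)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = statistic, condition = condition,
      value = value, display = signif2(value))
  }
  ratios <- c(mock = NA_real_, auxin = NA_real_)
  for (cond in c("mock", "auxin")) {
    cen <- .lookupCount(ab, cond, "CEN")
    pn <- .lookupCount(ab, cond, "PERICEN_NONCODING")
    pc <- .lookupCount(ab, cond, "PERICEN_CODING")
    if (is.na(cen) || is.na(pn) || cen == 0) {
      warning("noncoding:CEN ratio not computable for condition '", cond,
              "'", call. = FALSE)
    } else {
      ratios[cond] <- pn / cen
      add("noncoding_pericen_to_cen_ratio", cond, pn / cen)
    }
    if (!is.na(pc) && !is.na(pn) && pn > 0)
      add("coding_to_noncoding_pericen_ratio", cond, pc / pn)
  }
  for (cls in c("CEN", "PERICEN_NONCODING", "PERICEN_CODING")) {
    mo <- .lookupCount(ab, "mock", cls)
    au <- .lookupCount(ab, "auxin", cls)
    if (!is.na(mo) && !is.na(au) && mo > 0)
      add(paste0("auxin_mock_fold_", cls), "auxin/mock", au / mo)
  }
  for (lc in c("SHORT", "LONG")) {
    mo <- .lookupCount(ab, "mock", "CEN", lc)
    au <- .lookupCount(ab, "auxin", "CEN", lc)
    if (!is.na(mo) && !is.na(au) && mo > 0)
      add(paste0("auxin_mock_fold_CEN_", lc), "auxin/mock", au / mo)
  }
  if (all(!is.na(ratios)) && ratios["mock"] > 0)
    add("ratio_change_auxin_vs_mock", "auxin/mock",
        ratios[["auxin"]] / ratios[["mock"]])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Absolute abundance calibrated against reference genes
#'
#' Estimates molecules per cell for a target from its fragment count,
#' calibrating against reference genes of known copies per cell. Counts
#' are length-density normalised (reads per bp) before calibration, since
#' a ~117 bp core and kb-scale mRNAs are otherwise incomparable: per
#' reference i, \code{k_i = (count_i / length_i) / copiesPerCell_i}; the
#' estimate is \code{(targetCount / targetLength) / mean(k_i)} and its
#' uncertainty is the SEM across references propagated through the mean
#' (first-order).
#'
#' @param targetCount fragment count of the target feature.
#' @param targetLength target feature length in bp.
#' @param refs data.frame with columns id, length, copiesPerCell, count.
#' @param normaliseByLength set \code{FALSE} to calibrate on raw counts.
#' @return list with \code{estimate} (molecules per cell), \code{sem}
#'   (NA with a single reference) and the per-reference calibration
#'   factors \code{k}.
#' @export
moleculesPerCell <- function(targetCount, targetLength, refs,
                             normaliseByLength = TRUE) {
  .assertFlag(normaliseByLength, "normaliseByLength")
  need <- c("id", "length", "copiesPerCell", "count")
  if (!all(need %in% names(refs)))
    stop("refs must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(refs) < 1L || all(refs$count == 0))
    stop("at least one reference with count > 0 is required", call. = FALSE)
  if (any(refs$copiesPerCell <= 0))
    stop("copiesPerCell must be > 0", call. = FALSE)
  dens <- if (normaliseByLength) refs$count / refs$length else refs$count
  k <- dens / refs$copiesPerCell
  names(k) <- refs$id
  targetDens <- if (normaliseByLength) targetCount / targetLength
                else targetCount
  est <- targetDens / mean(k)
  sem <- if (length(k) > 1L) {
    semK <- stats::sd(k) / sqrt(length(k))
    est * semK / mean(k)
  } else NA_real_
  list(estimate = est, sem = sem, k = k)
}

#' Relative expression by the comparative Cq method
#'
#' Classic delta-delta-Cq: \code{dCq = Cq_target - Cq_reference} within
#' each arm, \code{ddCq = dCq_treated - dCq_control}; the fold change is
#' \code{2^-ddCq} (one qPCR cycle corresponds to a doubling).
#'
#' @param cqTargetTreated,cqRefTreated,cqTargetControl,cqRefControl
#'   quantification-cycle values; all four must be finite.
#' @param cqBand optional length-2 validation band for plausible Cq values
#'   (default 10-40); \code{NULL} disables.
#' @return list with \code{fold} (\code{2^-ddCq}), \code{log2Fold}
#'   (\code{-ddCq}) and \code{ddCq}.
#' @export
#' @examples
#' ddcqFold(20, 15, 24, 15)$fold # 16
ddcqFold <- function(cqTargetTreated, cqRefTreated,
                     cqTargetControl, cqRefControl,
                     cqBand = c(10, 40)) {
  cq <- c(cqTargetTreated, cqRefTreated, cqTargetControl, cqRefControl)
  if (length(cq) != 4L || any(!is.finite(cq)))
    stop("all four Cq values must be single finite numbers", call. = FALSE)
  if (!is.null(cqBand) && any(cq < cqBand[1] | cq > cqBand[2]))
    stop("Cq value outside plausible band [", cqBand[1], ", ", cqBand[2],
         "]; widen 'cqBand' if intended", call. = FALSE)
  ddCq <- (cqTargetTreated - cqRefTreated) -
    (cqTargetControl - cqRefControl)
  list(fold = 2^(-ddCq), log2Fold = -ddCq, ddCq = ddCq)
}

#' Read a reference-gene table
#'
#' Tab-separated with header columns id, chrom, start, end, copiesPerCell
#' and optionally count; a length column (end - start + 1) is added.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readReferenceGenes <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("id", "chrom", "start", "end", "copiesPerCell")
  if (!all(need %in% names(df)))
    stop("reference table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(df$copiesPerCell <= 0))
    stop("copiesPerCell must be > 0", call. = FALSE)
  df$length <- df$end - df$start + 1L
  df
}
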