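#' @importFrom methods new validObject is slot setClass setGeneric setMethod setValidity show
#' @importFrom stats rpois rlnorm rbinom runif median sd
#' @importFrom utils head
#' @importFrom data.table data.table := .N
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round to two significant figures for display
#'
#' Headline ratios and folds are conventionally reported at two significant
#' figures (e.g. 389.7 prints as 390, 2.333 as 2.3). Full precision is always
#' retained in machine-readable columns; this helper only produces the
#' display value.
#'
#' @param x numeric vector.
#' @return `x` rounded to two significant figures.
#' @export
#' @examples
#' signif2(c(389.7, 2.333, 1.853))
signif2 <- function(x) signif(x, 2L)

.assertFlag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", what), call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x) || (positive && x == 0))
    stop(sprintf("'%s' must be a single %s integer", what,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  invisible(as.integer(x))
}

## strand-aware 5' position of a fragment span (1-based, closed coordinates)
.fivePrime <- function(gr) {
  ifelse(as.character(BiocGenerics::strand(gr)) == "-",
         BiocGenerics::end(gr), BiocGenerics::start(gr))
}

.TCLASSES <- c("CEN", "PERICEN_NONCODING", "PERICEN_CODING", "OTHER")
.TERM_CLASSES <- c("FULL_CEN", "CDEI", "CDEII", "CDEIII", "NONE")
.LENGTH_CLASSES <- c("SHORT", "LONG", "NONE")
.SIDES <- c("UP", "DOWN", "BOTH", "NONE")
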