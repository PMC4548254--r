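#' @import methods
NULL

.LABELS <- c("TP", "FP", "TN")

#' AlignerComparison: per-read joint classification of two alignment results
#'
#' Holds one scenario call per read (scenario 1-8 plus the TP/FP/TN label it
#' implies for each aligner) together with side labels and join diagnostics.
#' Construct with [compareAlignments()]; inspect with [scenarioCalls()],
#' [scenarioCounts()] and [tallyCounts()].
#'
#' @slot calls data.frame with columns `read_key`, `scenario`, `label_a`,
#'   `label_b` (labels are `"TP"`, `"FP"`, `"TN"` or `NA` when a side
#'   contributes nothing, scenarios 6/8).
#' @slot labels character(2), display names of the two aligners.
#' @slot diagnostics list with counts `only_in_a`, `only_in_b`
#'   (read keys seen in one file only) and `unmapped_both` (reads skipped
#'   because neither aligner mapped them).
#' @slot maxOverhang numeric(1), splice-overhang threshold used (a spliced
#'   alignment with minimum overhang <= this is a false positive).
#' @export
setClass("AlignerComparison",
  slots = c(calls = "data.frame", labels = "character",
            diagnostics = "list", maxOverhang = "numeric"))

setValidity("AlignerComparison", function(object) {
  msgs <- character(0)
  need <- c("read_key", "scenario", "label_a", "label_b")
  if (!all(need %in% names(object@calls)))
    msgs <- c(msgs, "calls must have columns read_key, scenario, label_a, label_b")
  else {
    if (!all(object@calls$scenario %in% 1:8))
      msgs <- c(msgs, "scenario must be in 1..8")
    ok <- function(x) all(is.na(x) | x %in% .LABELS)
    if (!ok(object@calls$label_a) || !ok(object@calls$label_b))
      msgs <- c(msgs, "labels must be TP, FP, TN or NA")
    if (anyDuplicated(object@calls$read_key))
      msgs <- c(msgs, "each read key must be classified exactly once")
  }
  if (length(object@labels) != 2L)
    msgs <- c(msgs, "labels must name exactly two aligners")
  if (length(object@maxOverhang) != 1L || object@maxOverhang < 1)
    msgs <- c(msgs, "maxOverhang must be a single value >= 1")
  if (length(msgs)) msgs else TRUE
})

#' BootstrapResult: paired bootstrap comparison of specificity and accuracy
#'
#' Point estimates of specificity and accuracy per aligner, their differences
#' (side A minus side B), percentile confidence bounds over with-replacement
#' resamples of reads, and significance flags (a difference is significant
#' when its interval excludes zero). Construct with [bootstrapDifference()].
#'
#' @slot estimates named numeric: `spec_a`, `spec_b`, `acc_a`, `acc_b`.
#' @slot diff named numeric: `spec`, `acc` (A minus B, from the full data).
#' @slot ci 2x2 numeric matrix, rows `spec`/`acc`, columns `lower`/`upper`.
#' @slot significant named logical: `spec`, `acc`.
#' @slot nBoot,level,seed bootstrap configuration echoed for provenance.
#' @slot dropped named numeric: replicates excluded per metric because a
#'   resample left that metric's denominator zero.
#' @export
setClass("BootstrapResult",
  slots = c(estimates = "numeric", diff = "numeric", ci = "matrix",
            significant = "logical", nBoot = "numeric", level = "numeric",
            seed = "numeric", dropped = "numeric"))

setValidity("BootstrapResult", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@ci), c(2L, 2L)))
    msgs <- c(msgs, "ci must be a 2x2 matrix (spec/acc x lower/upper)")
  else if (any(object@ci[, 1L] > object@ci[, 2L], na.rm = TRUE))
    msgs <- c(msgs, "ci lower bound must not exceed upper bound")
  if (object@level <= 0 || object@level >= 1)
    msgs <- c(msgs, "level must be in (0, 1)")
  if (object@nBoot < 1) msgs <- c(msgs, "nBoot must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' ComparisonReport: end-to-end result of comparing two alignment files
#'
#' Bundles the scenario classification, the bootstrap comparison, and a
#' verdict: the side with significantly higher specificity AND accuracy is
#' selected; if neither difference is significant the verdict is
#' `"no significant difference"`; partial or opposed significance is
#' `"mixed"`. Construct with [runComparison()]; serialize with
#' [writeReport()].
#'
#' @slot comparison An [AlignerComparison-class] object.
#' @slot bootstrap A [BootstrapResult-class] object.
#' @slot verdict character(1) verdict string.
#' @export
setClass("ComparisonReport",
  slots = c(comparison = "AlignerComparison", bootstrap = "BootstrapResult",
            verdict = "character"))
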