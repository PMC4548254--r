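#' Per-read scenario calls
#'
#' @param x An [AlignerComparison-class] or [ComparisonReport-class] object.
#' @return data.frame with columns `read_key`, `scenario`, `label_a`,
#'   `label_b`.
#' @export
setGeneric("scenarioCalls", function(x) standardGeneric("scenarioCalls"))

#' @rdname scenarioCalls
#' @export
setMethod("scenarioCalls", "AlignerComparison", function(x) x@calls)

#' @rdname scenarioCalls
#' @export
setMethod("scenarioCalls", "ComparisonReport",
          function(x) scenarioCalls(x@comparison))

#' Read counts per scenario
#'
#' @param x An [AlignerComparison-class] or [ComparisonReport-class] object.
#' @return Named integer vector of length 8 (scenarios `"1"`..`"8"`).
#' @export
setGeneric("scenarioCounts", function(x) standardGeneric("scenarioCounts"))

#' @rdname scenarioCounts
#' @export
setMethod("scenarioCounts", "AlignerComparison", function(x) {
  tab <- table(factor(x@calls$scenario, levels = 1:8))
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname scenarioCounts
#' @export
setMethod("scenarioCounts", "ComparisonReport",
          function(x) scenarioCounts(x@comparison))

#' Per-aligner TP/FP/TN tallies
#'
#' @param x An [AlignerComparison-class] or [ComparisonReport-class] object.
#' @return 2x3 integer matrix with rows named after the two aligner labels
#'   and columns `TP`, `FP`, `TN`.
#' @export
setGeneric("tallyCounts", function(x) standardGeneric("tallyCounts"))

#' @rdname tallyCounts
#' @export
setMethod("tallyCounts", "AlignerComparison", function(x) {
  count <- function(lab) {
    tab <- table(factor(lab, levels = .LABELS))
    stats::setNames(as.integer(tab), names(tab))
  }
  m <- rbind(count(x@calls$label_a), count(x@calls$label_b))
  rownames(m) <- x@labels
  m
})

#' @rdname tallyCounts
#' @export
setMethod("tallyCounts", "ComparisonReport", function(x) tallyCounts(x@comparison))

#' Aligner display labels
#'
#' @param x An [AlignerComparison-class] or [ComparisonReport-class] object.
#' @return character(2).
#' @export
setGeneric("alignerLabels", function(x) standardGeneric("alignerLabels"))

#' @rdname alignerLabels
#' @export
setMethod("alignerLabels", "AlignerComparison", function(x) x@labels)

#' @rdname alignerLabels
#' @export
setMethod("alignerLabels", "ComparisonReport", function(x) x@comparison@labels)

#' Verdict of a comparison
#'
#' @param x A [ComparisonReport-class] object.
#' @return character(1).
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname verdict
#' @export
setMethod("verdict", "ComparisonReport", function(x) x@verdict)

#' Bootstrap component of a report
#'
#' @param x A [ComparisonReport-class] object.
#' @return A [BootstrapResult-class] object.
#' @export
setGeneric("bootstrapResult", function(x) standardGeneric("bootstrapResult"))

#' @rdname bootstrapResult
#' @export
setMethod("bootstrapResult", "ComparisonReport", function(x) x@bootstrap)

#' Confidence bounds of the metric differences
#'
#' @param x A [BootstrapResult-class] object.
#' @return 2x2 numeric matrix (rows `spec`, `acc`; columns `lower`, `upper`).
#' @export
setGeneric("confint2", function(x) standardGeneric("confint2"))

#' @rdname confint2
#' @export
setMethod("confint2", "BootstrapResult", function(x) x@ci)

setMethod("show", "AlignerComparison", function(object) {
  cat("AlignerComparison:", object@labels[1L], "vs", object@labels[2L], "\n")
  cat("  reads classified:", nrow(object@calls),
      "| overhang threshold:", object@maxOverhang, "nt\n")
  sc <- scenarioCounts(object)
  cat("  scenarios:", paste(sprintf("s%s=%d", names(sc), sc), collapse = " "), "\n")
  t <- tallyCounts(object)
  for (i in 1:2)
    cat(sprintf("  %s: TP=%d FP=%d TN=%d\n", rownames(t)[i],
                t[i, "TP"], t[i, "FP"], t[i, "TN"]))
  d <- object@diagnostics
  if (length(d))
    cat(sprintf("  diagnostics: only_in_a=%d only_in_b=%d unmapped_both=%d\n",
                d$only_in_a, d$only_in_b, d$unmapped_both))
  invisible(object)
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult (paired percentile bootstrap)\n")
  cat(sprintf("  n_boot=%d level=%.2f seed=%d\n",
              as.integer(object@nBoot), object@level, as.integer(object@seed)))
  e <- object@estimates
  cat(sprintf("  specificity: A=%.4f B=%.4f diff=%+.4f CI [%.4f, %.4f]%s\n",
              e["spec_a"], e["spec_b"], object@diff["spec"],
              object@ci["spec", "lower"], object@ci["spec", "upper"],
              if (isTRUE(object@significant["spec"])) " *" else ""))
  cat(sprintf("  accuracy:    A=%.4f B=%.4f diff=%+.4f CI [%.4f, %.4f]%s\n",
              e["acc_a"], e["acc_b"], object@diff["acc"],
              object@ci["acc", "lower"], object@ci["acc", "upper"],
              if (isTRUE(object@significant["acc"])) " *" else ""))
  if (any(object@dropped > 0))
    cat("  degenerate replicates dropped:",
        paste(sprintf("%s=%d", names(object@dropped),
                      as.integer(object@dropped)), collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "ComparisonReport", function(object) {
  show(object@comparison)
  show(object@bootstrap)
  cat("Verdict:", object@verdict, "\n")
  invisible(object)
})
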