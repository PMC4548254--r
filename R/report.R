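.verdictString <- function(boot, labels) {
  sig <- boot@significant
  d <- boot@diff
  if (!any(sig)) return("no significant difference")
  if (all(sig) && sign(d["spec"]) == sign(d["acc"]) && d["spec"] != 0) {
    side <- if (d["spec"] > 0) labels[1L] else labels[2L]
    return(sprintf("%s selected (significantly higher specificity and accuracy)",
                   side))
  }
  "mixed"
}

#' Compare two alignment files end to end
#'
#' Runs the full evaluation: classifies every read's joint mapping outcome
#' across the two files, tallies TP/FP/TN per aligner, computes specificity
#' and accuracy, bootstraps the paired differences, and derives a verdict.
#' The side with significantly higher specificity AND accuracy (both
#' confidence intervals excluding zero, same direction) is selected;
#' otherwise the verdict is "no significant difference" or "mixed".
#'
#' @inheritParams compareAlignments
#' @param nBoot,level,seed Bootstrap settings, see [bootstrapDifference()].
#' @param scenarioTsv Optional path: write the per-read scenario calls as
#'   TSV (`read_key`, `scenario`, `label_a`, `label_b`).
#' @return A [ComparisonReport-class] object.
#' @examples
#' fx <- builtinWorkedExamples()
#' rep <- runComparison(fx$path_a, fx$path_b, labels = c("A", "B"),
#'                      nBoot = 200, seed = 1)
#' verdict(rep)
#' @export
runComparison <- function(pathA, pathB, labels = c("A", "B"),
                          maxOverhang = 2L, nBoot = 10000L, level = 0.95,
                          seed = 1001L, scenarioTsv = NULL) {
  cmp <- compareAlignments(pathA, pathB, labels = labels,
                           maxOverhang = maxOverhang)
  boot <- bootstrapDifference(cmp, nBoot = nBoot, level = level, seed = seed)
  if (!is.null(scenarioTsv))
    utils::write.table(scenarioCalls(cmp), scenarioTsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  new("ComparisonReport", comparison = cmp, bootstrap = boot,
      verdict = .verdictString(boot, labels))
}

#' Flatten a report to a named list
#'
#' @param report A [ComparisonReport-class] object.
#' @return A named list with scenario counts, per-aligner tallies, metrics,
#'   interval bounds, significance flags, verdict, and the bootstrap
#'   configuration -- the structure serialized by [writeReport()].
#' @export
reportAsList <- function(report) {
  cmp <- report@comparison; boot <- report@bootstrap
  t <- tallyCounts(cmp)
  sc <- scenarioCounts(cmp)
  list(
    labels = cmp@labels,
    n_reads = nrow(cmp@calls),
    scenario_counts = as.list(stats::setNames(as.integer(sc),
                                              paste0("s", names(sc)))),
    tallies = list(
      a = as.list(t[1L, ]),
      b = as.list(t[2L, ])),
    metrics = as.list(boot@estimates),
    differences = as.list(boot@diff),
    ci = list(spec = as.list(boot@ci["spec", ]),
              acc = as.list(boot@ci["acc", ])),
    significant = as.list(boot@significant),
    verdict = report@verdict,
    config = list(max_overhang = cmp@maxOverhang,
                  n_boot = as.integer(boot@nBoot), level = boot@level,
                  seed = as.integer(boot@seed)),
    diagnostics = cmp@diagnostics)
}

#' Write a comparison report to disk
#'
#' @param report A [ComparisonReport-class] object.
#' @param path Output file.
#' @param format `"json"` or `"tsv"` (flat key/value table).
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  x <- reportAsList(report)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    flat <- unlist(x)
    utils::write.table(
      data.frame(key = names(flat), value = as.character(flat)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
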