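#' Specificity (true-negative rate) of one alignment result
#'
#' Specificity = TN / (TN + FP). Non-uniquely mapped reads form the negative
#' set and are all counted as true negatives; false positives are uniquely
#' mapped reads judged unreliable by the scenario classification. False
#' negatives are not considered.
#'
#' @param tp,fp,tn Non-negative counts of true-positive, false-positive and
#'   true-negative read alignments. `tp` does not enter the formula and is
#'   accepted for interface symmetry with [accuracy()].
#' @return Fraction in \[0, 1\].
#' @export
specificity <- function(tp, fp, tn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0)
  if (tn + fp == 0)
    stop("specificity is undefined when TN + FP == 0")
  tn / (tn + fp)
}

#' Accuracy of one alignment result
#'
#' Accuracy = (TP + TN) / (TP + FP + TN). False-negative alignments are
#' deliberately excluded: the method looks for false positives within the
#' uniquely mapped (positive) set only.
#'
#' @inheritParams specificity
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(tp, fp, tn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0)
  if (tp + fp + tn == 0)
    stop("accuracy is undefined when TP + FP + TN == 0")
  (tp + tn) / (tp + fp + tn)
}

# integer-code a label vector: TP=1, FP=2, TN=3, NA/none=0
.codeLabels <- function(x) {
  code <- match(x, .LABELS)
  code[is.na(code)] <- 0L
  code
}

# spec/acc for count triples; NA when the denominator is zero
.specVec <- function(tp, fp, tn) {
  den <- tn + fp
  ifelse(den > 0, tn / den, NA_real_)
}
.accVec <- function(tp, fp, tn) {
  den <- tp + fp + tn
  ifelse(den > 0, (tp + tn) / den, NA_real_)
}

#' Paired bootstrap comparison of specificity and accuracy
#'
#' Resamples reads (each read's pair of outcome labels, keeping the pairing)
#' with replacement, recomputes both aligners' specificity and accuracy on
#' every replicate, and returns percentile confidence intervals for the
#' differences (side A minus side B). Point estimates come from the
#' unresampled tallies. A difference is significant when its interval
#' excludes zero. Reads labelled on one side only (scenarios 6/8) are
#' resampled like any other read and contribute to that side's counts only.
#' Replicates in which a metric's denominator is zero are dropped from that
#' metric's percentiles; the count of dropped replicates is retained.
#'
#' Identical inputs and seed give bit-identical results; the caller's random
#' number generator state is left untouched.
#'
#' @param x An [AlignerComparison-class] object, or a data.frame with
#'   columns `label_a` and `label_b` (values `"TP"`, `"FP"`, `"TN"` or NA).
#' @param nBoot Number of bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.95); bounds are the
#'   `(1-level)/2` and `1-(1-level)/2` empirical percentiles.
#' @param seed Integer seed for the resampling stream.
#' @param labels character(2) used only when `x` is a data.frame.
#' @return A [BootstrapResult-class] object.
#' @examples
#' outc <- data.frame(
#'   label_a = c("TP", "TP", "FP", "TN"),
#'   label_b = c("TP", "FP", "FP", "TN"))
#' bootstrapDifference(outc, nBoot = 200, seed = 7)
#' @export
setGeneric("bootstrapDifference",
  function(x, nBoot = 10000L, level = 0.95, seed = 1001L, ...)
    standardGeneric("bootstrapDifference"))

#' @rdname bootstrapDifference
#' @export
setMethod("bootstrapDifference", "AlignerComparison",
  function(x, nBoot = 10000L, level = 0.95, seed = 1001L, ...)
    .bootstrapDifference(x@calls, nBoot, level, seed))

#' @rdname bootstrapDifference
#' @export
setMethod("bootstrapDifference", "data.frame",
  function(x, nBoot = 10000L, level = 0.95, seed = 1001L,
           labels = c("A", "B"), ...)
    .bootstrapDifference(x, nBoot, level, seed))

.bootstrapDifference <- function(outcomes, nBoot, level, seed) {
  stopifnot(is.data.frame(outcomes),
            all(c("label_a", "label_b") %in% names(outcomes)))
  n <- nrow(outcomes)
  if (n == 0L) stop("no per-read outcomes to resample")
  nBoot <- as.integer(nBoot)
  stopifnot(nBoot >= 1L, level > 0, level < 1)
  ca <- .codeLabels(outcomes$label_a)
  cb <- .codeLabels(outcomes$label_b)

  countSide <- function(code, idxMat) {
    # idxMat: n x k matrix of resampled read indices
    lab <- matrix(code[idxMat], nrow = nrow(idxMat))
    list(tp = .colSums(lab == 1L, nrow(lab), ncol(lab)),
         fp = .colSums(lab == 2L, nrow(lab), ncol(lab)),
         tn = .colSums(lab == 3L, nrow(lab), ncol(lab)))
  }

  dspec <- numeric(nBoot); dacc <- numeric(nBoot)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  chunk <- max(1L, min(nBoot, as.integer(5e6 / n)))
  done <- 0L
  while (done < nBoot) {
    k <- min(chunk, nBoot - done)
    idx <- matrix(sample.int(n, n * k, replace = TRUE), nrow = n)
    a <- countSide(ca, idx); b <- countSide(cb, idx)
    sl <- done + seq_len(k)
    dspec[sl] <- .specVec(a$tp, a$fp, a$tn) - .specVec(b$tp, b$fp, b$tn)
    dacc[sl]  <- .accVec(a$tp, a$fp, a$tn) - .accVec(b$tp, b$fp, b$tn)
    done <- done + k
  }

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pct <- function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(c(NA_real_, NA_real_))
    stats::quantile(d, probs, names = FALSE)
  }
  ciSpec <- pct(dspec); ciAcc <- pct(dacc)
  ci <- matrix(c(ciSpec, ciAcc), nrow = 2L, byrow = TRUE,
               dimnames = list(c("spec", "acc"), c("lower", "upper")))

  tally <- function(code) c(tp = sum(code == 1L), fp = sum(code == 2L),
                            tn = sum(code == 3L))
  ta <- tally(ca); tb <- tally(cb)
  est <- c(spec_a = .specVec(ta["tp"], ta["fp"], ta["tn"]),
           spec_b = .specVec(tb["tp"], tb["fp"], tb["tn"]),
           acc_a  = .accVec(ta["tp"], ta["fp"], ta["tn"]),
           acc_b  = .accVec(tb["tp"], tb["fp"], tb["tn"]))
  names(est) <- c("spec_a", "spec_b", "acc_a", "acc_b")
  dif <- c(spec = unname(est["spec_a"] - est["spec_b"]),
           acc  = unname(est["acc_a"] - est["acc_b"]))
  sig <- c(spec = !anyNA(ciSpec) && (ciSpec[1] > 0 || ciSpec[2] < 0),
           acc  = !anyNA(ciAcc) && (ciAcc[1] > 0 || ciAcc[2] < 0))
  new("BootstrapResult",
      estimates = est, diff = dif, ci = ci, significant = sig,
      nBoot = as.numeric(nBoot), level = level, seed = as.numeric(seed),
      dropped = c(spec = sum(is.na(dspec)), acc = sum(is.na(dacc))))
}
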