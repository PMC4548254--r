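#' Do two mapped records describe the exact same alignment?
#'
#' True when both records place the read on the same reference sequence and
#' strand with identical reference-block structure (same block starts, ends
#' and count). Differences confined to soft clipping or insertions that do
#' not move any block boundary are ignored by construction.
#'
#' @param recA,recB One-row data.frames (or lists) with fields `rname`,
#'   `strand`, `pos`, `cigar`, as in [readAlignments()] rows; both mapped.
#' @return Logical.
#' @export
sameAlignment <- function(recA, recB) {
  if (recA$rname != recB$rname || recA$strand != recB$strand) return(FALSE)
  ba <- referenceBlocks(recA$cigar, recA$pos)
  bb <- referenceBlocks(recB$cigar, recB$pos)
  nrow(ba) == nrow(bb) &&
    all(ba$start == bb$start) && all(ba$end == bb$end)
}

#' Do two mapped records overlap on the reference?
#'
#' True when the records are on the same reference and strand and at least
#' one reference block of one intersects a block of the other by one or more
#' bases. Alignments that share only an intron gap (block envelopes overlap
#' but no aligned base is shared) do not count as overlapping.
#'
#' @inheritParams sameAlignment
#' @return Logical.
#' @export
alignmentsOverlap <- function(recA, recB) {
  if (recA$rname != recB$rname || recA$strand != recB$strand) return(FALSE)
  ba <- referenceBlocks(recA$cigar, recA$pos)
  bb <- referenceBlocks(recB$cigar, recB$pos)
  for (i in seq_len(nrow(ba)))
    if (any(ba$start[i] <= bb$end & bb$start <= ba$end[i])) return(TRUE)
  FALSE
}

#' Label one unique alignment by the splice-overhang rule
#'
#' An un-spliced alignment, or a spliced alignment whose every splice gap is
#' anchored by more than `maxOverhang` read bases on both sides, is a true
#' positive; a spliced alignment with a minimum overhang of `maxOverhang`
#' (default 2) or fewer bases is a false positive, since such placements are
#' very likely wrong.
#'
#' @inheritParams sameAlignment
#' @param rec One-row data.frame/list with `cigar` and `pos`; mapped.
#' @param maxOverhang Largest overhang (in read bases) still called a false
#'   positive; default 2, i.e. one- and two-base anchors are false positives.
#' @return `"TP"` or `"FP"`.
#' @export
spliceLabel <- function(rec, maxOverhang = 2L) {
  oh <- minSpliceOverhang(rec$cigar, rec$pos)
  if (!is.na(oh) && oh <= maxOverhang) "FP" else "TP"
}

#' Classify one read's pair of mapping outcomes into a scenario
#'
#' Applies the eight-scenario decision table to the two record groups of one
#' read:
#' \describe{
#'   \item{both unique}{same alignment: scenario 1 (TP, TP); overlapping
#'     alignments: scenario 2/3 with each side labelled independently by
#'     [spliceLabel()] (reported as 3 when either side is FP, else 2);
#'     otherwise (different locations or opposite strands): scenario 4
#'     (FP, FP).}
#'   \item{unique vs non-unique}{scenario 5: the unique side is FP, the
#'     non-unique side TN.}
#'   \item{unique vs unmapped}{scenario 6: the mapping side is TP, the other
#'     contributes nothing (NA).}
#'   \item{both non-unique}{scenario 7 (TN, TN).}
#'   \item{non-unique vs unmapped}{scenario 8: the mapping side is TN, the
#'     other NA.}
#' }
#'
#' @param groupA,groupB Record data.frames for the same read key from the
#'   two aligners (zero rows = read absent from that file). Not both may be
#'   unmapped/absent.
#' @param maxOverhang See [spliceLabel()].
#' @return List with `read_key`, `scenario` (integer), `label_a`, `label_b`.
#' @export
classifyPair <- function(groupA, groupB, maxOverhang = 2L) {
  key <- if (nrow(groupA)) groupA$read_key[1L] else
         if (nrow(groupB)) groupB$read_key[1L] else
         stop("both groups are empty")
  sa <- resolveStatus(groupA)
  sb <- resolveStatus(groupB)
  if (sa == "unmapped" && sb == "unmapped")
    stop("read '", key, "' is unmapped/absent in both files; no scenario applies")
  if (sa == "unique" && sb == "unique") {
    ra <- .primaryRecord(groupA); rb <- .primaryRecord(groupB)
    if (sameAlignment(ra, rb)) {
      sc <- 1L; la <- "TP"; lb <- "TP"
    } else if (alignmentsOverlap(ra, rb)) {
      la <- spliceLabel(ra, maxOverhang)
      lb <- spliceLabel(rb, maxOverhang)
      sc <- if (la == "FP" || lb == "FP") 3L else 2L
    } else {
      sc <- 4L; la <- "FP"; lb <- "FP"
    }
  } else if (sa == "unique" && sb == "non-unique") {
    sc <- 5L; la <- "FP"; lb <- "TN"
  } else if (sa == "non-unique" && sb == "unique") {
    sc <- 5L; la <- "TN"; lb <- "FP"
  } else if (sa == "unique") {            # sb unmapped
    sc <- 6L; la <- "TP"; lb <- NA_character_
  } else if (sb == "unique") {            # sa unmapped
    sc <- 6L; la <- NA_character_; lb <- "TP"
  } else if (sa == "non-unique" && sb == "non-unique") {
    sc <- 7L; la <- "TN"; lb <- "TN"
  } else if (sa == "non-unique") {        # sb unmapped
    sc <- 8L; la <- "TN"; lb <- NA_character_
  } else {                                # sb non-unique, sa unmapped
    sc <- 8L; la <- NA_character_; lb <- "TN"
  }
  list(read_key = key, scenario = sc, label_a = la, label_b = lb)
}

#' Compare two alignment results read by read
#'
#' Reads both files, joins their record groups by read key (the join is
#' deterministic and independent of the two files' name orders), classifies
#' every read mapped by at least one aligner with [classifyPair()], and
#' returns an [AlignerComparison-class] object. Reads present in only one
#' file flow into scenarios 6/8; a warning reports their count so
#' accidentally mismatched read sets are noticed. Reads unmapped or absent
#' in both files carry no information and are skipped (counted in the
#' diagnostics).
#'
#' @param pathA,pathB SAM/BAM files from two aligners over the same reads,
#'   each name-grouped.
#' @param labels character(2) display names for the two sides.
#' @param maxOverhang Splice-overhang false-positive threshold, see
#'   [spliceLabel()].
#' @return An [AlignerComparison-class] object.
#' @examples
#' fx <- builtinWorkedExamples()
#' cmp <- compareAlignments(fx$path_a, fx$path_b,
#'                          labels = c("aligner-1", "aligner-2"))
#' scenarioCalls(cmp)
#' tallyCounts(cmp)
#' @export
compareAlignments <- function(pathA, pathB, labels = c("A", "B"),
                              maxOverhang = 2L) {
  grpsA <- alignmentGroups(readAlignments(pathA))
  grpsB <- alignmentGroups(readAlignments(pathB))
  keys <- c(names(grpsA), setdiff(names(grpsB), names(grpsA)))
  onlyA <- sum(!(names(grpsA) %in% names(grpsB)))
  onlyB <- sum(!(names(grpsB) %in% names(grpsA)))
  if (onlyA + onlyB > 0L)
    warning(onlyA, " read(s) only in ", labels[1L], " and ", onlyB,
            " only in ", labels[2L],
            "; treating absence as failure to map (scenarios 6/8)")
  empty <- utils::head(
    if (length(grpsA)) grpsA[[1L]][0L, , drop = FALSE]
    else if (length(grpsB)) grpsB[[1L]][0L, , drop = FALSE]
    else stop("both alignment files are empty"), 0L)
  n <- length(keys)
  scen <- integer(n); la <- character(n); lb <- character(n)
  keep <- logical(n); skipped <- 0L
  for (i in seq_len(n)) {
    k <- keys[i]
    ga <- if (!is.null(grpsA[[k]])) grpsA[[k]] else empty
    gb <- if (!is.null(grpsB[[k]])) grpsB[[k]] else empty
    if (resolveStatus(ga) == "unmapped" && resolveStatus(gb) == "unmapped") {
      skipped <- skipped + 1L
      next
    }
    call <- classifyPair(ga, gb, maxOverhang)
    scen[i] <- call$scenario; la[i] <- call$label_a; lb[i] <- call$label_b
    keep[i] <- TRUE
  }
  calls <- data.frame(read_key = keys[keep], scenario = scen[keep],
                      label_a = la[keep], label_b = lb[keep])
  rownames(calls) <- NULL
  new("AlignerComparison", calls = calls, labels = labels,
      diagnostics = list(only_in_a = onlyA, only_in_b = onlyB,
                         unmapped_both = skipped),
      maxOverhang = as.numeric(maxOverhang))
}
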