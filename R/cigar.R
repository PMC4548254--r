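#' Parse a CIGAR string into operations
#'
#' Splits a SAM CIGAR string into its ordered (operation, length) pairs.
#'
#' @param cigar A single CIGAR string, e.g. `"1M257N39M"`.
#' @return A data.frame with columns `op` (character) and `len` (integer),
#'   one row per operation in order.
#' @examples
#' cigarOps("5S20M3D10M")
#' @export
cigarOps <- function(cigar) {
  if (length(cigar) != 1L || is.na(cigar) || cigar == "" || cigar == "*")
    stop("cannot parse CIGAR: ", deparse(cigar))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!nzchar(cigar) || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar)
  data.frame(
    op  = substr(toks, nchar(toks), nchar(toks)),
    len = as.integer(substr(toks, 1L, nchar(toks) - 1L))
  )
}

#' Read length implied by a CIGAR
#'
#' Sums the lengths of read-consuming operations (M, I, S, =, X), giving the
#' length of the read sequence the CIGAR describes.
#'
#' @inheritParams cigarOps
#' @return Integer read length.
#' @export
cigarReadLength <- function(cigar) {
  ops <- cigarOps(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

#' Decompose an alignment into reference blocks split at splice gaps
#'
#' A block is a maximal run of reference-consuming CIGAR operations
#' (M, =, X, D) split only at N (splice/intron) operations. S, H, I and P
#' consume no reference and never open or close a block. Coordinates are
#' 1-based inclusive, as in SAM. Each block also carries the number of read
#' bases aligned within it (the sum of its M/=/X lengths) -- the quantity the
#' splice-overhang rule is computed from.
#'
#' @param cigar A CIGAR string for a mapped record.
#' @param pos 1-based leftmost reference position (SAM POS).
#' @return A data.frame with one row per block and columns `start`, `end`
#'   (1-based inclusive reference coordinates) and `read_bases`.
#' @examples
#' referenceBlocks("1M257N39M", 152318455)
#' referenceBlocks("5S20M3D10M", 100)
#' @export
referenceBlocks <- function(cigar, pos) {
  ops <- cigarOps(cigar)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("mapped record requires POS >= 1")
  refcon <- ops$op %in% c("M", "=", "X", "D")
  if (any(ops$op == "N")) {
    nidx <- which(ops$op == "N")
    # an N gap must be flanked by aligned reference on both sides
    if (!any(refcon[seq_len(min(nidx) - 1L)]) ||
        !any(refcon[seq_len(nrow(ops)) > max(nidx)]))
      stop("N operation at the start or end of CIGAR: ", cigar)
  }
  starts <- integer(0); ends <- integer(0); rb <- integer(0)
  cur <- pos
  bstart <- NA_integer_; bend <- NA_integer_; bread <- 0L
  flush <- function() {
    if (!is.na(bstart)) {
      starts <<- c(starts, bstart); ends <<- c(ends, bend); rb <<- c(rb, bread)
    }
    bstart <<- NA_integer_; bend <<- NA_integer_; bread <<- 0L
  }
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "N") {
      flush()
      cur <- cur + len
    } else if (refcon[i]) {
      if (is.na(bstart)) bstart <- cur
      bend <- cur + len - 1L
      cur <- cur + len
      if (op != "D") bread <- bread + len
    }
    # I, S, H, P: no reference consumed, block unchanged
  }
  flush()
  data.frame(start = starts, end = ends, read_bases = rb)
}

#' Minimum splice-junction overhang of a spliced alignment
#'
#' The overhang of a splice gap is the number of read bases aligned in a
#' reference block flanking that N gap. This returns the minimum overhang
#' over all blocks adjacent to an N operation, or `NA` for an un-spliced
#' alignment (no N in the CIGAR). A spliced alignment anchored by only one
#' or two bases on one side of an intron is very likely misplaced.
#'
#' @inheritParams referenceBlocks
#' @return Integer minimum overhang, or `NA_integer_` if the CIGAR has no N.
#' @examples
#' minSpliceOverhang("1M257N39M")  # 1
#' minSpliceOverhang("40M")        # NA
#' @export
minSpliceOverhang <- function(cigar, pos = 1L) {
  ops <- cigarOps(cigar)
  if (!any(ops$op == "N")) return(NA_integer_)
  blocks <- referenceBlocks(cigar, pos)
  # with >= 2 blocks every block flanks at least one N gap
  min(blocks$read_bases)
}
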