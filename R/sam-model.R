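#' Read alignment records from a SAM or BAM file
#'
#' Reads every record of a name-sorted (or at least name-grouped) SAM/BAM
#' file into a flat record table, in file order. BAM files are read through
#' \pkg{Rsamtools}; plain-text SAM is parsed directly. The uniqueness tag
#' NH:i is extracted when present.
#'
#' The read key is QNAME for single-end records; when the paired flag (0x1)
#' is set, `"/1"` or `"/2"` is appended according to the first/second-of-pair
#' flags, so each mate is treated as an independent read.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data.frame with one row per record, in file order, with columns
#'   `read_key`, `qname`, `flag`, `mapped`, `rname`, `strand`, `pos`,
#'   `cigar`, `nh`, `secondary`, `supplementary`.
#' @export
readAlignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar"),
      tag = "NH"
    )
    res <- Rsamtools::scanBam(path, param = p)[[1L]]
    df <- data.frame(
      qname = res$qname,
      flag  = as.integer(res$flag),
      rname = as.character(res$rname),
      pos   = as.integer(res$pos),
      cigar = as.character(res$cigar),
      nh    = if (is.null(res$tag$NH)) rep(NA_integer_, length(res$qname))
              else as.integer(res$tag$NH)
    )
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      df <- data.frame(qname = character(0), flag = integer(0),
                       rname = character(0), pos = integer(0),
                       cigar = character(0), nh = integer(0))
    } else {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      nf <- lengths(fields)
      if (any(nf < 11L))
        stop("malformed SAM record (fewer than 11 fields) at line ",
             which(nf < 11L)[1L], " of ", path)
      flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
      pos  <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
      if (anyNA(flag) || anyNA(pos))
        stop("malformed SAM record (non-numeric FLAG or POS) in ", path)
      nh <- vapply(fields, function(f) {
        tags <- f[-seq_len(11L)]
        hit <- tags[startsWith(tags, "NH:i:")]
        if (length(hit)) as.integer(substring(hit[1L], 6L)) else NA_integer_
      }, integer(1))
      df <- data.frame(
        qname = vapply(fields, `[[`, "", 1L),
        flag  = flag,
        rname = vapply(fields, `[[`, "", 3L),
        pos   = pos,
        cigar = vapply(fields, `[[`, "", 6L),
        nh    = nh
      )
    }
  }
  df$mapped <- bitwAnd(df$flag, 4L) == 0L
  df$strand <- ifelse(bitwAnd(df$flag, 16L) == 0L, "+", "-")
  df$secondary <- bitwAnd(df$flag, 256L) != 0L
  df$supplementary <- bitwAnd(df$flag, 2048L) != 0L
  paired <- bitwAnd(df$flag, 1L) != 0L
  mate <- ifelse(bitwAnd(df$flag, 128L) != 0L, "/2", "/1")
  df$read_key <- ifelse(paired, paste0(df$qname, mate), df$qname)
  if (any(df$mapped & (is.na(df$pos) | df$pos < 1L |
                       is.na(df$cigar) | df$cigar == "*")))
    stop("mapped record without valid POS/CIGAR in ", path)
  # normalize placeholder fields of unmapped records across SAM/BAM sources
  df$rname[!df$mapped] <- NA_character_
  df$pos[!df$mapped] <- NA_integer_
  df$cigar[!df$mapped] <- NA_character_
  rownames(df) <- NULL
  df[, c("read_key", "qname", "flag", "mapped", "rname", "strand",
         "pos", "cigar", "nh", "secondary", "supplementary")]
}

#' Group alignment records by read key
#'
#' Splits a record table (as returned by [readAlignments()]) into one group
#' per distinct read key, preserving file order, and verifies that the file
#' was name-grouped: all records of a read must be adjacent.
#'
#' @param records Record data.frame from [readAlignments()].
#' @return A named list of data.frames, one per read key, in file order.
#' @seealso [resolveStatus()]
#' @export
alignmentGroups <- function(records) {
  if (nrow(records) == 0L) return(structure(list(), names = character(0)))
  r <- rle(records$read_key)
  if (anyDuplicated(r$values))
    stop("input is not grouped by read name: read '",
         r$values[duplicated(r$values)][1L],
         "' reappears after a different read; sort the file by name")
  grp <- rep.int(seq_along(r$values), r$lengths)
  out <- split(records, grp)
  names(out) <- r$values
  out
}

#' Resolve the mapping status of one read's record group
#'
#' A read is `"unique"` when its primary mapped record carries NH:i:1 (or,
#' when NH is absent, when exactly one mapped non-supplementary record
#' exists); `"non-unique"` when NH is 2 or more (or several mapped
#' non-supplementary records exist); `"unmapped"` when no mapped record
#' exists -- a read flagged unmapped and a read absent from the file are the
#' same condition.
#'
#' If an NH value disagrees with the number of mapped non-supplementary
#' records in the group, a warning is emitted and the record count decides.
#'
#' @param group A data.frame of records for one read (possibly zero rows).
#' @return One of `"unique"`, `"non-unique"`, `"unmapped"`.
#' @export
resolveStatus <- function(group) {
  mapped <- group[group$mapped, , drop = FALSE]
  if (nrow(mapped) == 0L) return("unmapped")
  nMapped <- sum(!mapped$supplementary)
  if (nMapped == 0L) nMapped <- nrow(mapped)  # only supplementary records
  prim <- mapped[!mapped$secondary & !mapped$supplementary, , drop = FALSE]
  nh <- if (nrow(prim)) prim$nh[1L] else mapped$nh[1L]
  if (!is.na(nh)) {
    if (nh != nMapped) {
      warning("read '", group$read_key[1L], "': NH:i:", nh, " disagrees with ",
              nMapped, " mapped record(s); using the record count")
      return(if (nMapped == 1L) "unique" else "non-unique")
    }
    return(if (nh == 1L) "unique" else "non-unique")
  }
  if (nMapped == 1L) "unique" else "non-unique"
}

# primary mapped record of a group (one-row data.frame), used for geometry
.primaryRecord <- function(group) {
  mapped <- group[group$mapped, , drop = FALSE]
  prim <- mapped[!mapped$secondary & !mapped$supplementary, , drop = FALSE]
  if (nrow(prim)) prim[1L, , drop = FALSE] else mapped[1L, , drop = FALSE]
}
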