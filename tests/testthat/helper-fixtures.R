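# build record rows / groups matching the readAlignments() schema, and
# small SAM writers, for tests that construct cases directly

mkrec <- function(key, rname = "chr1", pos = 1L, cigar = "40M", nh = 1L,
                  strand = "+", mapped = TRUE, secondary = FALSE,
                  supplementary = FALSE) {
  flag <- 0L
  if (!mapped) flag <- flag + 4L
  if (strand == "-") flag <- flag + 16L
  if (secondary) flag <- flag + 256L
  if (supplementary) flag <- flag + 2048L
  data.frame(read_key = key, qname = key, flag = flag, mapped = mapped,
             rname = if (mapped) rname else NA_character_,
             strand = strand, pos = as.integer(pos), cigar = cigar,
             nh = as.integer(nh), secondary = secondary,
             supplementary = supplementary)
}

mkgroup <- function(...) do.call(rbind, list(...))

emptyGroup <- function() mkrec("x")[0L, , drop = FALSE]

# write a SAM file from mkrec-style rows (sequences are placeholders)
writeTestSam <- function(rows, path,
                         refs = c(chr1 = 2e8, chr2 = 2e8, chr7 = 2e8,
                                  chr11 = 2e8, MT = 16299)) {
  hdr <- c("@HD\tVN:1.6\tSO:queryname",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    L <- if (r$mapped) alnCompare::cigarReadLength(r$cigar) else 40L
    seq <- substr(strrep("ACGT", 20L), 1L, L)
    tag <- if (!is.na(r$nh)) sprintf("\tNH:i:%d", r$nh) else ""
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
            r$qname, r$flag,
            if (r$mapped) r$rname else "*",
            if (r$mapped) r$pos else 0L,
            if (r$mapped) 60L else 0L,
            if (r$mapped) r$cigar else "*",
            seq, strrep("I", L), tag)
  }, "")
  writeLines(c(hdr, lines), path)
  path
}

# random valid CIGAR: optional clips, M/=/X blocks separated by N, D, I
randomCigar <- function() {
  nops <- sample(1:5, 1)
  parts <- character(0)
  for (j in seq_len(nops)) {
    parts <- c(parts, paste0(sample(1:60, 1), sample(c("M", "M", "M", "=", "X"), 1)))
    if (j < nops)
      parts <- c(parts, paste0(sample(1:300, 1), sample(c("N", "D", "I"), 1)))
  }
  if (runif(1) < 0.4) parts <- c(paste0(sample(1:10, 1), "S"), parts)
  if (runif(1) < 0.4) parts <- c(parts, paste0(sample(1:10, 1), "S"))
  if (runif(1) < 0.15) parts <- c(paste0(sample(1:5, 1), "H"), parts)
  paste(parts, collapse = "")
}
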