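# Brute-force reference classifier, independent of the package internals:
# parses SAM text on its own, derives reference blocks through
# GenomicAlignments' CIGAR machinery, and applies the eight-scenario table
# read by read on fully materialized files.

oracleParseSam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    flag <- as.integer(f[2])
    tags <- f[-(1:11)]
    nh <- tags[grepl("^NH:i:", tags)]
    list(qname = f[1], flag = flag,
         mapped = bitwAnd(flag, 4L) == 0L,
         rname = f[3], pos = as.integer(f[4]), cigar = f[6],
         strand = if (bitwAnd(flag, 16L)) "-" else "+",
         secondary = bitwAnd(flag, 256L) != 0L,
         supplementary = bitwAnd(flag, 2048L) != 0L,
         nh = if (length(nh)) as.integer(sub("NH:i:", "", nh[1])) else NA_integer_)
  })
}

oracleGroups <- function(recs) {
  keys <- vapply(recs, function(r) {
    if (bitwAnd(r$flag, 1L)) {
      paste0(r$qname, if (bitwAnd(r$flag, 128L)) "/2" else "/1")
    } else r$qname
  }, "")
  split(recs, factor(keys, levels = unique(keys)))
}

oracleStatus <- function(group) {
  mapped <- Filter(function(r) r$mapped, group)
  if (length(mapped) == 0L) return("unmapped")
  nMapped <- sum(!vapply(mapped, `[[`, FALSE, "supplementary"))
  if (nMapped == 0L) nMapped <- length(mapped)
  prim <- Filter(function(r) !r$secondary && !r$supplementary, mapped)
  nh <- if (length(prim)) prim[[1]]$nh else mapped[[1]]$nh
  if (!is.na(nh) && nh == nMapped)
    return(if (nh == 1L) "unique" else "non-unique")
  if (nMapped == 1L) "unique" else "non-unique"
}

# reference blocks via GenomicAlignments (D merged into flanking ranges,
# split at N), plus aligned read bases per block by M/=/X range intersection
oracleBlocks <- function(cigar, pos) {
  rng <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE)[[1]]
  aligned <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, ops = c("M", "=", "X"), pos = pos)[[1]]
  rb <- vapply(seq_along(rng), function(i)
    sum(IRanges::width(IRanges::pintersect(
      IRanges::findOverlapPairs(aligned, rng[i])))), integer(1))
  data.frame(start = IRanges::start(rng), end = IRanges::end(rng),
             read_bases = rb)
}

oracleSpliceLabel <- function(rec, maxOverhang = 2L) {
  if (!grepl("N", rec$cigar)) return("TP")
  b <- oracleBlocks(rec$cigar, rec$pos)
  if (min(b$read_bases) <= maxOverhang) "FP" else "TP"
}

oraclePrimary <- function(group) {
  mapped <- Filter(function(r) r$mapped, group)
  prim <- Filter(function(r) !r$secondary && !r$supplementary, mapped)
  if (length(prim)) prim[[1]] else mapped[[1]]
}

oracleClassifyRead <- function(ga, gb, maxOverhang = 2L) {
  sa <- oracleStatus(ga); sb <- oracleStatus(gb)
  lab <- function(sc, la, lb) list(scenario = sc, label_a = la, label_b = lb)
  if (sa == "unique" && sb == "unique") {
    ra <- oraclePrimary(ga); rb <- oraclePrimary(gb)
    ba <- oracleBlocks(ra$cigar, ra$pos); bb <- oracleBlocks(rb$cigar, rb$pos)
    sameChromStrand <- ra$rname == rb$rname && ra$strand == rb$strand
    identicalBlocks <- sameChromStrand && nrow(ba) == nrow(bb) &&
      all(ba$start == bb$start & ba$end == bb$end)
    if (identicalBlocks) return(lab(1L, "TP", "TP"))
    overlap <- sameChromStrand && any(outer(ba$start, bb$end, `<=`) &
                                      outer(ba$end, bb$start, `>=`))
    if (overlap) {
      la <- oracleSpliceLabel(ra, maxOverhang)
      lb <- oracleSpliceLabel(rb, maxOverhang)
      return(lab(if (la == "FP" || lb == "FP") 3L else 2L, la, lb))
    }
    return(lab(4L, "FP", "FP"))
  }
  if (sa == "unique" && sb == "non-unique") return(lab(5L, "FP", "TN"))
  if (sa == "non-unique" && sb == "unique") return(lab(5L, "TN", "FP"))
  if (sa == "unique") return(lab(6L, "TP", NA_character_))
  if (sb == "unique") return(lab(6L, NA_character_, "TP"))
  if (sa == "non-unique" && sb == "non-unique") return(lab(7L, "TN", "TN"))
  if (sa == "non-unique") return(lab(8L, "TN", NA_character_))
  if (sb == "non-unique") return(lab(8L, NA_character_, "TN"))
  NULL  # unmapped in both: no scenario
}

oracleCompare <- function(pathA, pathB, maxOverhang = 2L) {
  ga <- oracleGroups(oracleParseSam(pathA))
  gb <- oracleGroups(oracleParseSam(pathB))
  keys <- union(names(ga), names(gb))
  rows <- lapply(keys, function(k) {
    res <- oracleClassifyRead(if (k %in% names(ga)) ga[[k]] else list(),
                              if (k %in% names(gb)) gb[[k]] else list(),
                              maxOverhang)
    if (is.null(res)) return(NULL)
    data.frame(read_key = k, scenario = res$scenario,
               label_a = res$label_a, label_b = res$label_b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# independent percentile-bootstrap oracle; mirrors the documented RNG
# contract (single sample.int draw stream under set.seed(seed))
oracleBootstrap <- function(outcomes, nBoot, level, seed) {
  n <- nrow(outcomes)
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = n)
  met <- function(lab) {
    tp <- sum(lab == "TP", na.rm = TRUE)
    fp <- sum(lab == "FP", na.rm = TRUE)
    tn <- sum(lab == "TN", na.rm = TRUE)
    c(spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      acc = if (tp + fp + tn > 0) (tp + tn) / (tp + fp + tn) else NA_real_)
  }
  d <- vapply(seq_len(nBoot), function(b) {
    met(outcomes$label_a[idx[, b]]) - met(outcomes$label_b[idx[, b]])
  }, c(spec = 0, acc = 0))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rbind(spec = quantile(d["spec", ][!is.na(d["spec", ])], probs, names = FALSE),
        acc = quantile(d["acc", ][!is.na(d["acc", ])], probs, names = FALSE))
}
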