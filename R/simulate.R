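#' @name simulate
#' @title Synthetic paired SAM fixtures with known per-read truth
#' @description
#' The generator emits two name-sorted SAM files describing the same read
#' set as seen by two hypothetical aligners, together with a truth table
#' (read key, scenario 1-8, per-side TP/FP/TN label). Classification never
#' inspects base identity -- only coordinates, CIGAR, flags and the NH tag --
#' so read sequences are arbitrary placeholder bases and no reference FASTA
#' is involved.
NULL

# mouse-sized references; coordinates of the worked examples fit inside
.DEFAULT_REFS <- c(chr1 = 195471971, chr2 = 182113224, chr7 = 145441459,
                   chr11 = 122082543, MT = 16299)

.samHeader <- function(refs) {
  c("@HD\tVN:1.6\tSO:queryname",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
}

# rec: list(key, flag, rname, pos, cigar, nh (NA ok), mapq)
.samLine <- function(rec) {
  mapped <- bitwAnd(rec$flag, 4L) == 0L
  L <- if (mapped) cigarReadLength(rec$cigar) else rec$len
  seq <- substr(strrep("ACGT", ceiling(L / 4)), 1L, L)
  qual <- strrep("I", L)
  tags <- if (!is.na(rec$nh)) sprintf("\tNH:i:%d", rec$nh) else ""
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
          rec$key, rec$flag,
          if (mapped) rec$rname else "*",
          if (mapped) rec$pos else 0L,
          rec$mapq,
          if (mapped) rec$cigar else "*",
          seq, qual, tags)
}

.writeSam <- function(records, refs, path) {
  lines <- c(.samHeader(refs), vapply(records, .samLine, ""))
  writeLines(lines, path)
  invisible(path)
}

.rec <- function(key, rname, pos, cigar, nh = 1L, strand = "+",
                 secondary = FALSE, mapq = 60L) {
  flag <- 0L
  if (strand == "-") flag <- flag + 16L
  if (secondary) flag <- flag + 256L
  list(key = key, flag = flag, rname = rname, pos = as.integer(pos),
       cigar = cigar, nh = as.integer(nh), mapq = mapq, len = NA_integer_)
}

.unmappedRec <- function(key, len) {
  list(key = key, flag = 4L, rname = "*", pos = 0L, cigar = "*",
       nh = NA_integer_, mapq = 0L, len = as.integer(len))
}

#' Built-in worked-example fixtures
#'
#' Three reads whose contrasting mapping outcomes are reproduced at their
#' published genome coordinates:
#' \describe{
#'   \item{wx_fig3 (scenario 3)}{side A maps the 40-base read un-spliced to
#'     chr2:152,318,712-152,318,751 (TP); side B maps the same read spliced,
#'     1 base at 152,318,455, a 257-bp intron gap, then 39 bases at
#'     152,318,713-152,318,751 -- a 1-base overhang, hence FP.}
#'   \item{wx_s2fig (scenario 4)}{the two sides place the 40-base read
#'     uniquely at different locations (chr11:109,011,648 vs
#'     chr7:110,059,825); each missed the placement found by the other, so
#'     both are FP.}
#'   \item{wx_s3fig (scenario 5)}{side A maps the 51-base read non-uniquely
#'     (MT:7,465 and chr1:24,615,063-24,615,663, NH=2; TN) while side B
#'     reports it unique at MT:7,465 (FP). The chr1 record's published span
#'     (601 bases for a 51-base read) is synthesized as a spliced alignment
#'     filling that span; truth labels do not depend on its exact CIGAR.}
#' }
#'
#' @param dir Directory to write `worked_a.sam` / `worked_b.sam` into.
#' @return List with `path_a`, `path_b` and `truth` (data.frame with
#'   `read_key`, `scenario`, `label_a`, `label_b`).
#' @examples
#' fx <- builtinWorkedExamples()
#' fx$truth
#' @export
builtinWorkedExamples <- function(dir = tempfile("workedex")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recsA <- list(
    .rec("wx_fig3",  "chr2",  152318712L, "40M", nh = 1L),
    .rec("wx_s2fig", "chr11", 109011648L, "40M", nh = 1L),
    .rec("wx_s3fig", "MT",    7465L,      "51M", nh = 2L, mapq = 1L),
    .rec("wx_s3fig", "chr1",  24615063L,  "25M550N26M", nh = 2L,
         secondary = TRUE, mapq = 0L)
  )
  recsB <- list(
    .rec("wx_fig3",  "chr2", 152318455L, "1M257N39M", nh = 1L),
    .rec("wx_s2fig", "chr7", 110059825L, "40M", nh = 1L),
    .rec("wx_s3fig", "MT",   7465L,      "51M", nh = 1L)
  )
  pa <- file.path(dir, "worked_a.sam")
  pb <- file.path(dir, "worked_b.sam")
  .writeSam(recsA, .DEFAULT_REFS, pa)
  .writeSam(recsB, .DEFAULT_REFS, pb)
  truth <- data.frame(
    read_key = c("wx_fig3", "wx_s2fig", "wx_s3fig"),
    scenario = c(3L, 4L, 5L),
    label_a = c("TP", "FP", "TN"),
    label_b = c("FP", "FP", "FP"))
  list(path_a = pa, path_b = pb, truth = truth)
}

#' Generate a paired SAM fixture with a chosen scenario mix
#'
#' Draws a scenario for every read according to `proportions` and
#' synthesizes record pairs realizing that scenario's geometry: identical
#' unique alignments (1), overlapping unique alignments that are both
#' reliable (2), overlapping with a 1-2 nt overhang spliced alignment on a
#' random side (3), discordant unique locations (4), unique versus
#' non-unique (5), unique versus unmapped-or-absent (6), non-unique on both
#' sides (7), and non-unique versus unmapped-or-absent (8). Output files are
#' name-sorted with complete headers; the generation is deterministic given
#' `seed`.
#'
#' @param nReads Number of reads (>= 1).
#' @param proportions Numeric vector of length 8, proportions of scenarios
#'   1-8, summing to 1 (tolerance 1e-9). The default mix is dominated by
#'   concordant unique mappings, as in typical short-read data.
#' @param readLength Integer range `c(min, max)` of read lengths; default
#'   40-51 nt short reads.
#' @param references Named vector of reference sequence lengths.
#' @param seed Integer seed.
#' @param dir Output directory for `sim_a.sam` / `sim_b.sam`.
#' @return List with `path_a`, `path_b`, `truth` (read_key, scenario,
#'   label_a, label_b) and `seed`.
#' @examples
#' sim <- simulateComparison(50, seed = 7)
#' table(sim$truth$scenario)
#' @export
simulateComparison <- function(nReads,
                               proportions = c(0.70, 0.02, 0.04, 0.02,
                                               0.05, 0.04, 0.10, 0.03),
                               readLength = c(40L, 51L),
                               references = .DEFAULT_REFS,
                               seed = 1001L,
                               dir = tempfile("simcmp")) {
  stopifnot(nReads >= 1L, length(proportions) == 8L, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("scenario proportions must sum to 1")
  maxGap <- 2000L
  if (min(references) < 2L * max(readLength) + maxGap + 20L)
    stop("reference sequences too short for the requested read geometries")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  scen <- sample.int(8L, nReads, replace = TRUE, prob = proportions)
  recsA <- vector("list", 4L * nReads); recsB <- vector("list", 4L * nReads)
  ia <- 0L; ib <- 0L
  pushA <- function(r) { ia <<- ia + 1L; recsA[[ia]] <<- r }
  pushB <- function(r) { ib <<- ib + 1L; recsB[[ib]] <<- r }
  chroms <- names(references)
  randPos <- function(chr, span) sample.int(references[[chr]] - span, 1L)
  labA <- character(nReads); labB <- character(nReads)

  for (i in seq_len(nReads)) {
    key <- sprintf("sim%06d", i)
    L <- if (readLength[1L] == readLength[2L]) readLength[1L] else
      sample(seq.int(readLength[1L], readLength[2L]), 1L)
    st <- sample(c("+", "-"), 1L)
    chr <- sample(chroms, 1L)
    s <- scen[i]
    if (s == 1L) {
      spliced <- stats::runif(1) < 0.3
      cigar <- if (spliced) {
        o <- sample(seq.int(3L, L - 3L), 1L); g <- sample(50:maxGap, 1L)
        sprintf("%dM%dN%dM", o, g, L - o)
      } else sprintf("%dM", L)
      span <- if (spliced) L + g else L
      p <- randPos(chr, span)
      pushA(.rec(key, chr, p, cigar, 1L, st))
      pushB(.rec(key, chr, p, cigar, 1L, st))
      labA[i] <- "TP"; labB[i] <- "TP"
    } else if (s == 2L) {
      d <- sample.int(L - 1L, 1L)
      p <- randPos(chr, L + d)
      pushA(.rec(key, chr, p, sprintf("%dM", L), 1L, st))
      pushB(.rec(key, chr, p + d, sprintf("%dM", L), 1L, st))
      labA[i] <- "TP"; labB[i] <- "TP"
    } else if (s == 3L) {
      o <- sample(1:2, 1L); g <- sample(50:maxGap, 1L)
      p <- randPos(chr, L + g + o)
      spl <- .rec(key, chr, p, sprintf("%dM%dN%dM", o, g, L - o), 1L, st)
      uns <- .rec(key, chr, p + g, sprintf("%dM", L), 1L, st)
      if (stats::runif(1) < 0.5) {
        pushA(spl); pushB(uns); labA[i] <- "FP"; labB[i] <- "TP"
      } else {
        pushA(uns); pushB(spl); labA[i] <- "TP"; labB[i] <- "FP"
      }
    } else if (s == 4L) {
      v <- sample(3L, 1L)
      if (v == 1L) {
        two <- sample(chroms, 2L)
        pushA(.rec(key, two[1L], randPos(two[1L], L), sprintf("%dM", L), 1L, st))
        pushB(.rec(key, two[2L], randPos(two[2L], L), sprintf("%dM", L), 1L, st))
      } else if (v == 2L) {
        p <- randPos(chr, L)
        pushA(.rec(key, chr, p, sprintf("%dM", L), 1L, "+"))
        pushB(.rec(key, chr, p, sprintf("%dM", L), 1L, "-"))
      } else {
        gap <- sample(1000:10000, 1L)
        p <- randPos(chr, 2L * L + gap)
        pushA(.rec(key, chr, p, sprintf("%dM", L), 1L, st))
        pushB(.rec(key, chr, p + L + gap, sprintf("%dM", L), 1L, st))
      }
      labA[i] <- "FP"; labB[i] <- "FP"
    } else if (s == 5L) {
      two <- sample(chroms, 2L)
      p1 <- randPos(two[1L], L); p2 <- randPos(two[2L], L)
      multi <- list(.rec(key, two[1L], p1, sprintf("%dM", L), 2L, st, mapq = 1L),
                    .rec(key, two[2L], p2, sprintf("%dM", L), 2L, st,
                         secondary = TRUE, mapq = 0L))
      uniq <- .rec(key, two[1L], p1, sprintf("%dM", L), 1L, st)
      if (stats::runif(1) < 0.5) {
        pushA(multi[[1L]]); pushA(multi[[2L]]); pushB(uniq)
        labA[i] <- "TN"; labB[i] <- "FP"
      } else {
        pushA(uniq); pushB(multi[[1L]]); pushB(multi[[2L]])
        labA[i] <- "FP"; labB[i] <- "TN"
      }
    } else if (s == 6L || s == 8L) {
      if (s == 6L) {
        mapRecs <- list(.rec(key, chr, randPos(chr, L), sprintf("%dM", L), 1L, st))
        lab <- "TP"
      } else {
        two <- sample(chroms, 2L)
        mapRecs <- list(
          .rec(key, two[1L], randPos(two[1L], L), sprintf("%dM", L), 2L, st,
               mapq = 1L),
          .rec(key, two[2L], randPos(two[2L], L), sprintf("%dM", L), 2L, st,
               secondary = TRUE, mapq = 0L))
        lab <- "TN"
      }
      absent <- stats::runif(1) < 0.5
      if (stats::runif(1) < 0.5) {
        for (r in mapRecs) pushA(r)
        if (!absent) pushB(.unmappedRec(key, L))
        labA[i] <- lab; labB[i] <- NA_character_
      } else {
        for (r in mapRecs) pushB(r)
        if (!absent) pushA(.unmappedRec(key, L))
        labA[i] <- NA_character_; labB[i] <- lab
      }
    } else { # s == 7
      for (side in c("a", "b")) {
        two <- sample(chroms, 2L)
        rr <- list(
          .rec(key, two[1L], randPos(two[1L], L), sprintf("%dM", L), 2L, st,
               mapq = 1L),
          .rec(key, two[2L], randPos(two[2L], L), sprintf("%dM", L), 2L, st,
               secondary = TRUE, mapq = 0L))
        if (side == "a") { pushA(rr[[1L]]); pushA(rr[[2L]]) }
        else { pushB(rr[[1L]]); pushB(rr[[2L]]) }
      }
      labA[i] <- "TN"; labB[i] <- "TN"
    }
  }

  pa <- file.path(dir, "sim_a.sam"); pb <- file.path(dir, "sim_b.sam")
  .writeSam(recsA[seq_len(ia)], references, pa)
  .writeSam(recsB[seq_len(ib)], references, pb)
  truth <- data.frame(read_key = sprintf("sim%06d", seq_len(nReads)),
                      scenario = scen, label_a = labA, label_b = labB)
  list(path_a = pa, path_b = pb, truth = truth, seed = as.integer(seed))
}
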