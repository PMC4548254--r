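test_that("worked-example fixtures reproduce their published geometry", {
  fx <- builtinWorkedExamples(withr::local_tempdir())
  recA <- readAlignments(fx$path_a)
  recB <- readAlignments(fx$path_b)

  # the spliced placement: 1 base, a 257-bp intron, 39 bases
  spliced <- recB[recB$read_key == "wx_fig3", ]
  blocks <- referenceBlocks(spliced$cigar, spliced$pos)
  expect_equal(blocks$start[2] - blocks$end[1] - 1L, 257L)
  expect_equal(blocks$read_bases, c(1L, 39L))
  expect_equal(minSpliceOverhang(spliced$cigar), 1L)

  # read lengths match the published 40- and 51-base reads
  expect_equal(cigarReadLength(recA$cigar[recA$read_key == "wx_fig3"]), 40L)
  expect_equal(cigarReadLength(recB$cigar[recB$read_key == "wx_s3fig"]), 51L)
  # the non-unique chr1 record fills its published 601-base span
  chr1 <- recA[recA$read_key == "wx_s3fig" & recA$rname == "chr1", ]
  b <- referenceBlocks(chr1$cigar, chr1$pos)
  expect_equal(b$start[1], 24615063)
  expect_equal(b$end[nrow(b)], 24615663)
  expect_equal(sum(b$read_bases), 51L)
})

test_that("generated SAM is structurally valid", {
  sim <- simulateComparison(150, seed = 13, dir = withr::local_tempdir())
  for (path in c(sim$path_a, sim$path_b)) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "@")]
    fields <- strsplit(body, "\t", fixed = TRUE)
    # SQ header covers every reference used
    sq <- sub("^@SQ\tSN:([^\t]+)\t.*$", "\\1", grep("^@SQ", lines, value = TRUE))
    rnames <- unique(vapply(fields, `[[`, "", 3L))
    expect_true(all(setdiff(rnames, "*") %in% sq))
    # SEQ length is consistent with the CIGAR of every mapped record
    for (f in fields) {
      if (f[6] != "*") expect_equal(nchar(f[10]), cigarReadLength(f[6]))
      expect_equal(nchar(f[10]), nchar(f[11]))
    }
    # NH tags agree with record multiplicity; name-grouped adjacency holds
    rec <- readAlignments(path)
    expect_silent(grps <- alignmentGroups(rec))
    for (g in grps) {
      nh <- g$nh[g$mapped][1]
      if (!is.na(nh)) expect_equal(sum(g$mapped & !g$supplementary), nh)
    }
    # samtools-compatible: conversion to BAM parses every record
    bam <- Rsamtools::asBam(path, destination = withr::local_tempfile(),
                            indexDestination = FALSE)
    expect_equal(Rsamtools::countBam(bam)$records, length(body))
  }
})

test_that("generation is deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulateComparison(60, seed = 99, dir = d1)
  s2 <- simulateComparison(60, seed = 99, dir = d2)
  expect_identical(readLines(s1$path_a), readLines(s2$path_a))
  expect_identical(readLines(s1$path_b), readLines(s2$path_b))
  expect_identical(s1$truth, s2$truth)
})

test_that("classification reproduces the generator's truth table", {
  sim <- simulateComparison(300, seed = 101, dir = withr::local_tempdir())
  cmp <- suppressWarnings(compareAlignments(sim$path_a, sim$path_b))
  calls <- scenarioCalls(cmp)
  m <- merge(sim$truth, calls, by = "read_key",
             suffixes = c(".truth", ".call"))
  expect_equal(nrow(m), nrow(sim$truth))  # every read classified once
  expect_identical(m$scenario.call, m$scenario.truth)
  expect_identical(m$label_a.call, m$label_a.truth)
  expect_identical(m$label_b.call, m$label_b.truth)
})

test_that("a single-scenario mix produces only that scenario", {
  prop <- c(1, rep(0, 7))
  sim <- simulateComparison(50, proportions = prop, seed = 3,
                            dir = withr::local_tempdir())
  cmp <- compareAlignments(sim$path_a, sim$path_b)
  expect_true(all(scenarioCalls(cmp)$scenario == 1L))
  expect_equal(unname(tallyCounts(cmp)[, "FP"]), c(0L, 0L))
})

test_that("invalid mix specifications are rejected", {
  expect_error(simulateComparison(10, proportions = rep(0.2, 8)), "sum to 1")
  expect_error(simulateComparison(10, references = c(tiny = 500), seed = 1),
               "too short")
  expect_error(simulateComparison(0))
})
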