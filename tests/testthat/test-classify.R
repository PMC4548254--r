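test_that("same-alignment requires identical block structure, chrom and strand", {
  a <- mkrec("r", "chr2", 152318712, "40M")
  expect_true(sameAlignment(a, mkrec("r", "chr2", 152318712, "40M")))
  # published discordant pair: spliced vs un-spliced placements differ
  expect_false(sameAlignment(mkrec("r", "chr2", 152318455, "1M257N39M"), a))
  expect_false(sameAlignment(mkrec("r", "chr1", 100, "40M"),
                             mkrec("r", "chr1", 100, "40M", strand = "-")))
  # soft clips move no block boundary
  expect_true(sameAlignment(mkrec("r", "chr1", 100, "38M"),
                            mkrec("r", "chr1", 100, "2S38M")))
})

test_that("overlap needs >= 1 shared aligned reference base on one strand", {
  expect_true(alignmentsOverlap(mkrec("r", "chr2", 152318455, "1M257N39M"),
                                mkrec("r", "chr2", 152318712, "40M")))
  expect_false(alignmentsOverlap(mkrec("r", "chr11", 109011648, "40M"),
                                 mkrec("r", "chr7", 110059825, "40M")))
  expect_false(alignmentsOverlap(mkrec("r", "chr1", 100, "20M"),
                                 mkrec("r", "chr1", 120, "20M")))
  expect_false(alignmentsOverlap(mkrec("r", "chr1", 100, "20M"),
                                 mkrec("r", "chr1", 110, "20M", strand = "-")))
  # envelope overlap via an intron gap is not an overlap
  expect_false(alignmentsOverlap(mkrec("r", "chr1", 100, "10M100N10M"),
                                 mkrec("r", "chr1", 115, "20M")))
})

test_that("splice-overhang rule labels 1-2 nt anchored junctions FP", {
  expect_equal(spliceLabel(mkrec("r", cigar = "40M")), "TP")
  expect_equal(spliceLabel(mkrec("r", pos = 152318455, cigar = "1M257N39M")), "FP")
  expect_equal(spliceLabel(mkrec("r", cigar = "2M100N38M")), "FP")
  expect_equal(spliceLabel(mkrec("r", cigar = "3M100N37M")), "TP")
  expect_equal(spliceLabel(mkrec("r", cigar = "20M100N20M")), "TP")
  # threshold is a parameter; raising it widens the FP net
  expect_equal(spliceLabel(mkrec("r", cigar = "3M100N37M"), maxOverhang = 5), "FP")
})

test_that("classifyPair applies the eight-scenario decision table", {
  uniq <- function(key, rname, pos, cigar, strand = "+")
    mkrec(key, rname, pos, cigar, nh = 1, strand = strand)

  # identical unique alignments: scenario 1
  c1 <- classifyPair(uniq("r", "chr1", 500, "40M"), uniq("r", "chr1", 500, "40M"))
  expect_equal(c1[c("scenario", "label_a", "label_b")],
               list(scenario = 1L, label_a = "TP", label_b = "TP"))

  # overlapping, both reliable: scenario 2
  c2 <- classifyPair(uniq("r", "chr1", 500, "40M"), uniq("r", "chr1", 510, "40M"))
  expect_equal(c2[c("scenario", "label_a", "label_b")],
               list(scenario = 2L, label_a = "TP", label_b = "TP"))

  # overlapping with a 1-nt overhang spliced side: scenario 3
  c3 <- classifyPair(uniq("r", "chr2", 152318712, "40M"),
                     uniq("r", "chr2", 152318455, "1M257N39M"))
  expect_equal(c3[c("scenario", "label_a", "label_b")],
               list(scenario = 3L, label_a = "TP", label_b = "FP"))

  # both spliced with short overhangs, overlapping: scenario 3, both FP
  c3b <- classifyPair(uniq("r", "chr1", 500, "2M100N38M"),
                      uniq("r", "chr1", 501, "1M99N39M"))
  expect_equal(c3b[c("scenario", "label_a", "label_b")],
               list(scenario = 3L, label_a = "FP", label_b = "FP"))

  # discordant unique locations: scenario 4
  c4 <- classifyPair(uniq("r", "chr11", 109011648, "40M"),
                     uniq("r", "chr7", 110059825, "40M"))
  expect_equal(c4[c("scenario", "label_a", "label_b")],
               list(scenario = 4L, label_a = "FP", label_b = "FP"))
  # opposite strands are discordant even at one position
  c4b <- classifyPair(uniq("r", "chr1", 100, "40M"),
                      uniq("r", "chr1", 100, "40M", strand = "-"))
  expect_equal(c4b$scenario, 4L)

  # unique vs non-unique: scenario 5, sides labelled by their own status
  multi <- mkgroup(mkrec("r", "MT", 7465, "51M", nh = 2),
                   mkrec("r", "chr1", 24615063, "25M550N26M", nh = 2,
                         secondary = TRUE))
  c5 <- classifyPair(multi, uniq("r", "MT", 7465, "51M"))
  expect_equal(c5[c("scenario", "label_a", "label_b")],
               list(scenario = 5L, label_a = "TN", label_b = "FP"))

  # unique vs unmapped/absent: scenario 6
  c6 <- classifyPair(uniq("r", "chr1", 100, "40M"), emptyGroup())
  expect_equal(c6[c("scenario", "label_a", "label_b")],
               list(scenario = 6L, label_a = "TP", label_b = NA_character_))
  c6b <- classifyPair(mkrec("r", mapped = FALSE, nh = NA),
                      uniq("r", "chr1", 100, "40M"))
  expect_equal(c6b[c("scenario", "label_a", "label_b")],
               list(scenario = 6L, label_a = NA_character_, label_b = "TP"))

  # both non-unique: scenario 7
  multi2 <- mkgroup(mkrec("r", "chr1", 100, "40M", nh = 2),
                    mkrec("r", "chr2", 900, "40M", nh = 2, secondary = TRUE))
  c7 <- classifyPair(multi, multi2)
  expect_equal(c7[c("scenario", "label_a", "label_b")],
               list(scenario = 7L, label_a = "TN", label_b = "TN"))

  # non-unique vs unmapped/absent: scenario 8
  c8 <- classifyPair(multi2, mkrec("r", mapped = FALSE, nh = NA))
  expect_equal(c8[c("scenario", "label_a", "label_b")],
               list(scenario = 8L, label_a = "TN", label_b = NA_character_))

  expect_error(classifyPair(mkrec("r", mapped = FALSE, nh = NA), emptyGroup()),
               "no scenario")
})

test_that("comparison joins read universes and warns on asymmetric keys", {
  dir <- withr::local_tempdir()
  pa <- writeTestSam(rbind(mkrec("r1", "chr1", 100, "40M"),
                           mkrec("r2", "chr1", 500, "40M"),
                           mkrec("r3", mapped = FALSE, nh = NA)),
                     file.path(dir, "a.sam"))
  pb <- writeTestSam(rbind(mkrec("r1", "chr1", 100, "40M"),
                           mkrec("r3", mapped = FALSE, nh = NA),
                           mkrec("r4", "chr2", 900, "40M")),
                     file.path(dir, "b.sam"))
  expect_warning(cmp <- compareAlignments(pa, pb), "only in")
  calls <- scenarioCalls(cmp)
  # r2 only in A (s6), r4 only in B (s6), r3 unmapped in both (skipped)
  expect_setequal(calls$read_key, c("r1", "r2", "r4"))
  expect_equal(calls$scenario[calls$read_key == "r2"], 6L)
  expect_equal(calls$scenario[calls$read_key == "r4"], 6L)
  expect_equal(cmp@diagnostics$unmapped_both, 1L)
  expect_equal(cmp@diagnostics$only_in_a, 1L)
  expect_equal(cmp@diagnostics$only_in_b, 1L)
})

test_that("comparing a file against itself yields no false positives", {
  sim <- simulateComparison(120, seed = 31, dir = withr::local_tempdir())
  cmp <- compareAlignments(sim$path_a, sim$path_a)
  t <- tallyCounts(cmp)
  expect_equal(unname(t[, "FP"]), c(0L, 0L))
  expect_true(all(scenarioCalls(cmp)$scenario %in% c(1L, 7L)))
  # both sides identical: per-read labels agree
  expect_identical(scenarioCalls(cmp)$label_a, scenarioCalls(cmp)$label_b)
})

test_that("swapping the input files swaps sides exactly", {
  sim <- simulateComparison(200, seed = 77, dir = withr::local_tempdir())
  ab <- suppressWarnings(compareAlignments(sim$path_a, sim$path_b))
  ba <- suppressWarnings(compareAlignments(sim$path_b, sim$path_a))
  ca <- scenarioCalls(ab); cb <- scenarioCalls(ba)
  cb <- cb[match(ca$read_key, cb$read_key), ]
  expect_identical(ca$label_a, cb$label_b)
  expect_identical(ca$label_b, cb$label_a)
  # scenario numbers are symmetric by construction of the table
  expect_identical(ca$scenario, cb$scenario)
  expect_identical(tallyCounts(ab)[1, ], tallyCounts(ba)[2, ])
  expect_identical(tallyCounts(ab)[2, ], tallyCounts(ba)[1, ])
})
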