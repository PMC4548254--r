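Package: alnCompare
Title: Relative Reliability of Two Spliced-Alignment Results from the Same RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two SAM/BAM alignment results produced from the same
    RNA-Seq read set by different spliced aligners (or different parameter
    sets of one aligner). Every read's joint mapping outcome is classified
    into one of eight scenarios built on unique versus non-unique mapping
    (NH tag), exact/overlapping/discordant placement, and a splice-junction
    overhang rule that flags spliced alignments anchored by only one or two
    nucleotides as false positives. Per-aligner true-positive, false-positive
    and true-negative tallies yield specificity (the true-negative rate) and
    accuracy; the significance of between-aligner differences is assessed
    with paired percentile bootstrap confidence intervals. Includes a
    synthetic SAM fixture generator with known per-read truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
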