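---
title: "Comparing two spliced-alignment results: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two spliced-alignment results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnCompare)
```

## The problem and the model

Two spliced aligners run on the same RNA-Seq reads rarely produce the same
alignments, and in a real experiment no ground truth exists to arbitrate.
`alnCompare` therefore measures *relative* reliability. The model rests on
three assumptions:

1. **Uniquely mapped reads are the positive set.** Downstream RNA-Seq
   analysis consumes uniquely mapped reads, so false calls inside that set
   are the errors that matter. Non-uniquely mapped reads are the negative
   set and are always accepted as true negatives: reporting ambiguity when
   placement is ambiguous is the honest answer, and no attempt is made to
   find false negatives within it.
2. **Agreement is evidence of correctness.** When both aligners uniquely
   place a read on the same bases, both are credited (TP). When their unique
   placements conflict, the conflict itself is informative: placements at
   different genomic locations mean each aligner missed a plausible
   alternative the other found, so both are penalized (FP); a unique call
   contradicted by the other side's multi-mapping is penalized (FP) against
   the multi-mapper's TN.
3. **Short splice anchors are unreliable.** Among overlapping unique
   placements that disagree only in splice structure, an alignment putting
   just one or two read bases across an intron gap is very probably
   misplaced (FP); un-spliced placements and splices anchored by three or
   more bases are kept (TP).

Every read mapped by at least one side falls into exactly one of eight
scenarios (see the README table); reads unmapped or absent on both sides
carry no information and are skipped (counted in diagnostics). Per-aligner
tallies then give

$$\mathrm{specificity} = \frac{TN}{TN+FP}, \qquad
  \mathrm{accuracy} = \frac{TP+TN}{TP+FP+TN},$$

with false negatives excluded from both by construction.

Significance of the between-aligner differences comes from a paired
bootstrap: reads — each read's *pair* of outcome labels — are resampled with
replacement, both metrics are recomputed per replicate for both sides, and
the differences (side A minus side B) get percentile confidence intervals.
A difference is significant when its interval excludes zero; the verdict
selects a side only when **both** metrics are significantly better in the
same direction, reports "no significant difference" when neither is, and
"mixed" otherwise.

## Input contract and the domain model

Inputs are SAM/BAM files **grouped by read name** (all records of a read
adjacent); a read key reappearing after another key raises an error rather
than a silent misgrouping. The read key is QNAME, with `/1`–`/2` appended
for paired flags so mates are treated as independent reads (the method's
logic is per read; fragment-level rules are deliberately not invented).

Uniqueness follows the NH tag: NH = 1 unique, NH ≥ 2 non-unique. When NH is
absent (some SAM dialects omit it) the count of mapped non-supplementary
records substitutes; when NH *disagrees* with that count a warning is
emitted and the count wins, since the records actually present are the
harder evidence. Supplementary records never enter the uniqueness count,
and secondary records alone never overturn a unique call.

CIGAR strings are decomposed into reference blocks: maximal runs of
reference-consuming operations (M, =, X, D) split **only at N**. D
(deletion) does not split a block because N is the operation reserved for
introns, and the splice rule is about introns. S/H/I/P consume no
reference. All coordinates are 1-based inclusive, as in SAM. An N gap with
no aligned block on one side is rejected as malformed. The overhang of a
spliced alignment is the minimum over its blocks of aligned (M/=/X) read
bases — with two or more blocks every block flanks a gap, so the minimum
over all blocks is the minimum over gap-adjacent blocks.

Two placements are *the same* only with equal reference, strand and block
lists; soft-clipping differences that move no block boundary are invisible,
which is intended. *Overlap* requires at least one shared aligned reference
base between some pair of blocks on the same strand — envelope overlap
through a shared intron does not count, since no aligned base agrees.
Opposite-strand placements are always "different locations" (scenario 4):
a read cannot originate from both strands at once. Scenarios 2 and 3 are
one geometric situation; the number reported is 3 when either side's
overhang label is FP and 2 otherwise, and each side is labelled
independently (both may be FP). Only the labels enter the statistics.

The two files are joined by read key as a deterministic keyed join, so the
result is independent of the two files' (possibly different) name orders.
Reads present in only one file are classified (scenarios 6/8) rather than
rejected — absence and an unmapped flag are one condition — but their count
is reported as a warning so accidentally mismatched read sets are caught.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maxOverhang` | 2 nt | largest splice anchor still called FP; the default encodes "one or two nucleotides across an intron" |
| `nBoot` | 10,000 | bootstrap replicates behind each interval |
| `level` | 0.95 | confidence level; significance = interval excludes 0 |
| `seed` | 1001 | fixed documented constant, so repeated runs agree |

## Numerical and degenerate-input choices

* **Percentile intervals** (empirical `(1-level)/2` and `1-(1-level)/2`
  quantiles, R's default quantile definition) rather than BCa or normal
  approximations: the simplest interval consistent with resampling reads,
  and exactly reproducible.
* **Point estimates** come from the unresampled tallies, never from the
  replicate mean.
* **Degenerate replicates**: a resample can empty a metric's denominator
  (e.g. no negatives drawn). Such replicates are dropped from that metric's
  percentile computation and counted in the result (`dropped`); an undefined
  ratio cannot enter a quantile. On the full data the metrics raise an
  error instead, since a comparison without any negatives (or any calls) is
  meaningless.
* **One-sided reads** (scenarios 6/8) carry a label for the mapping side
  only; they are resampled like any read and contribute asymmetrically,
  keeping every replicate's tallies consistent with the full-data tally
  definition.
* **Reproducibility**: the bootstrap and the generator are pure functions
  of their inputs and seed, and both restore the caller's RNG state.

## What the generator emulates — and what it does not

`simulateComparison()` draws a scenario per read and synthesizes SAM record
pairs realizing that scenario's geometry: single-end 40–51 nt reads (the
short-read regime the scenario rules were designed around), NH-tagged
unique and multi-mapped records, spliced alignments with 50–2000 bp gaps
including 1–2 nt overhang misplacements, unmapped-flag records and reads
absent from one file, over mouse-sized reference lengths. The default mix
is dominated by concordant unique mappings (70% scenario 1, with the
remainder spread over discordant, multi-mapped and unmapped scenarios) —
the regime where most reads agree and the comparison hinges on the
disagreeing minority, chosen once as a realistic short-read profile.

The generator is deliberately not a read simulator: no sequencing-error or
quality model, no expression structure, placeholder base content (the
classifier never inspects bases — only coordinates, CIGAR, flags and NH),
and no reference FASTA. Passing round-trip tests therefore demonstrates
that classification, tallying and resampling are correct *given* the
mapping geometry, not that any aligner's behaviour on real reads is
emulated. The three built-in worked-example reads
(`builtinWorkedExamples()`) complement this with real published
coordinates; the one record whose internal splice structure is not printed
in its source (the 601-base span of a 51-base multi-mapped read) is
synthesized as a spliced alignment filling that span, which no truth label
depends on.

## Problem sizes

The shipped checks use sizes chosen to exercise the method well past its
corner cases while staying desk-scale: round trips over 20 seeds × 500
reads plus a 2000-read run, brute-force oracle equivalence on 50-read
fixtures across all eight scenarios, and bootstrap calibration over 200
simulation repetitions of 400 reads at 1000 replicates, where the nominal
95% interval's observed null coverage is required to sit within ±4 points
of nominal. All quantities reported by `scripts/acceptance.R` are computed
fresh at run time.

## Known limitations

* Relative, not absolute: a systematic bias shared by both aligners is
  invisible; the verdict ranks the pair, it does not certify either.
* Three or more results are compared pairwise and sequentially (compare
  two, then compare the winner with the third); no n-way mode exists.
* Mates of paired-end data are scored as independent reads; no
  fragment-level concordance is modelled.
* The equal-strand requirement for "same"/"overlapping" and the
  record-count tie-break for inconsistent NH values are this package's
  codifications of situations the underlying method leaves unstated.
* CRAM input, re-alignment, annotation handling and any judgement of which
  discordant placement is *truly* correct are out of scope.
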