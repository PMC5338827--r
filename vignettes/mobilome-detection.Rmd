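---
title: "Detecting transposable-element eccDNA from mobilome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transposable-element eccDNA from mobilome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobscan)
```

## The detection problem

Active LTR retrotransposons leave a transient trace outside the
chromosomes: reverse transcription produces a linear extrachromosomal DNA
copy whose ends can be joined into a covalently closed circle (a "2-LTR
circle"), and recombination between the two LTRs produces 1-LTR circles.
Mobilome sequencing enriches circular DNA (exonuclease digestion of linear
DNA followed by rolling-circle amplification) and sequences it as an
ordinary paired-end library. Against a reference genome, an element that
is forming circles shows two coupled signals:

1. **Depth of coverage (DOC).** Circles are massively over-represented
   relative to the trace of linear genomic DNA that survives enrichment,
   so the donor locus is covered tens to hundreds of times above
   background.
2. **Split reads (SR).** A read crossing the circle junction cannot map
   contiguously — the junction (3' end of the element fused to its 5'
   start) does not exist in the chromosome — and maps as two segments at
   the element's two ends. The junction is *perfect* when the fusion is
   seamless and *imperfect* when extra bases sit between the fused ends,
   classically a primer-binding-site (PBS) remnant.

A third, mapping-free route — de novo assembly followed by per-scaffold
read-count scoring — catches highly abundant circles of repetitive
families whose reads scatter across many genomic copies.

`mobscan` implements the computational side of this design: organelle
masking, windowed coverage statistics, split-read junction calling,
candidate-TE calling and scaffold scoring, plus a simulator that
generates libraries with known ground truth so every stage can be
validated without external data.

## Statistical model of the coverage track

The genome is tiled into consecutive non-overlapping 100-bp windows
(trailing short window kept). The per-window statistic is the number of
alignment records overlapping the window by at least one base — a record
crossing a boundary counts in both windows — normalized to reads per
million mapped records (rpm) for reporting.

Peak detection is two-staged, with bare thresholds and no
multiple-testing correction:

* **Stage 1 — covered windows.** A Poisson model is fitted to the raw
  counts of all non-excluded windows by maximum likelihood (the mean;
  zero-count windows included, an `include_zeros` switch exposes the
  alternative). A window is *covered* when its exact upper tail
  `P(X >= x)` is below `1e-5`. With a fitted mean of 1 the smallest
  covered count is 9. Tails are computed exactly (`ppois`), never by
  normal approximation; with a zero mean, any positive count is trivially
  covered (tail 0).
* **Stage 2 — peak windows.** A negative binomial is fitted by the method
  of moments (`p = m/v`, `r = m^2/(v-m)`); under-dispersed input falls
  back to a Poisson with the same mean, and the fallback is recorded. A
  covered window is a *peak* window when its NB upper tail is below
  `1e-3`; runs of boundary-sharing significant windows merge into peak
  regions (any gap splits them), which are annotated with every
  overlapping TE feature.

**Which counts feed the stage-2 fit?** The procedure reads literally as
"fit on the covered windows". On sparse, strongly enriched libraries,
however, stage 1 can isolate a covered set that is a single homogeneous
locus (one active element); a distribution fitted to those counts can
never call them extreme, and the stage would return nothing by
construction. The pipeline therefore defaults to fitting the NB on *all*
non-excluded windows while testing only covered windows against it
(`negbin_fit = "all"`); the literal covered-only fit is available as
`negbin_fit = "covered"` and behaves identically whenever the covered set
is broad and heterogeneous, as it is in real multi-locus libraries. Note
that with the default, peak regions remain a subset of covered windows,
so stage 1 still controls what can possibly be reported. The candidate
decision rule (below) does not depend on this choice at all.

## Organelle masking

Mitochondrial and chloroplast genomes are circular and abundant, and
fragments of them are integrated in the nuclear genome. Organelle reads
surviving the organelle-mapping pass pile up on those nuclear insertions
and mimic eccDNA. `build_organelle_mask()` tiles the organelle sequences
into 100-bp pseudo-reads every 10 bp on both strands and marks every
nuclear interval carrying an exact match of at least 50 bp to a tile.
Because the tile step (10) is at most `tile_len - min_exact + 1`, this is
exactly equivalent to matching every 50-mer of the organelle, so planted
insertions are recovered over 100% of their length — a deterministic
replacement for simulating random organelle reads through an aligner.
`apply_mask()` then removes any record with >= 1 bp of segment overlap
with the mask (the `intersect -v` convention; half-open abutment is not
overlap), which makes the operation idempotent.

## Split reads and junction calls

From SAM input, a record is SR evidence iff it is a primary record, its
pair is flagged not-proper, and it carries two or more aligned segments;
secondary alignments never contribute. (The corresponding FLAG recipe in
the field's tooling is usually quoted as "not mapped in a proper pair,
excluding secondary alignments"; the literal bit combination `-f 14` is
self-contradictory under SAM semantics and the prose definition is what
is implemented.)

For FASTQ-level validation the package carries its own gapless
seed-and-extend split aligner, `split_align()`, governed by four
acceptance thresholds mirroring split-aware mappers: per-segment identity
>= 0.95, summed matched bases >= 24, per-segment length >= 25, and summed
query coverage >= 95% of the read. Two contract details are fixed
deliberately:

* a read whose best full-length contiguous placement already reaches the
  identity threshold is *not* split — otherwise every well-mapped read
  would admit a degenerate two-adjacent-segment "split";
* ties on total matched bases resolve deterministically: forward strand
  first, then smaller first-segment length, smaller query gap, then
  reference order. With identical LTR copies, a junction flank that lies
  entirely within the LTR is genuinely ambiguous between the two copies
  and resolves to the leftmost placement.

The default seed length is 15; any exact-seed length at most
`floor((L_min - m)/(m + 1))` for segment length `L_min` and mismatch
budget `m` makes the seeded search provably equivalent to exhaustive
placement enumeration (the test suite verifies equality against a
brute-force two-breakpoint aligner at seed length 8 on short reads).

`call_junctions()` classifies each same-TE split by the distances of the
query-first segment's end from the element 3' terminus and the
query-second segment's start from the 5' terminus (tolerance 20 bp,
configurable — the value is not dictated by the method and simulated
junctions sit at distance 0): `perfect` with no inserted query bases,
`imperfect` with an insert (e.g. PBS remnant, recovered verbatim from the
read), `internal` otherwise. Splits across two copies of one family are
reported at the upstream segment's locus, reflecting that per-copy
attribution is ambiguous in multi-copy families.

## Candidate TEs

Per TE locus, three evidence values are aggregated from the mask-filtered
alignments: *breadth* (fraction of bases with per-base depth >= 1),
*doc_rpm* (mean per-base depth over the locus per million mapped
records — the locus-level aggregation is not dictated by the method
description; the mean is used, with the per-window maximum available via
the window track) and *sr_rpm* (mean SR-track rpm over the windows
intersecting the locus, symmetric with doc_rpm; end-concentration is
reported separately by the junction calls). The decision rule is:

    breadth >= 0.90  AND  doc_rpm > 10  AND  sr_rpm > 10  AND  length > 100

with strict inequalities where stated. Candidates are ordered by
descending doc_rpm, ties by id, so reports are reproducible.

## Scaffold scoring

Externally assembled scaffolds (the assembler itself is out of scope) are
scored on reads-per-million-assembly-reads; a moment-fitted negative
binomial across scaffolds flags significant recruitment at p < 0.05, with
the upper tail evaluated at `ceiling(rpm)` (integer NB support). Best-hit
annotation keeps, per scaffold, the lowest-e-value hit with e < 1e-2 and
HSP >= 100 bp (ties: longer HSP, then subject id). Family-member search
applies HSP > 4000 bp, identity >= 70%, e < 1e-50 either to an external
hit table or to an internal desk-scale scan (gapless diagonals, Kadane
maximum-scoring segment at +1/-2, ungapped Karlin–Altschul e-values with
lambda = 1.28, K = 0.46).

## The simulator and what it does (not) emulate

`build_reference()` + `simulate_reads()` generate: uniform-composition
random chromosomes with planted element copies (identical by default;
per-copy divergence configurable up to 5% to probe multi-mapping),
a random organelle genome with exact substrings embedded in the nucleus,
and paired reads from three template classes — circles (uniform start
with wrap-around, so single reads overlap the junction with probability
`(R-1)/C`), linear background, and organelle. Defaults mirror a MiSeq-
style mobilome library: 250-bp reads, 500 +/- 50 bp fragments, circle
depth in the tens to hundreds of fold against a 1x linear background
(the real carry-over of linear DNA is not quantified anywhere; 1x is this
package's choice of a trace background), organelle carry-over a few
fold. Per-base substitution errors only; constant quality strings
(qualities are never used downstream).

`idealized_alignments()` places every read at its true origin —
junction-wrapping reads as two soft-clipped segments with the pair
flagged not-proper — which lets the whole downstream stack run without an
external aligner and makes truth-recovery tests exact.

Deliberately absent: indel errors, quality models, RCA chimeras and
branching artifacts, PCR duplicates, non-uniform base composition, nested
or fragmented TE copies. Passing tests therefore demonstrate the
correctness of the statistics and the bookkeeping, not robustness to
aligner idiosyncrasies or library artifacts of real data.

## Validation scale

The shipped tests and the acceptance script run the full chain on
libraries of one 1-Mb chromosome, three 5-kb elements (one active at
50–300x circle depth), ~5,000–7,000 read pairs each, ten seeds —
sizes chosen so a complete validation runs in minutes on a laptop while
every statistical contrast (peak tails, SR concentration, candidate
thresholds) is still decided by orders of magnitude rather than by luck.
Exact-tail agreement is checked against direct pmf summation to 1e-12;
the split aligner is checked for exact equality against an exhaustive
two-breakpoint aligner on 500 short reads.

## Known limitations

* The internal split aligner is for validation and desk-scale use;
  production libraries should be aligned with a split-aware mapper and
  ingested as SAM.
* Family-level attribution of junctions uses the upstream segment's
  locus; with high per-copy divergence and many copies, per-copy counts
  are better read from the family roll-up than from single loci.
* The NB stage-2 fit choice (`negbin_fit`) matters only for degenerate
  covered sets; see above.
* No GC/mappability correction and no per-chromosome background models;
  the windowed background is assumed homogeneous.
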