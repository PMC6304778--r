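---
title: "Demultiplexing ddSEQ/SureCell reads: model, tolerances and design choices"
author: "ddseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing ddSEQ/SureCell reads: model, tolerances and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddseqr)
```

## The read model

ddSEQ/SureCell Read 1 is modelled as a concatenation of ten segments:

```
PB | BC1 | L1 | BC2 | L2 | BC3 | ACG | UMI | GAC | tail
```

The phase block `PB` has variable length (bead chemistry releases cDNA at
different positions), which is the whole reason fixed-coordinate
demultiplexers fail on these data: every downstream segment floats with it.
The two 15-nt linkers are the only long fixed anchors, so the algorithm is
anchor-based: find the linkers, then read everything else off *relative* to
them. BC1 is the `barcode_len` bases immediately left of the linker-1 hit,
BC2 the bases between the two hits, BC3 the bases immediately right of the
linker-2 hit, and the UMI sits between the `ACG`/`GAC` trinucleotides that
follow BC3.

All structural knowledge lives in one declarative object,
`read_structure()`; a `key=value` file (`read_structure_file()`) overrides
it without touching code. The linker sequences are configuration, not
constants of the algorithm.

## Tolerances and what they buy

* **Per-linker edit budget: Levenshtein distance ≤ 1** (one substitution
  *or* one indel, not both; `max_linker_edits`, default 1). Indel awareness
  in the linkers and barcodes is the package's distinguishing feature —
  substitution-only matching silently discards every read in which the
  sequencer dropped or duplicated a base inside a 36-nt stretch of fixed
  sequence. Events needing more than one edit per linker are rare enough
  that chasing them costs more in false anchors than it recovers.
* **Accepted linker gap {20, 21, 22} nt** (`strict_gap = FALSE`). On a clean
  read the linker starts are exactly 21 nt apart (BC2 + L1). A single indel
  in BC2 or inside L1 shifts the gap by one; those reads are routed into
  indel-aware BC2 extraction (5- or 7-nt blocks) rather than discarded.
  The implied BC2 block must still be within one base of `barcode_len`,
  otherwise two indels are implied and the read is rejected (`D`).
  `strict_gap = TRUE` restores the literal 21-nt rule for users who want
  the conservative behaviour.
* **Linker-1 offset ≥ 7 nt** (`min_l1_start`): one phase-block base plus a
  full BC1 must precede the anchor; less means BC1 is truncated beyond
  repair (`P`).
* **Flankers: ≤ 1 mismatch total across ACG+GAC, no indels**
  (`max_flanker_mismatches`). Two design choices are folded in here. First,
  the budget is *total* rather than per-trinucleotide: with only six fixed
  bases guarding the UMI, allowing a mismatch in each trinucleotide doubles
  the chance of accepting a structurally broken read while rescuing little,
  so the conservative reading was chosen (the parameter is adjustable).
  Second, no indel search is performed on 3-nt sequences — an indel
  interpretation of a trinucleotide is statistically indistinguishable from
  noise at that length.
* **Barcode correction: unique whitelist neighbour within edit distance 1**
  (`max_barcode_edits`). A block matching two entries within the budget is
  ambiguous and fails (`B`); resolving it arbitrarily would silently merge
  droplets. One whitelist serves all three positions (the kit uses a single
  96-block set); per-position lists were deliberately left out of scope.
* **`N` bases** match nothing anywhere: they count as mismatches against
  linkers, flankers and whitelist entries alike, so a single `N` inside an
  otherwise clean segment consumes exactly the one-edit budget.

The UMI is never corrected — it is random sequence with no reference to
correct against; any "correction" would be invention.

## Resolving ambiguous linker interpretations

A single linker edit frequently admits several overlapping interpretations
at neighbouring starts. A deletion inside a leading homopolymer run, for
example, reads equally well (distance 1) as an insertion two bases to the
left, a substitution one base to the left, or the true deletion — and the
three interpretations imply different BC1 coordinates. Committing to the
leftmost interpretation misanchors BC1 and rejects reads that are perfectly
decodable.

The extractor therefore enumerates the minimal-distance hits of both
linkers, forms candidate (L1, L2) pairs in (edit distance, start) order,
and accepts the **first pair under which the whole read validates** —
geometry, flankers and all three whitelist lookups. If no candidate
validates, the primary (leftmost minimal) interpretation's error code is
reported, keeping error statistics anchored to one deterministic reading.
This is a maximum-parsimony rule: only equally-parsimonious (same edit
count) interpretations compete, and structure consistency arbitrates among
them. One consequence is honest ambiguity at segment boundaries: an
insertion that duplicates a linker's edge base is byte-identical to a
barcode-side insertion, and no algorithm can tell them apart; such reads
resolve to whichever interpretation validates, or fail.

Error codes are mutually exclusive with precedence
`LX > L1 > L2 > D > P > S > T > B`, mirroring the order of the checks:
structural failures mask content failures. `L1`/`L2`/`LX`/`B` are the
conventional identifiers for linker and barcode failures in this chemistry;
`D` (spacing), `P` (offset), `S` (truncated read) and `T` (flankers) are
this package's names for the remaining failure modes of the structural
checks.

## Whitelist lookup

`barcode_whitelist()` precomputes every string reachable from an entry by
one substitution (including to `N`), one deletion or one insertion
(~65 variants per entry) into a hashed variant table; variants reachable
from two entries are marked ambiguous up front. A query then costs one
hashed `match()`, which keeps 50,000-read runs in vectorized R. The
brute-force alternative — a Levenshtein distance matrix against all entries
via `utils::adist()` — is retained in the test suite and in the generator's
oracle as the independent cross-check; the two routes are compared
exhaustively over all 4^5 + 4^6 + 4^7 queries in the acceptance suite.

The shipped `synthetic_barcode_blocks_96.txt` is a generated stand-in for a
kit whitelist (96 six-mers, pairwise Hamming distance ≥ 2, homopolymer runs
≤ 4), adequate for testing and examples. Real analyses should supply the
vendor list; correction ambiguity rates depend on the list's distance
structure.

## Knee-based cell calling

`knee_estimate()` ranks barcodes by valid-read count, forms the cumulative
fraction curve over ranks, rescales ranks and fractions to the unit square
(anchored at the origin), and returns the rank with maximal perpendicular
distance to the chord through the curve's endpoints. Ties break toward the
smaller rank, so a perfectly uniform table — where the curve *is* the chord
— returns rank 1 rather than something arbitrary. The estimate is invariant
to uniform scaling of the counts (only fractions enter) and requires at
least three distinct barcodes. The unit-square normalization matters:
in raw (rank, fraction) coordinates the rank axis dominates the geometry
and the distance-to-chord criterion degenerates.

## The synthetic generator and its oracle

`simulate_reads()` builds each read from the ten segments above: cells are
distinct whitelist triples, phase blocks are uniform over a configurable
length range (default 1–5 nt; the structure only constrains PB ≥ 1, and
short phase blocks are the hard case for anchor search), UMIs are uniform
random, and Read 2 is random sequence — alignment is out of scope, so no
transcriptome is emulated. Qualities are constant high ('I'); extraction
ignores them by design. Errors are injected per an `error_model()` whose
entries fire independently per read; injected substitutions always change
the base and use distinct positions, so the intended edit distance is the
realized one.

`predict_status()` is the generator-side oracle: it recomputes each read's
mandated outcome *without the extraction scanner*, by brute-force window
classification around the bookkept linker positions (starts ±2, spans
14/15/16, distances from `utils::adist`), followed by the same contract
arithmetic and `adist`-based whitelist resolution. Its one assumption is
that no spurious linker match arises far from the true position — for
15-nt linkers a distance-≤1 match in random sequence has probability of
order 10⁻⁷ per window, negligible at the simulation sizes used. Because the
oracle and the extractor share no string-matching code, their 100%
agreement across every single-error class (asserted in the test suite) is
a meaningful check, not a tautology.

What passing these tests does *not* show about real data: the generator
draws errors independently and uniformly within segments, has no
quality-correlated error structure, no chimeric reads, no adapter
read-through, and its noise barcodes (for cell calling) are modelled
directly as count tables. Aggregate error rates on real runs will differ;
the package's claim is that *given* the structural model and budgets, reads
are classified exactly as specified.

## Problem sizes and numerical conventions

The test and acceptance workloads were sized to be decisive yet quick on a
laptop: 10,000 error-free reads for the recovery sweep, every position of
both linkers × three edit kinds for robustness, 10,000 reads against the
brute-force scanner oracle, all 21,504 length-5/6/7 queries against the
whitelist oracle, 50,000 reads for aggregate error-rate recovery (compared
with the closed-form expectation within three binomial standard
deviations), and a 300-cell / 2,000-noise-barcode table for the knee. All
coordinates in the R API are 1-based with inclusive ends, hits are ordered
by (edit distance, start, interpretation priority), and every randomized
component takes an explicit integer seed; equal seeds give byte-identical
outputs, including the gzipped FASTQ files.

## Known limitations

* Edit distance > 1 per linker and quality-aware barcode correction are out
  of scope; reads carrying such damage surface as `L1`/`L2`/`LX`/`B`.
* BC1 and BC3 indels are not positionally recoverable (only BC2 benefits
  from the gap geometry); they surface as `B` or `T` depending on where
  the downstream coordinates land.
* UMI deduplication, alignment and gene counting belong to downstream
  tools; the tagged unmapped BAM is the hand-off point.
* The `S` (too-short) check is anchored at the linker-2 hit, so a read
  truncated *before* L2 reports `L2`, not `S`.
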