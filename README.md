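# ddseqr

Cell barcode and UMI extraction for Bio-Rad ddSEQ / Illumina SureCell WTA 3'
single-cell RNA-seq reads.

## The problem

In ddSEQ/SureCell libraries the first read of each pair carries the molecular
tags and the second the cDNA. Read 1 has the anatomy

```
PB - BC1 - L1 - BC2 - L2 - BC3 - ACG - UMI - GAC - ...
```

a phase block (PB) of variable length, three 6-nt cell-barcode blocks (BC1,
BC2, BC3) separated by two fixed 15-nt linkers (L1, L2), and an 8-nt UMI
bracketed by the trinucleotides `ACG` and `GAC`. Because the phase block's
length varies from read to read, the barcodes sit at variable positions and
generic demultiplexers that assume fixed tag coordinates cannot process these
reads. `ddseqr` locates the linkers, validates the structure, corrects the
barcode blocks against a whitelist, and emits a tagged unmapped BAM that
drops into standard scRNA-seq pipelines (Drop-seq tools, dropEst, scPipe),
plus the QC tables needed to judge a run before alignment.

## The method

For each Read 1:

1. **Linker localization.** Both linkers are searched with a typed
   approximate scan tolerating Levenshtein distance ≤ 1 (one mismatch *or*
   one indel per linker). Hits are typed as exact / substitution / deletion /
   insertion; a deletion hit spans 14 read bases, an insertion hit 16.
2. **Geometry validation.** The distance between the linker start positions
   must be 21 nt (= BC2 + L1) or 20/22 when a single indel in BC2 or L1 is
   implied; L1 must be preceded by at least 7 bases (PB ≥ 1 nt + BC1); the
   read must extend through the post-UMI flanker.
3. **Flanker check.** The `ACG`/`GAC` trinucleotides around the UMI may carry
   at most one mismatch in total, with no indel search.
4. **Extraction and correction.** BC1/BC2/BC3 are read off relative to the
   linker hits and each block is resolved against the whitelist: exact
   membership, or the *unique* entry within edit distance 1 (5- and 7-nt
   blocks from implied indels included). Ambiguity is a failure, never a
   guess. The cell barcode is BC1+BC2+BC3 (18 nt, corrected); the UMI is
   reported verbatim and never corrected.

When one linker edit admits several overlapping interpretations, candidate
interpretation pairs are tried in (edit distance, start) order and the first
fully valid one wins. Invalid reads get exactly one error code, in
precedence order `LX > L1 > L2 > D > P > S > T > B` (see
`?ddseq_error_codes`), written to the BAM error tag (`XE`) while valid reads
carry cell/UMI tags (`XC`/`XM` by default; any scheme via `tag_scheme()`).

QC outputs: per-cell valid-read counts, the PASS/error-code distribution,
the cumulative fraction of reads over ranked barcodes, and a knee-based
estimate of the number of real cells (maximum distance between the
normalized cumulative curve and its chord).

A seeded synthetic-read generator (`simulate_reads()`) emulates the full
read anatomy with configurable error injection and computes, analytically
and independently of the extraction code, the status each read must receive
— so the whole pipeline is testable without sequencing data.

## Worked example

```r
library(ddseqr)

wl <- read_barcode_whitelist(
  system.file("extdata", "synthetic_barcode_blocks_96.txt", package = "ddseqr")
)

# 50 cells x 200 reads with realistic error injection, written as FASTQ
sim <- simulate_reads(
  n_cells = 50, reads_per_cell = 200, whitelist = wl, seed = 42,
  model = error_model("linker1:substitution:0.05",
                      "linker1:substitution:0.01:2",
                      "bc2:substitution:0.02"),
  out_dir = "readme_demo"
)

res <- demux("readme_demo/sim_R1.fastq.gz", "readme_demo/sim_R2.fastq.gz", wl,
             out_bam = "readme_demo/tagged.bam",
             summary_prefix = "readme_demo/run")
res
#> <ddseq_demux> 10000 read pairs
#>   PASS: 9847 (98.47%)
#>   errors: L1=0.98% B=0.55%
#>   cells with >=1 valid read: 53
glance(res)
#> # A tibble: 1 x 5
#>   n_pairs n_valid pass_fraction n_barcodes estimated_cells
#>     <int>   <int>         <dbl>      <int>           <int>
#> 1   10000    9847         0.985         53              50
```

98.47% of reads pass: 5% single linker substitutions are absorbed by the
edit-tolerant scan, 1% double substitutions defeat linker 1 (`L1` = 0.98%),
and the 2% BC2 substitutions are corrected except where two whitelist
entries are equally close (`B` = 0.55%). 53 barcodes receive at least one
valid read (50 real cells plus 3 mis-corrected strays) and the knee estimate
recovers the 50 cells. `tidy(res)` gives the per-read tibble;
`autoplot(res, "cumulative")` plots the ranked-barcode curve with the knee.

The same pipeline is scriptable from a shell via `exec/ddseqr`
(`ddseqr demux --r1 ... --r2 ... -o out.bam --whitelist wl.txt`,
`ddseqr simulate ...`).

The shipped whitelist is a synthetic 96-entry set (pairwise Hamming
distance ≥ 2) for testing and examples; pass your own kit whitelist for real
data. The default linkers/geometry can be overridden with a `key=value`
structure file (`inst/extdata/surecell_structure.txt` is an editable copy).

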