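---
title: "Demultiplexing MGI runs: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing MGI runs: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgidemux)
```

## The problem

MGI (DNBSEQ) instruments emit FASTQ whose read headers
(`@<flowcell>L<lane>C<col>R<row><serial>/<mate>`) and file naming differ from
Illumina conventions, and whose sample indices are not carried in the header
but appended to the read sequence itself: the last bases of R2 (paired-end)
or R1 (single-end) are the *read barcode*, holding the i7 index, optionally
an i5 index and optionally a UMI, each index possibly reverse-complemented.
Demultiplexing such a run means recovering, for every read, the sample whose
indices best explain the observed barcode, then rewriting the reads into
per-sample files a downstream pipeline will accept.

## Assignment model

The matcher is deliberately the conservative, quality-blind model used by
the standard vendor demultiplexers: per-index Hamming distance with a small
per-index allowance, best (minimal total distance) match wins, an exact tie
between distinct samples is *ambiguous*, no eligible sample is
*undetermined*. Substitutions are the only error mode modelled; an indel
would shift the frame of a fixed-position barcode and is outside the model.
An `N` base call consumes one unit of mismatch budget against any expected
base, which is why N-substituted variants are first-class members of every
mismatch neighbourhood.

Rather than scanning the sample sheet per read, `build_lookup()` expands
every sheet index into its Hamming ball of radius `m7`/`m5` over
{A,C,G,T,N} and registers every concatenated variant in a dictionary, so a
read costs one fetch regardless of the allowance. Collisions between
samples are resolved at build time (minimal total distance kept, exact ties
marked ambiguous), which also settles overlapping indices across samples
once instead of per read.

Two rules deserve explicit statement because the model leaves them open:

* **Tie decomposition.** A dual-index tie is judged on the *total* distance
  d7+d5. Two samples at (1,1) and (0,2) from the same observation tie and
  the read is ambiguous, even though the per-index split differs.
* **Index diversity.** A sample listed under several index pairs is one
  sample: if two of its own records tie for a key, the key resolves to the
  sample (lowest record) rather than being called ambiguous, since all its
  records route to the same output files anyway.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `m7`, `m5` | 1, 1 | per-index mismatch allowances (bp). Sequencing indices rarely carry more than one error; larger values grow the expansion as Σₖ C(L,k)·4ᵏ and erode separability. |
| `max_keys` | 5·10⁷ | refuse to build a lookup whose predicted size exceeds this; the expansion is exponential in the allowance, and hitting the cap is a sign `m` is too large for the index length. |
| `dialect` | `illumina` | output header/file naming. `mgi` keeps input headers verbatim (UMI appended after `#`); `illumina` synthesises `@fc:1:fc:lane:tile:x:y` with `tile = column·1000 + row`, `x = serial`, `y = 1` — a deterministic, invertible mapping that satisfies tools expecting the syntactic Illumina form. |
| `lane` | from headers | reports are per lane; mixed lanes in one input file are an error unless a label is forced. |
| detection `limit` | 5000 reads | exact-match scoring over the first reads of the file; thousands of reads give an unambiguous winner at trivial cost. |
| `top_undetermined` | 50 | rows kept in the undetermined-barcode table. The tally keys on the observed index combination (sheet orientation), not the raw barcode region, so a templated UMI cannot atomise the counts. |
| `buffer_lines` | 40000 | per-file output buffer before a flush to the open gzip stream; outputs are byte-valid gzip at any flush granularity. |

## Numerical and degenerate-input choices

* **Key encoding.** Dictionary keys are encoded as exact base-5 integers
  (A=0 … N=4 per position) held in doubles; 5²² < 2⁵³, so combined index
  lengths up to 22 bp are represented exactly and the build refuses longer
  ones. Queries are a vectorised binary search on the sorted key vector;
  build and lookup are allocation-light compared with hashing millions of
  short strings. Characters outside {A,C,G,T,N} in a read encode to NA and
  can never match a key — such a read is undetermined.
* **Tie-break in template detection.** Candidates are ranked by exact
  matches, ties broken by the spec-string ordering so results are
  deterministic; all ties are reported, and a best score under 50% of the
  sampled reads raises a low-confidence warning.
* **Degenerate reads.** A read exactly as long as the barcode leaves a legal
  empty biological sequence. Reads shorter than the template are an error,
  as are paired files that desynchronize (reported with the read ordinal).
* **Mixed libraries.** Per-record `template` overrides partition the sheet
  into template groups, each with its own extraction and lookup; a read
  assigned by exactly one group belongs to that sample, by two or more is
  ambiguous, by none is undetermined. Unassigned reads are trimmed and
  UMI-tagged by the first (default) group's template, a convention the
  output must pick one way or another.
* **Ambiguous routing.** Ambiguous reads are counted separately but share
  the `Undetermined` files by default (`separate_ambiguous = TRUE` gives
  them their own), since downstream re-demultiplexing treats both the same.

## The simulator: what it emulates, what it does not

`simulate_run()` is the package's ground-truth factory. It emulates the MGI
header grammar, all five canonical barcode layouts (index order, per-index
reverse complement, UMI before/between/after), per-base substitution errors
in the index segments (substituted base uniform over the three other bases
plus N), uniform random UMIs, an optional fraction of fully random barcodes,
multiple lanes, and strictly increasing serials; it records per read the
true sample, the realized per-index error counts and the emitted UMI.
Qualities are drawn per base from a two-state Q40/Q12 mixture (85% high) so
Q30 statistics are non-degenerate. Defaults — 4 samples, dual 8 bp indices,
100 bp biological reads, indices at pairwise distance ≥ 3 — mirror a small
dual-index run.

It does **not** emulate indels, per-cycle error profiles, quality-correlated
errors, index hopping, or optical/PCR duplicates. Passing tests on simulated
runs therefore demonstrate the correctness of the matching, trimming,
header rewriting and accounting machinery under the substitution model —
not robustness to error modes the Hamming model excludes by construction;
on real data those reads simply fall into the undetermined pool.

## What the tests compute, and at what size

Every empirical claim in the package is recomputed by the test suite or
`scripts/acceptance.R`, never hard-coded: lookup answers are compared
exhaustively against a full-scan oracle over all 5⁴ observations of a
length-4 sheet and over a simulated 10 000-read dual-index run at
m ∈ {0,1,2}; a 20 000-read run with ≤ 1 injected error per index is checked
for exact truth-table recovery; conservation, order preservation, template
recovery of the five layouts (1000 error-free reads each) and merge-vs-
concatenation equality run at a few hundred to a few thousand reads per
configuration. These sizes give binomially negligible flake risk for the
exact checks while keeping a full run in the order of a minute.

## Known limitations

Single-threaded streaming only; no BCL input; no quality trimming or
adapter removal; no 10X-specific barcode chemistry; no likelihood- or
quality-weighted rescue of ambiguous reads (by design — such reads are left
for specialised re-demultiplexers); combined index length capped at 22 bp
by the exact key encoding.
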