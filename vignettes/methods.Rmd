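---
title: "Methods: k-mer QC, junction clipping, demultiplexing and the metric store"
author: "knowyourdata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer QC, junction clipping, demultiplexing and the metric store}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knowyourdata)
```

This vignette records the models behind each analysis, the parameter
defaults and why they are what they are, the numerical choices made where
the design was genuinely open, and what the built-in simulator does and
does not emulate.

## Canonical k-mer counting

All analyses share one engine: a window of *k* bases slides base-by-base
over each read; every window free of non-ACGT characters is counted on its
**canonical form**, the lexicographically smaller (A < C < G < T, byte
order) of the k-mer and its reverse complement. Canonical counting makes
every downstream figure invariant under reverse-complementing the input —
a property asserted bit-exactly in the test suite. Windows containing N
are skipped entirely rather than masked or imputed: skipping is
deterministic and matches common k-mer-counter behaviour, at the cost of
slightly undercounting near ambiguous bases.

K-mers are 2-bit encoded in a 64-bit word (so *k* ≤ 32; the defaults are
21 for screening and 31 for spectra) and counted in a hash map in C++;
tables are returned sorted, which makes the two-column text serialization
(`#knowyourdata kmer-table v1 k=<k>` header, `kmer<TAB>count` rows)
diffable and the save/load round trip exact.

**Subsampling.** Screening subsamples 10% of the read stream by default,
for speed. The mechanism is systematic by default — every
`round(1/fraction)`-th read from the first — because it is reproducible
without any seed bookkeeping; a seeded Bernoulli mode is available when
periodicity in the input ordering is a concern. Filtering never
subsamples: a filter that misses 90% of its targets is not a filter.

## Contamination screening

A screen reports two figures: the percentage of sampled reads containing
at least one reference k-mer, and the percentage of the reference's
distinct k-mers observed anywhere in the sampled reads. The second figure
is what separates true contamination from shared sequence: a bacterial
sample will often show many reads carrying k-mers of a related species
while covering only a sliver of that species' genome. "Genome covered" is
implemented as distinct-k-mer coverage rather than per-base coverage — the
screen is k-mer-native and performs no alignment. `interpretScreen()`
encodes the two-threshold rule (defaults: 5% read-hit, 20% coverage; both
configurable — the interpretation logic is principled, the cutoffs are
conventions).

A read counts as a hit when it has at least `min_hit_kmers` matching
windows (default 1, at which "windows" and "distinct k-mers" coincide).
In paired filtering the pair moves as a unit — either mate hitting removes
both — so downstream pairing is never broken.

## K-mer spectra and their interpretation

`computeSpectra()` counts read 1, read 2 and the pooled reads separately;
the combined spectrum comes from one pooled table because a k-mer seen
m₁ and m₂ times in the two files belongs in bin m₁+m₂, which no sum of
histograms can produce.

**Error threshold.** Sequencing errors produce mostly-novel k-mers, hence
a spectrum peak at multiplicity 1. The threshold is the first local
minimum: the smallest *m* with *b(m+1) > b(m)* on dense bins. A monotone
decreasing spectrum has no valley; the analysis is then `undetermined`
rather than guessed at.

**Peaks, ploidy and genome size.** The dense histogram is smoothed with a
centered moving average (default window 5 bins — raw desk-scale histograms
are jagged; the window is a parameter). Local maxima above the threshold
are candidate peaks; candidates reaching at least 25% of the tallest are
retained. The **main peak is the retained peak at the highest
multiplicity**, not simply the tallest. The reason is arithmetic: in a
diploid at coverage *c*, heterozygous k-mers (two haplotype variants, each
at *c*/2) and homozygous k-mers (one variant at *c*) produce peaks whose
heights are nearly equal at realistic SNP rates — at a 1% SNP rate and
k = 31 roughly 0.53·G distinct k-mers at *c*/2 against 0.73·G at *c*,
whose modal bin heights differ by only a few percent — so "tallest" is a
coin flip, while "right-most major peak" is always the homozygous one.
This choice also makes the genome-size estimator ploidy-stable:

$$\hat G \;=\; \frac{\sum_{m > t} m\,b(m)}{m_{main}}$$

divides total above-threshold k-mer mass by the homozygous-peak
multiplicity, returning the haploid genome size (in distinct-k-mer units,
a proxy for bases) for haploids and diploids alike. Heterozygosity is
flagged when a second retained peak lies within ±25% (configurable) of
half the main multiplicity.

On simulated error-free 100 kb genomes at depth 50 the estimate lands
within 5% of the true distinct-k-mer count; the residual error is mostly
the ±1-bin granularity of locating a peak near multiplicity 35.

## Long-mate-pair junction analysis

The junction adaptor defaults to the 38-base Nextera junction (the 19-base
transposon end sequence concatenated with its reverse complement).
Matching is two-tier: interior windows must match the full junction;
at the read ends a prefix/suffix overlap of at least `min_overlap = 18`
bases qualifies. A window passes with at most
`floor(0.11 × overlap)` mismatches — 4 over the full window, scaled down
for partial overlaps. The thresholds are parameters, not citations: they
were fixed once, before any truth-recovery measurement, at values that
make a false hit in random sequence a ≲10⁻⁹-per-window event (the suite
checks ≥99/100 random 100-mers are junction-free).

Pairs are categorized A (junction in both mates), B (read 2 only), C
(read 1 only), D (neither); each detected mate is truncated at the
junction start, since everything beyond it belongs to the distal fragment
end. Pairs whose clipped mate falls under `min_length = 25` are excluded
from output files but still counted — category totals always sum to the
input pair count.

**Duplicates.** The pair signature is the first 16 bases of each raw mate,
concatenated; the rate is `100·(1 − distinct/total)`. Raw (unclipped)
prefixes are used because clipping varies with junction position while
prefixes are stable. Spiking a duplicate fraction *d* into a
distinct-signature library returns exactly `100·d/(1+d)`.

**Orientation.** With both mates mapped to one reference, the mate at the
smaller coordinate is "left": inward-facing (+/−) pairs are `paired_end`,
outward-facing (−/+) are `mate_pair`, equal strands are `tandem`; insert
size is the 1-based outer span. These are geometric labels; whether a
given library chemistry should yield inward or outward pairs after
circularization is left to the user's configuration, not asserted by the
toolkit.

## Offset inline-barcode demultiplexing

Reads carry `offset filler + barcode + overhang + genomic sequence`. Every
(sample, offset) candidate is scored jointly — no first-match shortcut, so
the result is independent of sample-sheet order. A candidate is valid when
the barcode mismatches ≤ 1 (default) and the overhang matches exactly;
the overhang is the restriction-site remnant and is what pins down the
offset, so loosening it (possible via a flag) mainly inflates ambiguity.
The unique minimum-mismatch valid candidate wins; any tie — including two
offsets of the same sample, where trimming would be ill-defined — is
`ambiguous`; no valid candidate is `undetermined`. Trimming removes filler
and barcode from read 1 only and keeps the overhang: it is genomic
sequence. Conservation (`assigned + undetermined + ambiguous = input`)
holds by construction and is asserted throughout.

With barcodes of minimum pairwise Hamming distance 3 or more, one barcode
error cannot reach another barcode's 1-mismatch ball, so assignment under
≤1 error per read is exact — the suite verifies 100% recovery with zero
misassignment on 10,000 simulated reads.

## Read metrics

Per-cycle quality statistics (mean, median, quartiles by linear
interpolation) are computed only over reads reaching each cycle. The
headline yield phrase "average length of read with quality at 30 or
above" admits two readings, so both are reported and labelled: the mean
count of Q ≥ 30 bases per read, and the percent of reads whose mean
quality is ≥ 30 (threshold inclusive). Red flags are breaches of
user-configured minima; none are enabled by default, and flags never
change a pipeline exit status — they are for humans.

## The metric store

Records are named values scoped `run`, `base` (one position) or `range`
(inclusive 1-based span), keyed by run alias, instrument, chemistry and
software versions, lane, sample and barcode. Storage is a typed
data.frame persisted to a single quoted TSV; numerics are written with 17
significant digits so the round trip is bit-exact. `putMetrics()` is an
idempotent upsert on the full record identity. The FastQC
`fastqc_data.txt` parser emits exactly one record per data row (module
pass/warn/fail statuses are stored separately, one per module); position
strings like `10-14` become range scope, single integers base scope.
Toolkit reports convert with scalars as run-scope records, per-cycle
series as base-scope records, and GC histograms as named run-scope
records — GC bins are percentages, not base positions, and do not belong
in the position columns. Grouped aggregation (mean/min/max/n) over
numeric values gives the consolidated cross-run tables; aggregating text
values is an error, not a coercion.

## The simulator, and what passing tests do not show

Generators are deterministic under a fixed seed and every emitted read or
pair has exactly one truth row. Genomes are i.i.d. base draws at a target
GC fraction (diploids add Bernoulli SNPs); reads start uniformly with
uniform strands; errors are uniform substitutions; qualities are constant
Q40 or a per-cycle profile; LMP fragments are normal (truncated below at
twice the read length) and artefact pairs are normal short inserts.

Two modelling choices deserve emphasis:

* **LMP arm lengths** are drawn from
  `[25, read_length − 18] ∪ [read_length, 180]`: an in-read junction
  always shows at least the detector's minimum overlap. Reads in which
  only a shorter junction stub is visible exist in real libraries and are
  intrinsically undetectable by overlap matching; the generator excludes
  that regime so that truth-recovery statements are well-posed.
* **Duplicate spikes** copy existing pairs, so the closed-form rate holds
  exactly only when the base library has distinct signatures (true for
  the simulated scales used).

Real data differ in ways the simulator does not attempt: non-uniform
coverage and GC bias, indels and platform-specific error profiles,
repeat structure in genomes (i.i.d. sequence has essentially no repeated
31-mers at 100 kb), PCR bias beyond explicit duplicate spiking, and
quality-score miscalibration. Passing tests therefore demonstrate
correctness of the algorithms under their stated models — exact category
recovery, exact filter partitions, unbiased spectrum interpretation — not
robustness to every artefact of production data.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical claims are comfortably
identifiable: 100 kb genomes, depth 50 for spectra (≈50,000 reads),
10,000 LMP pairs, 10,000 barcoded reads, 10⁴-record store states. Every
random quantity flows from explicit seeds; generators save and restore
the caller's RNG state, so library calls never perturb user code.
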