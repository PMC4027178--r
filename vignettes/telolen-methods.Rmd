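---
title: "Estimating telomere length from shotgun reads: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating telomere length from shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telolen)
```

## The measurement problem

Telomeres — TTAGGG tandem-repeat arrays at chromosome ends — shorten with
cell division, and their mean length is widely used as a marker of
replicative ageing. Shotgun sequencing samples telomeric DNA like any other
part of the genome, but alignment cannot localize it: the repeat array is
unmappable and reference assemblies terminate in Ns. What alignment discards,
read content retains: the number of telomere motif copies per read
distinguishes telomeric reads from everything else, and the *abundance* of
such reads, relative to sequencing depth, is proportional to total telomere
content.

## Classification: k repeats per read

`telomere_repeat_count()` counts exact occurrences of TTAGGG and of its
reverse complement CCCTAA and takes the maximum of the two. The maximum (not
the sum) is used because a genuinely telomeric read comes from one strand of
a tandem array: its count for one motif is the true repeat number and for the
other motif is essentially zero, so the maximum is the repeat number while
remaining symmetric under reverse complementation — important because BAM
stores reverse-strand alignments as reverse complements. Occurrences are
counted left to right without reusing characters; for these two motifs, which
cannot overlap themselves, this equals counting all match positions. Ns never
match.

A read is classified telomeric when it carries at least `k = 7` repeats.
The threshold is where signal separates from noise: in random sequence the
chance that a 100 bp read contains even a handful of aligned hexamer copies
collapses geometrically, and spectra against the 54 control hexamers — every
permutation of the letters {T,T,A,G,G,G} that is not a cyclic rotation of
TTAGGG, `control_hexamers()` — decay monotonically with repeat count, while
the TTAGGG spectrum turns up again beyond ~7 copies as true telomeric reads
appear. Rotations are excluded from the controls because a tandem array of a
rotation is the same DNA as a tandem array of the motif. The tally retains
the full repeat-count histogram, so `sweep_k()` re-evaluates any threshold
without rescanning; lax thresholds (k around 3–4) matter for exome
libraries, where only the 10–50% off-target fraction of reads carries
genome-wide signal.

## Normalization: GC-matched depth

Converting the telomeric read count `t_k` into a physical length requires a
depth normalizer. The total read count is a poor one: library preparation
amplifies fragments unevenly by GC composition, so read density is
composition-dependent. Telomere repeats are exactly 50% GC, so the estimator
normalizes by `n_gc`, the number of reads whose GC fraction lies in the
48–52% band — reads that experienced the same amplification bias as the
telomeric ones. The matching genome-side constant `L_gc` is the cumulative
reference length at that composition, computed by `gc_profile()`: the
reference is tiled with non-overlapping windows equal to the read length
(default 100 bp) so both sides of the ratio measure GC on the same length
scale; windows containing any N are excluded, as are trailing partial
windows. GC bins are fixed at width 0.02 and all bands are half-open
`[lo, hi)` on that grid, applied identically to reads and windows, so the
default band is exactly bins [0.48, 0.50) and [0.50, 0.52). The estimate is

\[
l = \frac{t_k}{n_{gc}} \cdot \frac{L_{gc}}{n_\mathrm{ends}}
\]

with `n_ends = 46` (23 chromosomes × 2) for a haploid human reference.
`t_k / n_gc` is the telomeric fraction of GC-matched sequencing;
multiplying by `L_gc` converts it to total telomeric bp per haploid genome,
and dividing by the number of ends gives mean length per end. Under uniform
sampling within the band the GC-dependent sampling rate cancels exactly,
which the simulation below verifies by parameter recovery. Telomeric reads
are *not* subtracted from `n_gc` even though their GC is in-band: for a
human-scale genome they are ~10⁻⁵ of band reads, and on synthetic genomes
the same tracts also sit in `L_gc`, so the ratio is consistent; the
second-order bias only matters if the telomere fraction of the genome is
large, which is why `build_genome()` requires a core at least 10× the
telomere tract.

Key defaults, all configurable: `k = 7` (repeat threshold), band 0.48–0.52
(GC fractions), `n_ends = 46`, window 100 bp. `L_gc` may also be supplied as
a plain number for users with an established constant for their reference;
no packaged constant is claimed here.

## Filtering and units of analysis

The input contract is one tally per read group (BAM RG tag; a FASTQ file is
one group), the unit of lane-level technical replication —
`replicate_cv_table()` computes the per-sample coefficient of variation
(SD/mean, n−1 denominator) across lanes. Secondary, supplementary and
QC-fail records are dropped so each molecule counts once; duplicates are
dropped by default (configurable), and unmapped reads always pass, because
telomeric reads mostly fail to map. Pooling across read groups
(`aggregate_sample()`) merges tallies and then estimates — read-count
weighting, identical to estimating the concatenated stream — rather than
averaging per-group estimates. Undefined estimates (no GC-band reads) are
reported as `NA`, never 0, so replicate statistics cannot silently ingest
failures.

## The synthetic validation

`build_genome()` emulates a chromosome whose ends are replaced by perfect
telomere tracts: CCCTAA repeats on the left end and TTAGGG on the right
(reference-strand convention for p and q arms; the estimator is strand
symmetric so this affects realism only), around an i.i.d. core with
configurable GC. `simulate_reads()` draws
`round(coverage × genome_length / (2 × read_length))` fragments with
uniform starts and normal lengths (truncated to `[2 × read_length,
genome_length]`), reads 100 bp from each fragment end, and applies i.i.d.
substitutions to a uniformly chosen different base. Defaults: fragment
length 350 ± 50 bp, a typical paired-end 100 bp library; error rate 1%, an
aggregate per-base substitution figure for such data. The error model is
deliberately uniform — no quality ramps, indels or GC-amplification bias —
because parameter recovery at ~1% substitution is insensitive to error-model
detail: a telomeric read carries ~16 repeats and one expected error, far
from the k = 7 boundary.

`coverage_titration()` runs the full simulate–tally–estimate pipeline across
a coverage grid (default 0.2X–10X in 0.2X steps, 5 replicates each, 250
runs, each with an independently derived seed) on a 5 Mb-core genome with
30 kb tracts, using `n_ends = 2` and `L_gc` profiled from the same genome.
This size keeps the full titration around five minutes on one CPU while
keeping telomeric contamination of the normalizer harmless; the estimator is
scale-free in genome length given a matched `L_gc`, so recovery at 5 Mb
demonstrates the same arithmetic as at 249 Mb. Expected behaviour, asserted
by the test suite:

* **Recovery, slightly low.** Mean estimates sit ~1–2% under the 30 kb
  truth (29.5–29.8 kb): reads straddling the telomere–core junction with
  fewer than 7 repeats are lost (~41 bp per junction), and whole fragments
  must fit inside the chromosome, so read-2 coverage ramps up over roughly a
  fragment length at the left end (and read-1 at the right). Estimates never
  exceed truth beyond sampling noise.
* **Variance inflation at low coverage.** `titration_summary()` compares
  runs below and above 2.5X with a variance F-test; the inflation is large
  and overwhelmingly significant. Mates of a fragment wholly inside a tract
  are both telomeric, so `var(t_k) ≈ 2 t_k` rather than Poisson — measured
  and confirmed by the simulator's own counting statistics.
* **SD of the pooled titration.** Above 2.5X the run-to-run SD is ~0.7 kb.
  Pooled over all coverages it is ~1.0 kb under this design; note that this
  quantity is a property of the titration *layout* (how many runs sit at
  very low coverage, where `t_k` is small) as much as of the estimator, and
  a layout weighting low coverage more heavily, or an error model with
  heavy read-end error ramps, yields larger pooled SDs.

What passing these tests does **not** show: robustness to subtelomeric
degenerate repeats (real subtelomeres contain variant-motif arrays that sit
near the threshold and shift the estimate's offset as k changes), to
interstitial telomeric repeats inside chromosome arms, to GC amplification
bias (the simulator samples uniformly, so the GC-band normalization is
exercised here only in its neutral regime; on real libraries it is precisely
what absorbs that bias), or to aneuploidy (the
per-end conversion assumes a fixed end count). Absolute estimates on real
data are expected to be offset from restriction-fragment (mTRF) measures,
which include ~1 kb of subtelomere.

## Numerical and degenerate-input choices

GC bin assignment uses `floor(frac / 0.02 + 1e-9)` so that fractions like
48/100 land in their own bin despite floating-point representation, with the
top bin closed at 1.0. Band bounds off the 0.02 grid are an error, not
rounded. Zero-length reads are skipped with a warning; an empty GC band is
an explicit error (`estimate_length()`) or an `NA` row (`estimate_report()`,
`coverage_titration()`), never a silent zero or infinity. Seeds: every
stochastic function takes an explicit seed and restores the caller's RNG
state (`withr::with_seed`); the titration derives one sub-seed per run, and
identical seeds give byte-identical simulated FASTQ. Fragment lengths are
rounded normals truncated by clamping; `merge_tallies()` refuses mismatched
histogram geometry rather than resampling. The bootstrap comparison of two
correlations (`bootstrap_corr_diff()`) uses paired case resampling with a
Pearson default, B = 1000, and a two-sided normal reference for the observed
difference over the bootstrap SD — a standard, assumption-light construction
chosen where several bootstrap schemes would be defensible; resamples where
a vector becomes constant are dropped from the SD.

## A small demonstration

A reduced titration (these sizes run in a few seconds; the full-scale run is
in `scripts/acceptance.R`):

```{r demo, eval = FALSE}
genome <- build_genome(core_length = 4e5, telomere_length = 10000,
                       core_gc = 0.5, seed = 1)
tab <- coverage_titration(genome, coverages = c(0.5, 2, 4, 8),
                          replicates = 5, seed = 2)
titration_summary(tab, cutoff = 2.5)
```

The summary reports mean and SD over all runs and over the >2.5X subset, and
the low-versus-high-coverage F-test. The same machinery backs the package's
validation: recovery of a known truth by the exact pipeline a user runs on
real data, BAM ingestion included (`write_reads_sam()` feeds the simulator's
output through the same reader as real alignments).
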