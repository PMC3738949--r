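---
title: "Binned-coverage peak calling: model, parameters and validation"
author: "chipscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binned-coverage peak calling: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chromatin immunoprecipitation followed by sequencing (ChIP-seq) measures
where a protein binds DNA: reads pile up around binding sites. Deciding
which pile-ups are real requires comparing the immunoprecipitated (ChIP)
sample against a non-immunoprecipitated input (control) sample, because the
input itself is non-uniform — open chromatin, copy-number differences and
"pseudobinding" loci at active promoters all produce ChIP-like pile-ups in
both samples. `chipscan` implements the whole desk-side workflow downstream
of read mapping: track building (`parse2wig()`), five-threshold
sliding-window peak calling (`call_peaks()`), swap-based empirical FDR
(`empirical_fdr()`), figure rendering, and a ground-truth simulator.

## Track model

Mapped reads (SAM, Bowtie text, or BED6) are reduced to one record per
mapped locus: chromosome, 0-based leftmost coordinate, strand, aligned
length, and multiplicity $n_k$ — the number of loci read $k$ maps to. All
internal coordinates are 0-based half-open; conversion happens only at
format boundaries (SAM and fixedStep wiggle are 1-based, BED is 0-based),
which confines off-by-one risk to the parsers.

Four steps turn loci into per-chromosome bin vectors:

1. **Mapping mode.** `"unique"` keeps only $n_k = 1$ reads; `"multi"`
   (default) keeps all loci of reads with $n_k \le M$ (default $M = 10$),
   each locus weighted $1/n_k$ so a read contributes unit mass in total;
   `"best"` keeps the best-scoring locus per read with weight reset to 1,
   ties broken deterministically by chromosome order then position (the
   input formats do not always carry scores, so a stable tie-break is
   required for reproducibility).

2. **PCR-duplicate filtering.** Reads sharing a strand-specific 5$'$ end
   beyond a cap $T_b$ are discarded as amplification artifacts. With
   $E(s) = N^s/L$ the expected per-base read count on strand $s$ ($L$ =
   genome length), $T_b = \max(1, \lceil 10 \max_s E(s) \rceil)$. The
   ceiling is our rounding choice for the generally non-integral product;
   the cap is applied after mode selection so the quality report describes
   the reads actually used. Opposite strands are independent keys. The
   filter keeps the first $T_b$ records per key in input order, which makes
   it idempotent.

3. **Fragment extension and binning.** Single-end reads are extended from
   their 5$'$ end to the expected sonication fragment length (default 150
   bp, never shrinking below the aligned length), clipped to the
   chromosome, and the weight $1/n_k$ is added to *every* bin (default 10
   bp) the fragment overlaps. Full-weight coverage-style assignment (rather
   than 5$'$-bin-only or overlap-fractional) matches the visual density
   semantics of read-distribution figures and is what the fragment
   extension is for.

4. **Normalization and smoothing.** Each chromosome is scaled by the
   modified RPKM
   $R_x = 10^6 \cdot (r_x / N_i) \cdot (L_i / 10^8)$ — reads per million
   mapped per 100 Mb — with $N_i$ the *post-filter weighted* read count of
   chromosome $i$ (so tracks describe the data actually binned) and $L_i$
   its length. Normalized values are then smoothed with a centered moving
   average of fixed genomic width (default 500 bp, i.e. 51 bins at the
   default bin size; an even bin count is forced odd). Edge windows
   truncate rather than zero-pad, so a constant track is a fixed point and
   total mass is preserved up to edge effects. Normalization precedes
   smoothing; `smooth = FALSE` disables smoothing.

Because $N_i$ scales linearly with $r_x$, duplicating the entire library
leaves $R_x$ unchanged — a property the tests check to $10^{-9}$.

## Peak calling

The genome is scanned with a sliding window of 30 contiguous bins (stride 1
bin; merging makes contiguous significance stride-insensitive). A window is
significant only when **all five** of these hold (strict inequalities,
evaluated by default on the smoothed track, `use_smoothed = FALSE` for the
unsmoothed one):

| # | quantity | default |
|---|----------|---------|
| i | one-sided Wilcoxon rank-sum $p$ (ChIP $>$ control) | $< 10^{-4}$ |
| ii | fold enrichment $\sum$ChIP / $\sum$control | $> 3.0$ |
| iii | max ChIP bin / ChIP chromosome mean depth | $> 3.0$ |
| iv | control window mean / control chromosome mean depth | $< 10.0$ |
| v | max ChIP bin intensity $R_x$ | $> 6.0$ |

Threshold (iv) rejects repetitive regions that inflate both samples;
threshold (v) makes calls comparable across samples. "Chromosome mean
depth" is the mean of the scanned bin values over *all* bins of the
chromosome, zeros included — all five quantities then live in the same bin
space. No multiplicity correction is applied to (i): the raw $p$ acts
together with four companion filters, and error control is reported via the
empirical FDR instead.

Two numerical choices were genuinely open:

* **Zero-control windows.** The fold denominator is floored at (control
  chromosome mean depth $\times$ window bins $\times$ `control_floor`),
  default 0.1. This pseudo-count-style guard prevents division by zero
  while still letting genuinely depleted-control windows pass.
* **Wilcoxon implementation.** Windows of $\ge 10$ bins per side use the
  normal approximation with midranks, tie-corrected variance and
  continuity correction (identical to `wilcox.test(exact = FALSE, correct
  = TRUE)`, which the tests verify to $10^{-12}$). Smaller windows use an
  exact tail $P(W \ge W_\mathrm{obs})$ computed by dynamic programming over
  the tied-rank multiset; the test suite compares it against full
  enumeration of rank partitions. Fully tied windows return $p = 1$ (no
  evidence). The conservative tail convention means a symmetric null gives
  $p \ge 0.5$, not exactly 0.5.

Contiguous (overlapping or abutting) significant windows merge into one
peak; the peak's $p$ is the minimum and its fold the maximum over member
windows, and the summit is the (leftmost) maximum ChIP bin inside the
merged span. Tightening any one threshold can only remove significant
windows, so peak intervals shrink monotonically — a property test.

The per-window kernel is compiled (Rcpp) with an incrementally maintained
sorted window, so a 10-Mb genome at 10-bp bins (~1M windows) scans in
about a second.

## Empirical FDR

`empirical_fdr()` calls peaks twice with identical parameters — as given
and with ChIP/control swapped — and reports (swapped peaks)/(ChIP peaks).
The estimate is undefined (NA, with a warning) at zero ChIP peaks and
unstable below roughly 100 peaks, where a warning is emitted;
`fdr_threshold_sweep()` tabulates peak counts and FDR across
maximum-intensity thresholds (v), where ChIP peak counts are non-increasing
in the threshold but the FDR need not be monotone when peaks become scarce.

## Sharp vs broad binding

Transcription-factor-style peaks (~1 kb) are called at the defaults.
Histone-modification domains (10 kb–1 Mb) carry modest, spatially extended
enrichment: at 10-bp bins the smoothed signal oscillates around the
absolute intensity threshold and domains fragment into shards. Enlarging
the bin (e.g. 1-kb bins, 2-kb smoothing) both averages the noise and —
because $R_x$ scales with bin width — effectively relaxes the absolute
thresholds, so whole domains merge into single peaks. The acceptance suite
reproduces this contrast on simulated 50-kb domains at 5-fold enrichment.

## What the simulator emulates — and what it does not

`simulate_reads()` draws uniform background fragments, planted peaks
(point-source with fragment-scale jitter for sharp sites; uniform over the
domain for broad ones) at rates giving a configured interval-averaged fold,
pseudobinding sites added to *both* samples, PCR duplicates re-emitting
existing fragments, and repeat families whose reads appear at every
homologous copy with `NH`-style multiplicity. Defaults — the validation
conditions used by the tests and the acceptance script — are a 2 × 5 Mb
genome, $10^6$ 36-bp reads per sample (~15× fragment coverage, a realistic
deep yeast-scale experiment), 20 sharp 1-kb peaks at fold 10, 5
pseudobinding sites at fold 5, 3- and 5-copy 2-kb repeat families, and 2%
duplication. The broad-domain validation plants ten 50-kb domains at fold
5; the null-model validation uses 100 paired track sets drawn from a
shared Poisson background per bin.

The simulator does **not** model sequencing errors or base qualities,
mappability outside the planted repeats, GC bias, chromatin-accessibility
structure in the input beyond discrete pseudobinding sites, or paired-end
reads. Passing the planted-recovery tests therefore demonstrates
correctness of the pipeline's arithmetic and the designed behavior of the
five filters under idealized noise — not peak-calling performance on any
particular real genome.

## Figures

Rendering is split into a pure *figure data model* (bars with positions,
heights, colors per panel: ratio orange, ChIP green, control blue, bins
inside peaks red, gene exons as thick boxes over a thin intron line) and a
thin base-graphics drawing layer (pdf, multi-page at one page per Mb by
default, or png). Tests assert on the model, not on pixels, keeping them
graphics-backend independent. The chromosome-wide view rebins raw counts
to a macro bin (default 100 kb), renormalizes, and colors macro bins red
where ChIP/control strictly exceeds `scale_ratio` (default 1); bins with no
reads in either sample (assembly gaps) are drawn at 0. Y-axes default to
the per-panel maximum.

## Known limitations

* Single-end fragment model only; no fragment-length estimation from data.
* No mappability or GC correction; multi-mapped weighting is the only
  repeat handling.
* The Bowtie parser trusts the "other alignments" column for $n_k$; for
  SAM without `NH` tags multiplicity falls back to counting same-name
  records across the file (two-pass), and to 1 when names are unique.
* The binary track dialect is this package's own documented layout, chosen
  for bit-exact round-trips, and is not interchangeable with other tools'
  binary wiggle formats.
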