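---
title: "Methods: absolute ChIP-chip quantification and centromere-proximity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute ChIP-chip quantification and centromere-proximity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the signal model the
pipeline assumes, what each tunable parameter means, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one convention was defensible.

## Signal model and assumptions

Probe-level tiling-array signal is treated as multiplicative:

\[ y_{ij} \;=\; a_j \, \mu_{ij} \, 2^{\varepsilon_{ij}}, \qquad
   \varepsilon_{ij} \sim \mathcal N(0, \sigma^2), \]

where \(\mu_{ij}\) is the true occupancy of probe \(i\) on array \(j\),
\(a_j\) is an array-level efficiency (amplification, labelling,
hybridization), and noise is Gaussian on the log2 scale — the standard error
model for two-condition tiling data, and the reason linear-scale values stay
positive. Everything downstream follows from this model:

* **Spike-in normalization.** Exogenous control material of known,
  condition-invariant abundance \(r_i\) is measured on every array. The
  estimator \(\hat a_j = \overline{y_{\text{spike},j}} / \bar r\) is removed
  by a single multiplicative factor per array (`scale_by_spike_ins()`).
  Scaling is idempotent and cancels any constant pre-multiplication of an
  array, which the test suite asserts as invariances. Only with this step is
  a *global* gain of signal between conditions measurable at all; per-array
  mean normalization would erase it by construction.
* **Global fold change** is the geometric mean of per-probe ratios,
  \(2^{\operatorname{mean}(\log_2 m_i/w_i)}\) over chromosomal probes
  (`estimate_global_fold_change()`). Under the log-normal error model the
  geometric mean is the unbiased location summary; an arithmetic mean of
  ratios would be inflated by \(e^{\sigma^2 \ln^2 2}\)-type terms. Which
  summary produced the published genome-wide estimate is not stated, so the
  choice is recorded here as the package's own.
* **Domain calling** marks probes strictly above
  `fold_threshold × genome-wide average` on the *linear* ratio track and
  keeps maximal marked runs. "More than \(k\)-fold" is read as
  \(v > k\bar x\) (strict), not \((v-\bar x) > k\bar x\). A region's span is
  `[first probe, last probe + spacing)`, so an \(n\)-probe run has length
  \(n \times\) spacing and a 1 kb minimum is attainable on an even 20 bp
  grid exactly when a run reaches 50 probes.
* **Proximity testing** reduces each region to its midpoint and asks whether
  it lies within `window` bp of a centromere edge. The hypergeometric
  population is made explicit: the genome is tiled into `bin_size` bins
  (1 kb by default, the minimum region length); bins whose midpoints fall in
  centromere bodies are excluded, giving the population size \(N\) and the
  proximal count \(K\), and \(P(X \ge k)\) is evaluated in log space
  (underflow starts near \(10^{-308}\); the interesting values here are
  near \(10^{-80}\)).
* **Metagene profiles** average TSS-aligned, strand-oriented per-gene
  vectors within expression classes and attach two-sided Student-t
  confidence half-widths per position. t intervals are the standard small-n
  choice — the smallest class holds a few dozen genes.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_region_length` | 1000 | bp | minimum enriched-region span |
| `fold_threshold` | 2 | fold over genome mean | strict probe threshold |
| `max_gap` | 0 | probes | sub-threshold probes tolerated inside a run |
| `proximity_window` | 100000 | bp | distance from centromere edge defining "proximal" |
| `smoothing_window` | 100 | probes | centered running-average window |
| `ma_window`, `ma_step` | 100, 1 | genes | occupancy-vs-expression moving average |
| `ci_level` | 0.99 | — | metagene confidence level |
| class boundaries | 8, 10, 12, 14 | a.u. | five expression categories on the 5–15 scale |
| `probe_spacing` | 20 | bp | tiling resolution of the generator |
| `noise_sd` | 0.25 | log2 units | probe-level noise of the generator |
| `n_spike` | 2000 | probes | spike-in control count per array |

The analysis constants (1 kb, 2-fold, 100 kb, window of 100 probes/genes,
99% CIs, the class boundaries) are the published analysis settings and are
defaults, not hard-wired values. The class-boundary conventions required two
decisions the published description leaves open: the endpoints are printed
as "(>14)" and "(<8)", which forces 14 into *high* and 8 into *low*; the
interior boundaries at 10 and 12 are taken lower-inclusive, an arbitrary but
documented tie-break. One published legend says "four groups" while listing
five categories with their sizes; the explicit five-category list is
followed. Distance to a centromere is measured from the interval's *edges*
(not its midpoint), boundary-inclusive — with three centromeres and 100 kb
flanks this makes the proximal territory 600 kb of 12.57 Mb ≈ 4.8% of the
fixture genome, which is why the edge convention was adopted.

## What the generator emulates — and what it does not

`build_genome_model()` creates three chromosomes of 5.58/4.54/2.45 Mb with
centromeres of 40/65/110 kb at their midpoints and subtelomeric 50 kb ends:
the scale of the fission-yeast genome, chosen so the proximal genome
fraction reproduces the 4.8% figure. Genes are packed without overlap into
equal slots per chromosome arm (5073 by default), each occupying a seeded
random 45–80% of its slot; expression classes are assigned at *exactly* the
calibrated 815:1904:1726:591:37 proportions and values drawn uniformly
within each class interval. Exact counts, rather than multinomial sampling,
are the study condition here: the rarest class holds only 37 genes, and a
multinomial draw would routinely miss published class sizes by more than
the tolerance the recovery checks assume.

`simulate_probe_tracks()` plants: a flat wild-type baseline of 1.0; a
uniform mutant multiplier (`global_fold`); rectangular enrichment domains of
fixed linear fold; and transcription-coupled depletion multiplying mutant
gene-body signal by \(2^{s\,(E_g - 5)}\) with slope \(s\) per expression
unit (negative \(s\) depletes transcribed genes, emulating failure to
re-deposit histones behind RNA polymerase II). Spike-in probes live on a
separate virtual contig, keeping chromosomal coordinates clean.
`plant_domains()` spaces domains ≥ 6 kb apart on an even grid and keeps
proximal midpoints a guard distance (500 bp plus half a grid step) inside
the 100 kb boundary and distal ones outside it, so the planted truth cannot
be flipped by probe-level jitter of a called region's midpoint. The 100 kb
flanks barely hold 96 domains at 6 kb spacing (96 × 6 kb = 576 kb of
597 kb usable), which is why the explicit guard must stay small.

Defaults the data do not pin down: 20 bp probe spacing and σ = 0.25 log2
noise (0.2 in the fold-change recovery setting) are fixture choices in the
range of oligonucleotide tiling platforms, not claims about any particular
array.

The generator deliberately omits: probe GC/affinity bias and
cross-hybridization, saturation, replicate arrays, copy-number variation,
and any sequence-level realism — there is no FASTA. Passing recovery tests
therefore shows the estimators are correct *under the stated error model*,
not that they are robust to platform artifacts real arrays carry; with
rectangular planted domains the caller's exact-count recovery is easier
than on real, ragged enrichment.

## Numerical choices and degenerate inputs

* Even smoothing windows are widened to the next odd integer for an
  unambiguous centered window; chromosome ends use truncated (shrinking)
  windows rather than padding, so no data are invented.
* Domain calling requires an even probe grid per chromosome and rejects
  mixed spacing; `max_gap = 0` is the default because no gap-merging rule
  is published — it is the most conservative reading and is exposed as a
  parameter. Calling runs on the raw ratio track by default; smoothing
  before calling is available (`smooth = TRUE`) since the published figures
  display smoothed curves without saying which signal the search used.
* Coordinates are 0-based half-open everywhere internally (BED convention);
  GFF3 converts to 1-based closed only at the file boundary, and the
  conversion is round-trip exact. A minus-strand gene's TSS is its
  exclusive upper bound, and its metagene offsets reflect probe *intervals*,
  which makes mirror-symmetric signal give identical plus/minus vectors —
  a property the tests assert exactly.
* Degenerate inputs error loudly and early: empty spike sets, non-positive
  spike means, grids that differ between conditions, division by zero in
  linear ratios, windows exceeding a chromosome's probe count, empty region
  lists passed to the proximity test, infeasible gene packing, overlapping
  planted domains.
* %IP values above 100 are reported with a warning rather than capped —
  they indicate dilution bookkeeping errors the user must see. A single
  qPCR replicate yields an undefined (NA) standard deviation, flagged, not
  zero. Relative enrichment is a ratio of means, matching how a relative
  bar is formed from two plotted means, and satisfies
  \(r(a,b)\,r(b,a) = 1\).

## Problem sizes

The default fixture tiles 628,500 chromosomal probes (12.57 Mb / 20 bp),
the size at which all recoveries run: the planted-domain experiment calls
regions on the full grid, and the fold-change recovery uses the same grid
with ≥ 10⁵ probes as its design floor. At these sizes the standard error
of the mean log2 ratio is ~4 × 10⁻⁴ and the spike-factor error ~0.3% per
array (2000 spikes, σ = 0.2), so the 1.7× recovery tolerance of 2% and the
one-decimal reporting precision hold with large margin at any seed — the
margins, not a favourable seed, carry the recoveries. Property suites use
smaller genomes (~1.5 Mb, 300–400 genes) and brute-force oracles on tracks
of ≤ 500 probes, where exhaustive enumeration is feasible.

## Interface

The package is driven from R: exported functions per stage and
`run_pipeline()`, which composes them and writes tracks (bedGraph), regions
(BED5), gene annotations (GFF3), tables (TSV), a JSON manifest capturing
seed, parameters and stage counts, and a stage log. A shell wrapper would
add nothing over `Rscript -e` for this audience, so none is shipped;
`scripts/acceptance.R` shows the headless usage pattern.

## Known limitations

* The hypergeometric population behind the published significance statement
  is not specified there; under this package's explicit 1-kb-bin
  parameterization the same counts give log₁₀ p ≈ −82, so published tail
  magnitudes should be read as qualitative bounds when comparing.
* Region proximity is decided by the midpoint alone; a long region
  straddling the window boundary contributes once, by midpoint.
* The caller is a threshold rule, faithful to the published search: no HMM
  or changepoint segmentation, and no FDR control on region calls.
* Expression values are fixture inputs, not estimated from RNA data; the
  metagene machinery consumes whatever per-gene values are supplied.
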