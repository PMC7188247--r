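---
title: "Methods: copy-number, fragment-size and concentration analysis of plasma cfDNA"
author: "plasmaSCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number, fragment-size and concentration analysis of plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plasma of cancer patients contains circulating cell-free DNA (cfDNA), a
small and variable fraction of which is tumor-derived (ctDNA).  Two
physical signatures separate the tumor component: somatic copy number
alterations (SCNAs), visible as coherent shifts in binned sequencing
coverage even at very shallow depth (~0.1x), and fragment length — ctDNA
is shifted below the mononucleosomal ~167 bp mode of healthy-tissue
cfDNA.  plasmaSCNA implements the computational chain that exploits both:
shallow whole-genome sequencing (sWGS) bin counts, GC-bias correction,
median-normalized log2 copy-number profiles, in-silico size selection,
and the trimmed median absolute deviation from copy-number neutrality
(tMAD) as a single-number ctDNA detection statistic.  Alongside it sit
the longitudinal statistics used when cfDNA concentration is followed
through chemo-radiotherapy: Bland–Altman limits of agreement for repeat
sampling, baseline summaries, change-from-baseline by histology, an
exact rank-sum test and Spearman correlation.

Because studies of this design deposit no raw sequencing data, the
package ships a fully seeded synthetic-data module that generates
fragment tables and concentration series with the statistical structure
the analysis assumes.  Every pipeline stage is exercised end-to-end on
simulated data; the limits of that evidence are discussed at the end.

## The copy-number pipeline

### Binning and counting

The genome (by default one synthetic chromosome) is divided into
contiguous, non-overlapping, 0-based half-open bins (`make_bins()`).
Each fragment is assigned to exactly one bin by its midpoint,
`floor((start + end)/2)` — unambiguous and length-unbiased for fragments
straddling a boundary.  Fragments whose midpoint lies outside all bins
are dropped and counted in the report.  The default geometry — 1000 bins
of 1 Mb — was chosen so that a 5-million-fragment sample (the depth-QC
minimum) yields ~5000 fragments per bin.  At that depth the noise floor
of the detection statistic sits safely below the 0.015 threshold (see
below), which is the regime the method is designed for.

### GC correction

Library preparation and sequencing over- or under-represent bins as a
smooth function of their GC content.  `gc_correct()` fits a local
regression (`stats::loess`, span 0.3, degree 2, robust `"symmetric"`
fitting so genuinely altered segments are down-weighted as outliers) of
raw count on GC fraction over usable nonzero bins, then rescales each
bin by `raw / f(gc) * median(f)`.  The rescaling preserves the overall
count level (the median changes by well under 0.5%), so the subsequent
normalization is unaffected.  Numerical guards: with fewer than 20
informative bins the fit is refused (use raw counts instead); a
degenerate GC track (all values equal) short-circuits to the identity;
bins where the fitted curve collapses below 1e-6 of its median are
masked rather than divided.

A known limitation: local regression can only separate GC effects from
copy-number effects when altered bins do not dominate any GC stratum.
With realistic bin counts (hundreds to thousands of bins, alterations a
minority at any GC value) the robust fit leaves segment boundaries
intact, and the package's parameter-recovery tests run in that regime.
In a caricature where one large altered segment monopolizes the high-GC
tail, part of the signal is absorbed into the curve — as it would be in
any coverage-based GC correction.

### Log2 profile and SCNA calls

`to_log2_profile()` computes `r_i = log2(corrected_i / m)` with `m` the
median corrected count over usable nonzero bins, pinning copy-number
neutrality at `r = 0` by construction (`median(2^r) = 1`).  Zero-count
bins are masked, never mapped to `-Inf`.

`call_scnas()` reports maximal runs of at least `min_bins` consecutive
usable bins at or beyond the gain/loss thresholds (defaults ±0.15 log2
units, `min_bins = 10`).  No segmentation model (CBS, HMM) is imposed:
bin-level thresholding with a minimum run length is the minimal faithful
reading of "is the region increased or decreased", and the defaults were
chosen so that neutral noise at the default depth produces essentially
no calls (the suite measures a false-call rate below 5% over 100 seeded
neutral samples; ±0.15 is ~7 standard deviations of bin noise at 5000
fragments/bin).

## Size selection and tMAD

`size_select()` retains fragments with length in the inclusive window
[90, 150] bp.  Inclusivity at both ends is a deliberate reading of
"between 90 and 150 bp"; the bounds are parameters.  Selection is an
order-preserving, idempotent subset, and retained/dropped counts are
attached for QC reporting.

`tmad()` summarizes genome-wide SCNA burden: absolute deviations
`d_i = |r_i|` of usable bins from neutrality, the `ceiling(q*n)` largest
discarded (one-sided trim, default `q = 0.05`), and the median of the
rest returned.  Design choices:

* The trim is one-sided — only the largest deviations are removed — so a
  handful of extreme bins (focal amplifications, artifacts) cannot
  dominate, while the bulk of the genome sets the level.  The exact
  trimming scheme is not standardized in the field, so `q` is an exposed,
  documented parameter rather than a constant.
* No normal-consistency factor (1.4826) is applied: the conventional
  0.015 detection threshold is stated on the raw trimmed-median-deviation
  scale, and the package applies it there.
* Detection is strict: `tmad > threshold`, so a value exactly at 0.015
  does not flag.
* tMAD is computed on the GC-corrected, median-normalized log2 profile —
  the only profile the pipeline produces.

### The noise floor is depth-specific

For a copy-neutral genome with `N` fragments over `B` bins, bin counts
are approximately Poisson with mean `N/B`, so the log2 ratio has
standard deviation `sigma ~ 1/(sqrt(N/B) * ln 2)` and the untrimmed
median absolute deviation is `0.6745 * sigma`; the 5% one-sided trim
lowers the median slightly (to the 47.5th percentile of the half-normal,
factor 0.636).  At 5000 fragments/bin this gives ~0.013 — just below the
0.015 threshold, which is why the default geometry is what it is.  The
acceptance machinery verifies this prediction by simulation.

The flip side: in-silico size selection keeps only ~20% of a neutral
sample's fragments (the [90,150] mass of the 167±20 bp length model), so
the selected arm of a 5M-fragment sample runs at ~1000 fragments/bin
where the noise floor is ~0.029 — above the threshold.  A fixed tMAD
threshold is therefore only meaningful at a stated depth: applied
naively after size selection it will flag even tumor-free samples.  The
paired pipeline (`compare_pipelines()`) is still informative — the
selected arm's tMAD responds much more steeply to tumor fraction, and
the package's property tests assert exactly that paired, directional
statement (selected ≥ unselected per seed; detection rate non-decreasing
in tumor fraction in both arms) rather than the absolute specificity of
the selected arm at fixed threshold.  Users calibrating a real assay
should set the threshold from matched-depth controls.

### Depth QC

`qc_depth()` flags samples below 5 million fragments (the conventional
minimum for copy-number evaluation at this bin size; 4 million is an
accepted alternative convention and both are reachable through
`min_fragments`).  Failure is a flag carried into reports, not a hard
stop — an under-sequenced sample can still be profiled, it simply
carries the flag.

## Concentration dynamics

* **Bland–Altman** (`bland_altman()`): measurements are clustered within
  patient (baseline test/retest; the three post-chemotherapy draws; the
  three post-radiotherapy draws), each measurement's difference from its
  own cluster mean is taken, and the pooled differences give
  `mean ± 1.96 * SD` limits with the sample (n−1) SD — the small-n
  convention.  Deviations from a size-`m` cluster mean have SD
  `sigma * sqrt(1 - 1/m)`; pooling one pair and two triplets gives
  `sigma * sqrt(5/8)`, the closed form the simulation tests check.
* **Baseline summaries** (`summarize_baseline()`): test/retest pairs are
  averaged within patient before any statistic; median and range over
  patients; per-histology means over a declared subset.
* **Change from baseline** (`change_from_baseline()`): per-patient
  deltas, grouped by histology with mean and range.  Missing timepoints
  are excluded pairwise and surfaced in the result, never imputed; a
  missing baseline is an error.
* **Exact rank-sum test** (`rank_sum_exact()`): the two-sided p-value is
  the null probability that the rank sum deviates from its mean by at
  least the observed amount, over all label assignments of the pooled
  midranks.  Doubling the midranks makes all subset sums integers, so
  the exact distribution is built by a generating-function recursion
  (counts of size-k subsets by sum) without materializing the
  `choose(n, n_a)` assignments; up to 12 per group this is instant.
  Beyond that a tie-corrected normal approximation (no continuity
  correction) takes over.  Midranks handle ties throughout.
* **Spearman correlation** (`spearman_rho()`): product-moment
  correlation of midranks via `stats::cor`; a constant vector is
  reported as undefined (`NA` with a warning) rather than silently 0.

## The synthetic-data generator

The generator's defaults are the study conditions the package is tested
under, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| fragments/sample | 5,000,000 | the depth-QC minimum |
| bins | 1000 × 1 Mb | ~5000 fragments/bin, noise floor below 0.015 |
| normal length model | round(N(167, 20)) bp | mononucleosomal mode |
| tumor length model | round(N(145, 20)) bp | tumor cfDNA shifted shorter |
| GC bias | exp(−8·(gc − 0.45)²) | mild, smooth, unimodal coverage bias |
| GC track | AR(1), lag-1 r = 0.95, mapped to [0.30, 0.60] | megabase-scale GC drift |
| measurement SD | 1 ng/ml | 1.96·SD ≈ the ±2 ng/ml repeatability band |
| count noise | multinomial (+ optional gamma over-dispersion) | Poisson-like per bin |

Fragments fall in bin `i` with probability proportional to
`w_i · bias(gc_i)` where `w_i = (1−tf)·2 + tf·c_i` is the tumor/normal
mixture weight; within a bin a fragment is tumor-derived with
probability `tf·c_i/w_i`, draws its length from its compartment's model,
and starts uniformly in the bin.  The true origin is carried in a
column downstream stages never read, so enrichment can be asserted in
tests without information leaking into the pipeline.  All generators are
bit-reproducible under a fixed seed and restore the global RNG state.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: mappability and blacklist
structure, replication-timing and fragmentation-site coverage waves,
multi-chromosome karyotypes (a single synthetic chromosome is the
default), subclonal copy-number mixtures, library duplicates, and any
non-Gaussian tail of Qubit quantification error.  Conclusions from the
test suite are about the correctness of the computations under the
stated statistical model, not about clinical sensitivity.

## Problem sizes in the test suite

The property tests run at the default statistical regime (5000
fragments/bin) with genome sizes chosen to keep a full run comfortable
on one CPU: 100 paired seeds at 5M fragments for the size-selection
comparison, a 5-point tumor-fraction grid (0–0.1) with 20 common-seeded
replicates at 2.5M fragments/500 bins, boundary-recovery at 1000 bins,
and 100 seeded neutral samples for the false-call rate.  Common random
seeds across the tumor-fraction grid couple the replicates so the
monotonicity check is not dominated by between-seed noise.

## Known limitations

* BED-like text fragment tables are the interface; alignment-level
  processing (duplicate marking, mapping quality) is upstream and out of
  scope, and BAM ingestion is deliberately not a core dependency.
* The fixed 0.015 tMAD threshold is depth-specific (see above); the
  package applies it as stated but exposes it as a parameter.
* Run-length SCNA calling has no segment-merging across masked bins; a
  masked bin inside a true segment splits the call.
* GC correction assumes altered bins are a minority within every GC
  stratum.
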