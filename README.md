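# plasmaSCNA

Detection of circulating tumor DNA (ctDNA) from shallow whole-genome
sequencing (sWGS) of plasma cell-free DNA (cfDNA), and the longitudinal
statistics used when cfDNA is monitored through chemo-radiotherapy.

Tumor-derived cfDNA carries two exploitable signatures: somatic copy
number alterations (SCNAs), visible as coherent shifts in binned
sequencing coverage even at ~0.1x depth, and fragment length — ctDNA
sits below the mononucleosomal ~167 bp mode of healthy-tissue cfDNA.
`plasmaSCNA` implements the full computational chain for both, plus a
seeded synthetic-data generator so every stage runs and is tested
without any sequencing download.  It is aimed at computational
biologists building or evaluating liquid-biopsy copy-number pipelines.

## The core statistics

Fragments are counted into fixed-size genome bins by midpoint, GC-bias
is removed with a robust local regression of count on GC fraction, and
each usable bin gets a log2 ratio

```
r_i = log2( corrected_i / median(corrected) )
```

so copy-number neutrality sits at `r = 0`.  Genome-wide SCNA burden is
summarized by the **trimmed median absolute deviation from copy-number
neutrality (tMAD)**: with deviations `d_i = |r_i|` over the `n` usable
bins, discard the `ceiling(q*n)` largest (one-sided trim, default
`q = 0.05`) and take the median of the rest.  A sample is called
ctDNA-positive when `tMAD > 0.015` (strict).  **In-silico size
selection** — keeping fragments of 90–150 bp inclusive — enriches the
shorter tumor-derived fragments and steepens tMAD's response to tumor
fraction; `compare_pipelines()` runs both arms on the same sample.

For concentration series the package provides Bland–Altman limits of
agreement (`mean ± 1.96·SD` of within-cluster differences, n−1 SD),
baseline summaries with test/retest averaging, change-from-baseline by
histology, an exact two-sided Wilcoxon rank-sum test on midranks
(generating-function enumeration, ties included), and Spearman's rho.

## Worked example

Simulate a 5-million-fragment plasma sample at 5% tumor fraction with a
copy-number gain (c = 4) over 20% of the genome, then run the paired
detection pipeline:

```r
library(plasmaSCNA)

bins  <- make_bins(n_bins = 1000, bin_size = 1e6, seed = 42)
seg   <- data.frame(from = c(1, 401, 601), to = c(400, 600, 1000),
                    cn   = c(2, 4, 2))
truth <- make_truth(bins, seg, tf = 0.05)
frags <- simulate_fragments(truth, bins, n_fragments = 5e6, seed = 43)

compare_pipelines(frags, bins)
#> <pipeline_comparison> size window [90, 150] bp; depth QC PASS
#>   unselected    5000000 fragments  tMAD 0.0172  DETECTED      0 SCNA call(s)
#>   selected      1143276 fragments  tMAD 0.0394  DETECTED      1 SCNA call(s)
```

At 5% tumor fraction the unselected arm's tMAD (0.0172) barely clears
the 0.015 threshold, and no individual region survives run-length SCNA
calling.  After size selection the tumor fraction of the retained
fragments roughly triples: tMAD more than doubles and the gained
segment itself becomes callable — the sensitivity gain that motivates
size selection.

The bundled ten-patient NSCLC cohort baseline table reproduces the
cohort-level concentration summaries:

```r
summarize_baseline(cohort_baseline(as_series = TRUE))
#> <baseline_summary> 10 patient(s)
#>   median 3.87 ng/ml, range [1.47, 17.78]
#>   AC: mean 3.69 ng/ml (n = 4)
#>   SCC: mean 6.83 ng/ml (n = 6)

part2 <- subset(cohort_baseline(), study_part == 2)$patient
summarize_baseline(cohort_baseline(as_series = TRUE), group_subset = part2)
#>   AC: mean 2.97 ng/ml (n = 3)
#>   SCC: mean 5.86 ng/ml (n = 3)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/plasmascna.R` (subcommands `simulate-fragments`,
`size-select`, `profile`, `tmad`, `dynamics`, `run-all`), and
`run_all()` drives the whole pipeline from a serializable
`run_config()`.

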