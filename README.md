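# txchromdyn

Transcription and chromatin dynamics from interval-level sequencing data.

Cells answer genotoxic stress by re-organising transcription: promoter-
proximally paused RNA polymerase II is released into gene bodies, a
synchronized elongation wave advances along long genes, incompletely
processed nascent transcripts linger, and the nucleosomes downstream of
active promoters shift and blur. txchromdyn is a tidyverse-native R toolkit
for quantifying each of these layers from the standard intermediate files of
ChIP-seq / GRO-seq / pulse-chase / ATAC-seq experiments — gene tables, read
and fragment intervals (BED), peak sets, and count tables — for
computational genomicists who want the bespoke statistics of such studies as
tested, reusable, seeded functions rather than one-off scripts.

## What it computes

* **Escape index (EI).** Per gene, EI = D<sub>b</sub>/D<sub>p</sub>, the
  gene-body read density (+100 to +2000 bp from the TSS, rpm/bp) over the
  promoter-proximal density (−250 to +100 bp). ΔEI = EI₊UV/EI₋UV, and the
  percentage of genes with ΔEI > 1 summarises pause release. Includes the
  TSS-clustering, ≥2 kb, and clear-signal annotation filters, peak region
  assignment (TSS/intragenic/TTS/intergenic), and peak-overlap activity
  classification (active / repressed / inactive / ambiguous).
* **Elongation wave.** A two-state left-to-right Poisson HMM
  (ON → ON/OFF, OFF absorbing) fit by exact EM on gene×bin count matrices;
  Viterbi front calls per gene, per-timepoint medians, and elongation speed
  as the least-squares slope of median front (kb) vs time (min).
* **Intron retention.** Pulse-chase retention = CPM intronic(t₁) / CPM
  nascent gene(t₀) after a self-contained median-activity filter, with an
  IQR-trimmed, seeded resampling permutation t-test for cell-line
  differences.
* **Nucleosome organisation.** Vplots (fragment size × midpoint offset
  around +1 dyads), zero-floored Vplot subtraction, flatten/band tests, a
  kernel-density dyad caller with occupancy and fuzziness, modal +1/+2
  spacing (distances >1 kb excluded), and fuzziness comparison of ΔEI
  extremes.
* **Synthetic data with ground truth** for every analysis, and a
  manifest-driven `run_pipeline()` that writes tables, JSON summaries, and
  a checksum index (byte-reproducible given a seed).

Everything takes a data frame first and returns a tibble; fitted objects
have broom-style `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
figures.

## Worked example

```r
library(txchromdyn)

genome <- simulate_genome(n_genes = 400, seed = 42)
genes  <- genome$genes |> filter_min_length() |> filter_clear_signal()

sim     <- simulate_chip_reads(genes, seed = 43, responder_fraction = 0.3)
ei_ctrl <- compute_ei(sim$control, genes)
ei_uv   <- compute_ei(sim$treated, genes)
deltas  <- compute_delta_ei(ei_ctrl, ei_uv)
head(deltas, 3)
#> # A tibble: 3 × 5
#>   gene_id ei_control ei_treated delta_ei increased
#>   <chr>        <dbl>      <dbl>    <dbl> <lgl>
#> 1 G00001       0.781      0.539    0.690 FALSE
#> 2 G00002       1.41       3.03     2.14  TRUE
#> 3 G00003       1.10       1.11     1.01  TRUE
percent_increased(deltas)
#> [1] 65.5
```

30% of genes were simulated as responders (2× body-intensity boost after
UV), yet 65.5% show ΔEI > 1: a non-responding gene still exceeds 1 about
half the time under symmetric counting noise, so the measured percentage
sits near `100·f + (1−f)·50`. The generators expose this noise floor
directly (measure it at `responder_fraction = 0`), which is how the
recovery tests correct for it.

```r
wave   <- simulate_wave(seed = 44, n_genes = 300, speed = 2,
                        timepoints = c(10, 20, 60))
fronts <- dplyr::bind_rows(lapply(names(wave$counts), function(tp) {
  fit <- fit_wave_hmm(wave$counts[[tp]], bin_size = wave$bin_size)
  dplyr::mutate(call_fronts(wave$counts[[tp]], fit),
                timepoint = as.numeric(sub("^t", "", tp)))
}))
wave_summary(fronts)
#> # A tibble: 3 × 7
#>   timepoint     n n_censored median_bp  q1_bp  q3_bp median_kb
#>       <dbl> <int>      <int>     <dbl>  <dbl>  <dbl>     <dbl>
#> 1        10   300          0     19800  18600  21300      19.8
#> 2        20   300          0     39900  38400  41325      39.9
#> 3        60   300          0    119900 118300 121400     120.
estimate_speed(wave_summary(fronts))
#> Elongation wave speed: 2.001 kb/min (intercept -0.18 kb, 3 timepoints)
```

The planted 2 kb/min wave is recovered to three digits: median fronts of
19.8, 39.9 and 120 kb at 10, 20 and 60 minutes. See
`vignettes/methods.Rmd` for the models, assumptions, and design decisions.

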