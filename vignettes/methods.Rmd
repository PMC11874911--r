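---
title: "Models and methods behind txchromdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind txchromdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txchromdyn)
```

txchromdyn characterises four layers of transcription and chromatin
dynamics from interval-level sequencing data: release of promoter-proximally
paused RNA polymerase II (escape index), progression of the synchronized
elongation wave after release (a hidden Markov model on binned
nascent-transcription signal), persistence of unprocessed nascent RNA
(pulse-chase intron retention), and nucleosome organisation downstream of
active promoters (Vplots, dyad calling, fuzziness and spacing). This
vignette documents the models, their assumptions, the tunable parameters,
and the design decisions taken where the problem was genuinely open. All
empirical claims below are the ones the package's test suite and
`scripts/acceptance.R` compute on synthetic data; nothing is quoted from
external datasets.

## Gene universe

All metrics are anchored on strand-oriented windows around the TSS or TTS
of a filtered gene set, in BED convention (0-based, half-open; the TSS of a
minus-strand gene is its `end` coordinate). The filters mirror standard
promoter-metric practice:

* `cluster_tss(radius = 50)` — transcripts whose TSSs lie within 50 bp on
  the same chromosome and strand collapse to the longest representative
  (single linkage; ties broken by smallest `gene_id`, a deterministic rule
  chosen because "longest" alone is not a total order).
* `filter_min_length(min_len = 2000)` — promoter (−250/+100) and body
  (+100/+2000) windows must fit inside the gene, so only genes of at least
  2 kb are meaningful; the threshold is inclusive.
* `filter_clear_signal(window_up = 250, window_down = 2000)` — a
  neighbouring TSS inside a gene's own promoter/body footprint contaminates
  both windows, so **both** members of such a pair are removed. The window
  is strand-oriented because every other window in the toolkit is.

`assign_region_category()` labels peaks by TSS (±0.5 kb), TTS (±0.5 kb),
intragenic (the oriented remainder of the body), or intergenic. A peak
touching several footprints gets one label by the fixed priority
TSS > TTS > Intragenic > Intergenic — a deterministic partition that sums
to the number of input peaks — and `multiple = TRUE` additionally reports
every footprint it touches, since pooled-peak category counts can
legitimately double-count spanning peaks.

## Escape index

For each gene, `compute_ei()` counts reads overlapping the
promoter-proximal window (−250 to +100 around the TSS) and the gene-body
window (+100 to +2000), converts them to densities in rpm/bp, and reports
`EI = Db / Dp`. Window counting uses any-overlap semantics (the
`coverageBed -counts` convention); the ratio is library-size invariant.
Two decisions matter:

* **No pseudocounts.** Genes with `Dp = 0` are dropped and counted in a
  message rather than smoothed; smoothing would silently bias ΔEI for
  weakly expressed genes.
* **Strict increases.** `delta_ei = EI_treated / EI_control`, and
  `increased` means `delta_ei > 1` exactly; ties are not increases, so a
  condition compared against itself yields `percent_increased()` of 0.

Because a non-responding gene still flips a fair coin under symmetric
counting noise, the *percent increased* statistic has a noise floor near
50%. The synthetic generator exposes this directly: with
`responder_fraction = 0`, the measured percent sits at 50 ± a few points.
Recovery tests therefore measure the floor in a matched null simulation
(same seed, hence same per-gene noise via per-gene RNG substreams) and
correct the measured percent as `(m − floor) / (100 − floor)`; replicate
averaging then suppresses Monte Carlo error of the measurement itself.
These are properties of the *estimator*, not adjustments to the planted
conditions.

`classify_activity()` implements the peak-overlap truth table over the
−250/+2 kb extended TSS region: overlap with both elongating-polymerase
(Ser2P) and H3K27ac peaks is *active*; H3K27ac together with H3K27me3 is
*ambiguous* (evaluated first and excluded downstream); H3K27me3 alone is
*repressed*; no overlap is *inactive*. The same extended region is used for
all three marks — the simplest reading consistent with a single region
definition.

## Elongation-wave HMM

After release from pausing, nascent-transcription signal forms a wave: bins
between the TSS and the front are transcribed, bins beyond it are not. The
model in `fit_wave_hmm()` is the minimal chain consistent with a single
advancing front: two states (ON, OFF), the gene starts ON, ON persists with
probability `p_stay_on` per bin, OFF is absorbing, and emissions are
Poisson with means `lambda_on > lambda_off`. Every hidden path is therefore
determined by its front index *k*, so the E-step is computed exactly by
enumerating *k* with cumulative sums — mathematically identical to
forward–backward for this chain, at O(genes × bins) per iteration. EM
initialisation is deterministic (top-decile bin mean for `lambda_on`,
bottom-half mean for `lambda_off`), convergence is a log-likelihood gain
below 1e-6 or 200 iterations, and the log-likelihood trace is monotone
(checked by tests). `call_fronts()` Viterbi-decodes each gene;
`front_bp = bin_size × k`, with `k = 0` for silent genes and a `censored`
flag when the front hits the region boundary. With `lambda_off = 0` the
decode provably reduces to the last-nonzero-bin rule, which the tests
exploit as an independent cross-check.

Speeds come from `estimate_speed()`: an ordinary least-squares line of
median front (kb) against time (min), intercept free. Region sizing follows
the two-threshold practice for this assay (first 100 kb of >100 kb genes at
early timepoints, longer regions late); the simulations here use a 150-kb
region so that a 2 kb/min front remains uncensored at 60 min. Problem sizes
in the tests (300 genes × 1,500 bins per condition; 60-gene replicates for
the ordering check) were chosen as the smallest sets at which the
recovery tolerances are comfortably met.

`compare_fronts()` offers both published readings of the significance
annotation: a paired t-test on per-gene front differences, and a seeded
permutation test with a Pearson (point-biserial) statistic. Constant
nonzero paired differences have zero variance; the paired test then reports
the smallest representable p with a `degenerate` flag instead of failing.

## Pulse-chase retention

`derive_intronic()` defines intronic counts by subtraction
(`gene − exonic`, floored at zero with a logged count of negatives), and
`median_activity_filter()` keeps genes whose gene-level counts strictly
exceed the per-condition median in *every* supplied condition — a
self-contained activity filter needing no external annotation. Retention of
a gene is the CPM-normalised intronic count at the chase timepoint over the
CPM-normalised nascent gene count at baseline. Under exponential intron
decay at rate λ the expected retention is `exp(−λt)`; the generator
emulates exactly this, and stamps a *common nominal library size* on all
tables (depth-matched libraries). This matters: if library sizes were taken
as column totals, the decayed late-timepoint library would inflate
retention by its lost mass and the `exp(−λt)` identity would not hold.

### The IQR permutation test

The group test is a 1000-fold permutation t-test on quartile-trimmed
values with 100 sampling instances. Two details of that procedure are
genuinely open (pooled vs per-group quartiles; what exactly is resampled),
so the package picked the variant that is *calibrated*:

* Trimming at **pooled** quartiles keeps the retained values exchangeable
  under the null. Trimming each group at its own quartiles was measured at
  a type-I rate of ~0.3 at α = 0.05 (each group's trimmed values then live
  on their own interval, and the observed partition becomes extreme
  relative to any permutation of the pooled values — significance is
  manufactured from sampling noise).
* Instances subsample `min(|A'|, |B'|)` values per group **without
  replacement**; each instance computes a Welch t and a permutation null on
  its own draw with the add-one rule (`p` is never 0), and the reported p
  is the median over instances. Measured type-I rate: ≈0.045–0.05.
  The bootstrap (with-replacement) reading is available via
  `replace = TRUE` and measured ≈0.07.

The defaults (`n_perm = 1000`, `n_sampling = 100`) follow the procedure's
description; calibration harnesses in the tests run scaled-down settings
(smaller groups, fewer permutations and instances) so that the replicate
count — which controls the precision of the measured rate — can be large.

## Nucleosome organisation

`build_vplot()` accumulates fragments into a fragment-size × midpoint-offset
matrix around +1 dyad anchors (sizes 1–250 bp, offsets ±250 bp, 1-bp
resolution, strand-oriented). Mononucleosome-protecting fragments form a
band near 147 bp centred on the dyad. Density normalisation (matrix sums
to 1) is required before `subtract_vplots()`, which floors negative
differences at zero so the result reads as "excess density in A over B".
Comparisons use the flattened per-offset column sums: a paired t-test for
the whole matrix, and a Wilcoxon signed-rank test restricted to the
mononucleosome band, fixed at 147 ± 20 bp since the protected-fragment mode
is ~147 bp and the exact band is a free choice. Identical inputs yield
all-zero differences, reported as p = 1 with a `degenerate` flag.

`call_dyads()` is a deliberately simple dyad caller: Gaussian-kernel
density (`kernel_bw = 20` bp) of mononucleosome-fragment midpoints
(130–180 bp) on a 1-bp grid over the oriented search region (TSS→+250 bp
for the +1 nucleosome, TSS→+1 kb for +1 and +2), local maxima at least
120 bp apart (one nucleosome footprint cannot fit two dyads closer than
that), each needing ≥5 supporting fragments. Although the single-dyad
description is an argmax, local maxima are required for the two-nucleosome
search window — a single argmax cannot return the +2 dyad. Occupancy is the
density at the peak; fuzziness is the population SD of supporting midpoints
within ±75 bp (half a nucleosome footprint) — firm positioning gives low
fuzziness. Externally produced dyad tables (`chrom`, `position`) are
accepted by all downstream functions, so the simplified caller is not a
bottleneck. `spacing_mode()` reports, per TSS, the two nearest downstream
dyad centres (distances >1 kb excluded), and the mode of the
integer-distance histogram per rank with ties broken toward the smaller
distance, plus the modal +1→+2 spacing. `fuzziness_by_delta_ei()` contrasts
the fuzziness of the bottom-n and top-n genes ranked by ΔEI (default
n = 1000, shrunk with a warning when fewer genes qualify) with a rank-sum
test.

## Synthetic data and what the tests do and do not show

Every analysis ships with a seeded generator that emulates the statistical
structure the method assumes, plus a ground-truth table the pipeline never
reads:

* `simulate_chip_reads()` — per-gene log-normal EI (meanlog 0, sdlog 0.5),
  Poisson read counts with expected promoter count 60 and body intensity
  set so the analytic density ratio equals the drawn EI; responders
  multiply body intensity by 2 under treatment. The noiseless mode rounds
  expected counts and re-derives the emitted truth from the realised
  counts, so truth always matches what was placed.
* `simulate_wave()` — fronts at `speed × t` with 2-kb per-gene jitter;
  Poisson emissions (λ_on 15, λ_off 0.3 by default) with length-weighted
  mixing in the straddled bin.
* `simulate_pulse_chase()` — shared per-gene baselines (log-normal around
  200 counts), Poisson intronic counts decaying at per-line rates
  (defaults 0.4/h vs 0.1/h), consistent `gene = intronic + exonic`
  accounting, depth-matched libraries.
* `simulate_atac()` — a three-component fragment mixture (sub-nucleosomal
  35%, mononucleosomal 50%, di-nucleosomal 15%); mono fragments sized
  Normal(147, 10) with midpoints jittered by the planted positional SD
  around +1/+2 dyads at +120 and +310 bp.

Per-gene RNG substreams make paired simulations with common random numbers
possible (changing one gene's condition leaves every other gene's draws
untouched), and every generator is byte-reproducible from its seed — the
pipeline-level determinism check hashes every output file across reruns.

These generators use Poisson counting noise and Gaussian positional noise
only. They contain no mappability or GC bias, no over-dispersion beyond
Poisson (available as future config, off by default), no correlated noise
between conditions, and no sequence-level artefacts. Passing recovery
tests therefore demonstrates that the estimators are correct and
well-calibrated under their stated models — not that real libraries meet
those models. Printed percentages from real datasets are consequently out
of scope here; the pipeline reproduces the computations, with acceptance
on synthetic truth.

## Degenerate inputs and numerical choices

* Quantiles are type-7 (R's default linear interpolation) everywhere,
  stated to avoid silent drift.
* Permutation p-values use the add-one rule and can never be 0.
* All-zero signal sets abort the wave fit ("degenerate input"); all-zero
  paired differences return p = 1 with a flag; constant nonzero paired
  differences return the smallest representable double.
* Emission means are floored at tiny positive values inside EM, but
  `call_fronts()` handles `lambda_off = 0` exactly.
* `run_pipeline()` derives bounded child seeds (< 2^31) per stage from the
  manifest seed, so stages can be re-run in isolation reproducibly.
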