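# comboscreen

Analysis of dose-matrix (checkerboard) drug-combination screens in R.

High-throughput combination screens plate every library compound in a full
factorial dose grid against a fixed *anchor* drug — each axis a serial
dilution series plus a vehicle level, measured in replicate — and ask which
pairs kill cells beyond what the single agents explain. comboscreen covers
that workflow end to end for people running or re-analyzing such screens:

* **Normalization** of raw plate signal to fraction-of-control viability
  `v` and fraction affected `fa = 1 - v`, per block, against the block's own
  vehicle well.
* **Single-agent dose-response**: the median-effect model
  `fa/fu = (D/Dm)^m` (with `fu = 1 - fa`; `Dm` the IC50, `m` the slope),
  fitted by the classical log-linearization with censoring of saturated and
  super-ceiling dose levels, plus a four-parameter logistic fit for QC, and
  IC50-in-combination fold shifts.
* **Per-well synergy surfaces**: excess over the highest single agent
  (`v_combo − min` of the matched singles) and delta Bliss
  (`v_combo − vA·vB`); negative values mean synergy.
* **Per-pair scores**: the Chou–Talalay combination index
  `CI = dA/DxA(fa) + dB/DxB(fa)` with `Dx(fa) = Dm (fa/(1-fa))^(1/m)`,
  collapsed over the matrix by a configurable policy (default: median
  per-well CI over matched-ratio wells in the 25–75% effect band), and a
  maximal-efficacy beta ratio (top-dose combination viability over the best
  single agent's).
* **Two-stage triage**: hits require `CI < 0.5` and `beta < 1` (strict);
  flagged pairs are reported, never dropped; hits aggregate by
  mechanism-of-action class; a 6×6 primary design and a 10×10 confirmatory
  design are built in.
* **An in-silico screen generator** with known ground truth (Hill single
  agents; Bliss-independent, highest-single-agent, and Loewe-style
  potency-shift interactions with strength ψ, which gives a closed-form
  per-well CI of `1/ψ`), so every stage is testable without external data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` heatmaps for surfaces.

## Worked example

Simulate a 50-compound primary screen with 20% planted synergists at 10%
replicate noise, run the triage stage, and compare with the ground truth:

```r
library(comboscreen)

sim <- simulate_library(n_compounds = 50, fraction_synergists = 0.2,
                        noise_cv = 0.1, seed = 42)
res <- run_stage(sim$dataset, screen_config())
res
#> <screen_result> stage = primary: 50 pair(s) scored, 10 hit(s), 9 excluded
#> # A tibble: 10 × 4
#>    drugA_id     ci   beta sum_neg_bliss
#>    <chr>     <dbl>  <dbl>         <dbl>
#>  1 cmpd037  0.0905 0.0583         -5.06
#>  2 cmpd024  0.103  0.0542         -2.93
#>  3 cmpd018  0.151  0.0595         -7.31
#>  4 cmpd007  0.166  0.0698         -6.61
#>  5 cmpd001  0.181  0.0899         -6.06
#>  6 cmpd010  0.187  0.0904         -4.36
#>  7 cmpd049  0.196  0.127          -5.88
#>  8 cmpd036  0.232  0.0706         -7.03
#>  9 cmpd045  0.310  0.182          -3.25
#> 10 cmpd025  0.473  0.208          -3.11
```

Ten pairs pass `CI < 0.5` and `beta < 1`; nine pairs had undefined scores
(saturating singles or no well in the effect band) and are listed in
`res$excluded` rather than silently dropped. The calls match the planted
truth exactly here:

```r
score_against_truth(res, sim$truth)
#> # A tibble: 1 × 6
#>   n_synergists n_nulls_scoreable    tp    fp sensitivity false_positive_rate
#>          <int>             <int> <int> <int>       <dbl>               <dbl>
#> 1           10                31    10     0           1                   0

head(res$class_summary, 4)
#> # A tibble: 4 × 4
#>   moa_class               n_tested n_hits hit_fraction
#>   <chr>                      <int>  <int>        <dbl>
#> 1 HDAC inhibitor                 2      2        1
#> 2 PLK1 inhibitor                 2      2        1
#> 3 topoisomerase inhibitor        1      1        1
#> 4 taxane                         3      1        0.333
```

Single-agent fitting, on the classic three-point series:

```r
fit <- fit_median_effect(c(100, 400, 1600) * 1e-9, c(0.2, 0.5, 0.8))
fit
#> <medfit> Dm = 4e-07 M (400 nM), m = 1.000, n = 3, R^2 = 1.0000 [linearized]
dose_for_effect(fit, 0.8) * 1e9   # dose for 80% effect, in nM
#> [1] 1600
```

`delta_bliss(normalize_block(...))` and `excess_hsa(...)` return per-well
surface tibbles with `autoplot()` heatmaps; `sum_neg()` gives the scalar
synergy summary.

## Command line

A thin CLI wraps the same functions
(`inst/scripts/comboscreen`, or `screen_cli()` from R):

```sh
comboscreen simulate --n 50 --fraction 0.1 --seed 1 --out run/
comboscreen score    --input run/wells.csv --annotations run/compounds.csv --out run/
comboscreen triage   --reports run/reports.csv --annotations run/compounds.csv --out run/
comboscreen report   --input run/wells.csv --out run/
```

Outputs are CSVs with a version/config-hash header; seeded runs are
byte-identical across repeats.

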