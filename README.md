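# tracekin

Quantitative analysis of dye-dilution (CellTrace / CFSE) T-cell
proliferation experiments, with a companion toolkit for the transcriptomic
receptor surveys that typically accompany them.

## Who this is for

Immunologists and cytometry analysts who quantify division from tracking
dyes and want reproducible, scriptable statistics instead of manual peak
gating, plus the standard rule set for surveying receptor expression
(e.g. Fcγ receptors) in bulk and single-cell RNA-seq count matrices.

## What it computes

A tracking dye halves with each division, so generations appear as peaks
spaced `log10(2)` apart on a log10 fluorescence axis. Because a cell that
divided `g − 1` times stands in for only `1/2^(g−1)` of an input cell,
event frequencies `X_g` are converted to precursor (cohort) counts
`n_g = X_g / 2^(g−1)`. The central statistic is the precursor-normalized
percent undivided

    Phi_1 = 100 * X_1 / (X_1 + sum_{i=1..D} X_{i+1} / 2^i)
          = 100 * n_1 / sum_g n_g,

with `D` = observed divisions (peaks − 1), its truncations `Phi_k`
(recomputed after excluding generations `< k`), the percent-division curve
`theta_i = 100 − Phi_i`, and the standard cohort indices (division,
proliferation, expansion).

The package provides, module by module:

* **Synthetic data** — `simulate_cohort()` (quota or multinomial
  generation assignment, log-normal label, 2-fold dilution,
  autofluorescence floor, instrument CV, per-event truth labels),
  `simulate_dose_series()`, and `simulate_counts()` (negative-binomial
  matrices with planted fold changes and paralog families).
* **Flow I/O** — minimal, dialect-strict FCS 3.0/3.1 read and FCS 3.1
  write, CSV event tables, recorded per-channel transforms, rectangular
  gates with closed bounds, and equal-count downsampling.
* **Generation deconvolution** — `fit_generations()`: a constrained 1-D
  Gaussian mixture whose means sit on the dilution lattice; weights become
  generation frequencies; `assign_events()` labels single events;
  `bin_generations()` reports Gen1 / Gen2–5 / Gen6+.
* **Proliferation statistics** — `percent_undivided()`, `phi_series()`,
  `theta_series()`, `proliferation_indices()`, `compare_conditions()`
  (percent change in mean Phi_1, Welch or pooled t-tests per generation
  with Holm–Šidák adjustment, Mann–Whitney on division numbers),
  `anova_conditions()`.
* **Receptor expression** — `group_paralogs()` (FCGR2 = 2A+2B+2C,
  FCGR3 = 3A+3B by default), median-of-ratios `size_factors()`,
  `normalized_per_kb()`, `tpm()`, threshold-based `expression_calls()`
  (1 / 0.5 / 0.25 TPM, basal flag at 1.2), `deg_classify()` (DEG iff
  adjusted p < 0.05 and FC ≥ 1.5 either direction; trend calls at
  p < 0.10), and per-cell `sc_cpm()`.
* **Enrichment** — `signal2noise()` ranking, weighted running-sum
  `enrichment_score()`, gene-set `permutation_fdr()` (NES, nominal p,
  signed null-pool FDR q, enriched at q < 0.25), hypergeometric
  `overlap_test()` over an explicit universe, GMT read/write.

## Worked example

```r
library(tracekin)

lab <- labeling_model(log10_initial_sd = 0.06, instrument_cv_log10 = 0,
                      autofluorescence_floor = -Inf)
truth  <- division_profile(c(0.40, 0.25, 0.20, 0.10, 0.05))  # 40% undivided
events <- simulate_cohort(truth, 10000, lab, seed = 42)
fit    <- fit_generations(events)
fit
#> <generation_frequencies> D = 4 divisions
#>  Gen1  Gen2  Gen3  Gen4  Gen5
#> 12.11 15.18 24.19 24.25 24.27
#> means: 4.499 4.199 3.898 3.598 3.297  shared sd: 0.0606

percent_undivided(fit)
#> [1] 39.96983
```

The fitted event frequencies (12.1% of *events* undivided) convert to
precursor terms: `Phi_1 = 40.0%` of *input cells* never divided,
recovering the simulated truth. Comparing three inhibited wells (55%
undivided precursors) against three controls:

```r
treated <- lapply(1:3, function(i) proliferation_summary(
  fit_generations(simulate_cohort(
    division_profile(c(0.55, 0.20, 0.12, 0.08, 0.05)), 10000, lab,
    seed = 100 + i))$X, sample_id = paste0("IC_", i)))
control <- lapply(1:3, function(i) proliferation_summary(
  fit_generations(simulate_cohort(truth, 10000, lab,
    seed = 200 + i))$X, sample_id = paste0("ctrl_", i)))
compare_conditions(treated, control)
#> <comparison_result> +37.7% change in percent undivided (Phi_1 55.1 vs 40.0)
#> median divisions 4.0 vs 4.0 (Mann-Whitney p = NA)
#>   generation theta_treated theta_control theta_diff    p_raw    p_adj flag
#> 1          1          44.9          60.0     -15.07 1.23e-10 4.91e-10
#> 2          2          55.6          58.3      -2.70 1.57e-07 2.68e-07
#> 3          3          51.9          42.8       9.10 6.05e-10 1.82e-09
#> 4          4          38.5          33.4       5.13 1.34e-07 2.68e-07
#> 5          5           0.0           0.0       0.00       NA       NA degenerate_variance
```

The headline effect (+37.7%) is the percent increase in mean percent
undivided; per-generation percent-division differences carry Holm–Šidák
adjusted p-values; the final generation is flagged rather than tested
(theta of the last generation is 0 by construction).

## Command line

A thin CLI wraps the main operations:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tracekin.R", package = "tracekin"))')
Rscript $CLI simulate --profile 0.5,0.3,0.2 --n 10000 --seed 7 --out events.fcs
Rscript $CLI deconvolve --in events.fcs --channel CellTrace --out freqs.csv
Rscript $CLI prolif --in freqs.csv
```

Run `Rscript $CLI` with no arguments for all commands.

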