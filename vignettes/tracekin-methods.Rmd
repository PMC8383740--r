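---
title: "Methods: dye-dilution proliferation statistics and receptor surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dye-dilution proliferation statistics and receptor surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracekin)
```

## The measurement problem

Amine-reactive tracking dyes (CellTrace, CFSE) covalently label cellular
proteins; daughter cells inherit roughly half of the labelled protein at
each division, so on a log10 fluorescence axis the generations of a
T-cell culture appear as a ladder of peaks spaced `log10(2) ≈ 0.301`
apart. Two questions follow from such a histogram:

1. What fraction of the *original input cells* never divided, and how does
   an immunomodulatory treatment change it?
2. How are the divided cells distributed over generations?

Raw event frequencies answer neither directly, because a precursor that
divided `g − 1` times is represented by `2^(g−1)` descendants. All
statistics in this package therefore work on *precursor (cohort) counts*

$$n_g = X_g / f^{\,g-1},$$

where $X_g$ is the measured event frequency of generation $g$ and $f$ the
dilution factor (2 unless stated otherwise).

## Percent undivided and percent division

`percent_undivided()` computes

$$\Phi_1 = 100 \cdot \frac{X_1}{X_1 + \sum_{i=1}^{D} X_{i+1}/f^{\,i}}
        = 100 \cdot \frac{n_1}{\sum_g n_g},$$

with $D$ the number of observed divisions (peaks minus one). The second
form makes the statistic's meaning transparent — the share of input cells
still in the undivided peak — and is the basis of the package's exactness
test: on a cohort simulated with known per-generation precursor counts the
two sides agree to floating-point precision, because
$X_g = n_g f^{\,g-1}$ identically under quota assignment.

`phi_series()` generalizes to $\Phi_k$ by truncating the frequency vector
at generation $k$ and re-applying the same formula (the analysis
"excluding generations $1..k-1$"); `theta_series()` returns
$\theta_i = 100 - \Phi_i$, whose curve against $i$ is the mathematical
form of a FACS proliferation curve. The orientation question — whether
$\theta_i$ is plotted from $i = 1$ or from the first dividing
generation — is left to the caller: the full vector is returned and either
axis convention is a trivial re-indexing.

Cohort indices use the standard definitions: division index
$\sum (g-1) n_g / \sum n_g$ (mean divisions per input cell),
proliferation index $\sum (g-1) n_g / \sum_{g \ge 2} n_g$ (mean divisions
per *dividing* input cell), expansion index $\sum X_g / \sum n_g$ (fold
expansion). These are documented as the package's own choice of the
conventional cohort formulas; proprietary plugin implementations are not
reverse-engineered.

## Generation deconvolution

`fit_generations()` replaces manual peak gating with a constrained
one-dimensional Gaussian mixture on the log10 axis:

* component means lie on a lattice $\mu_g = \mu_1 - (g-1)\Delta$ with
  $\Delta$ initialized at $\log_{10} f$ and, by default, refined within
  ±10% (labels do not always dilute exactly two-fold in practice);
* a single shared standard deviation (label CV is division-independent to
  first order; a per-component option would add parameters the typical
  histogram cannot support);
* mixture weights × 100 are the generation frequencies $X_i$.

Numerical choices worth knowing:

* **Anchoring.** The lattice is anchored on the *strongest* kernel-density
  mode — the most reliably detected landmark — and then extended upward so
  that the brightest events are covered. In heavily divided cultures the
  undivided peak can hold well under 1% of events (10% undivided
  precursors behind seven dividing generations is ≈ 0.1% of events) and
  is invisible to any mode detector, but its events still sit an integer
  number of dilution steps above the anchor. Leading lattice positions
  that collect negligible weight (< 0.05%, far below any real generation
  in the intended regime) are dropped after fitting; trailing components
  below `min_weight` (0.5%) are dropped and `D` reduced, so `D` is always
  derived from the data.
* **Binned EM.** Above 5000 events the sample is collapsed into a
  2048-bin weighted histogram before EM. The bin width is far below the
  component sd in any realistic fit, the weighted EM is exact for the
  binned data, and fitting cost becomes independent of sample size.
* **Noiseless data.** When the channel takes at most `max_generations`
  distinct values the events are counted directly on the lattice; the
  zero-noise limit is exact by construction rather than by EM luck.
* **Degenerate variance.** The shared sd is floored at `1e-4` log10 units
  so the E-step stays defined for near-discrete data.
* **Ties.** Maximum-posterior event labels break exact ties toward the
  lower (brighter, less divided) generation.
* **Floor pile-up.** Events below the last lattice mean are absorbed by
  the last component, mirroring how high-generation peaks merge into the
  autofluorescence floor.

Reporting bins follow the field's convention: `Gen1` (undivided),
`Gen2_5`, and `Gen6plus` (at least five divisions).

## Condition comparisons

`compare_conditions()` reports the percent change in mean $\Phi_1$
(treated vs control) as the headline effect, per-generation $\theta_i$
differences tested with unpaired two-tailed t-tests — Welch by default,
since equal variances should not be assumed across wells; pooled variance
as the single-well-assay option — and adjusts with the Holm–Šidák
step-down: sort raw p ascending, $\tilde p_{(k)} = \max_{j \le k}
\left[1 - (1-p_{(j)})^{m-j+1}\right]$, clipped at 1. Per-sample division
numbers $D$ are compared by Mann–Whitney U; a one-way ANOVA wrapper
covers multi-condition aggregates. Zero-variance generations are flagged
(`NA` p) rather than given a fabricated p-value.

## The synthetic world

`simulate_cohort()` states the world the tests live in:

* each precursor is assigned a final generation by deterministic quota
  (largest-remainder rounding of $p_g n$) so that closed-form checks are
  exact; a multinomial option exists for stochastic realism;
* division is synchronous and complete — a generation-$g$ precursor
  yields exactly $2^{g-1}$ events; no death model (viability in the
  motivating experiments exceeded 80% and dead cells are outside the
  statistic);
* measured fluorescence is
  $\mu_1 - (g-1)\log_{10} f + \varepsilon$, with
  $\varepsilon \sim N\!\left(0,\; \sigma_0^2 + (g-1)\sigma_i^2 +
  \sigma_{cv}^2\right)$ — initial labelling spread, per-division
  inheritance jitter accumulating as $\sqrt{g-1}$, and instrument CV in
  quadrature, drawn once per event;
* autofluorescence is a hard floor (censoring), not additive background:
  it reproduces the visual pile-up of dim peaks and keeps the noiseless
  limit exact.

Defaults $\sigma_0 = 0.08$, $\sigma_{cv} = 0.04$ log10 units are
calibration choices — no quantitative noise model for CellTrace peaks is
published — selected so that adjacent peaks are distinct but visibly
overlapping, as in real histograms. The recovery fixtures used by the
acceptance properties draw the undivided precursor fraction from
U(0.1, 0.5) — bracketing the ≈ 20% undivided seen in control cultures and
the ≈ 60% seen under immune-complex inhibition — with the remaining mass
Dirichlet(2)-distributed over up to seven dividing generations.

What a green test does *not* establish: robustness to asynchronous or
incomplete division, cell death correlated with generation, non-Gaussian
instrument noise, spectral spillover, or dyes whose dilution drifts from
two-fold. The simulator deliberately excludes all of these (they are
listed non-goals), so recovery results speak to the estimator's
correctness under its stated model, not to every real-world histogram.

`simulate_counts()` plants ground truth for the transcriptomic rules:
negative-binomial counts (dispersion $\alpha$, variance
$\mu + \alpha\mu^2$) with per-gene baselines $10^{U(0.5, 3)}$, per-sample
library factors, a planted fold change (random direction) in a chosen
fraction of genes, and optional paralog-family members appended as null
genes with independent baselines. Gene lengths are drawn log-uniformly
between 300 bp and 10 kb.

## Receptor-survey rules

The transcriptomic module reimplements, over explicit inputs, the survey
rules used in the motivating study:

* **Paralog grouping** — FCGR2A/B/C (and FCGR3A/B) transcripts are nearly
  indistinguishable at the read level; `group_paralogs()` sums member
  counts (each read counted once) and member lengths, then removes the
  member rows. Grouping commutes with TPM and with per-kb normalization,
  and that commutation is tested.
* **Size factors** — the median-of-ratios estimator (per-gene geometric
  mean reference), normalized to geometric mean 1; a `poscounts`-style
  fallback covers matrices with no all-nonzero gene.
* **Expression units** — `tpm()` (rate normalization; every column sums
  to $10^6$), `normalized_per_kb()` (size-factor-normalized counts per
  kilobase), `sc_cpm()` (per-cell counts per million for grouped genes,
  zero-total cells dropped).
* **Threshold calls** — per-subset mean TPM classified at inclusive
  thresholds 1.0 (expressed), 0.5 (very low), 0.25 (still ranked), with a
  per-gene basal flag at 1.2; "inclusive" is applied uniformly because
  the source rules are phrased as "at least". The subset mapping is an
  explicit argument, so averaging within replicates or across donors are
  both expressible.
* **DEG classes** — DEG iff adjusted p < 0.05 *and* linear fold change
  ≥ 1.5 in either direction; otherwise a trend call when the adjusted or
  nominal p < 0.10; otherwise `ns`.

The built-in differential test is a *convenience*, not a DESeq2 clone:
median-of-ratios normalization, pooled within-group method-of-moments
dispersion floored at the genome-wide median (a deliberately conservative
moderation — per-gene moment estimates at n = 4 are far too noisy to use
raw), and a per-gene negative-binomial likelihood-ratio (deviance) test
with the dispersion held fixed. A delta-method Wald variant was evaluated
and rejected: it is anti-conservative with raw moment dispersions and
underpowered once the dispersions are floored hard enough to fix that,
whereas the deviance test controls the empirical FDR well below nominal
on the planted benchmark while keeping sensitivity above 0.85. At n ≤ 3
per group the moment dispersions degrade further; the supported path for
publication-grade inference remains ingesting externally computed
per-gene statistics into `deg_classify()`.

## Enrichment

`signal2noise()` ranks genes by $(\mu_A - \mu_B)/(\sigma_A + \sigma_B)$
with each sd floored at $\max(0.2\,|\mu|,\; 0.2)$ — the reference
implementation's convention, adopted because the source protocol says
only "default settings". `enrichment_score()` is the weighted
running-sum statistic (hits add $|s|^p / \sum_{set}|s|^p$, misses
subtract $1/(N - n)$; ES is the signed maximum deviation); it is verified
against literal position-by-position enumeration. One degenerate case is
worth noting: a gene set equal to the whole list has no misses, so the
running sum climbs monotonically to 1 and ES = 1.

`permutation_fdr()` implements gene-set permutation (the mode matching
"1000 gene set permutations"): null ES from random same-size sets,
NES = ES / mean(|null ES| of the same sign), nominal p within the
same-sign null, and FDR q as the signed null-pool ratio, clipped to
[0, 1]. Null ES for a random set is computed from hit positions only
(O(set size) per permutation), which keeps 1000 permutations over
thousands of genes interactive. Phenotype permutation is intentionally
not implemented — it requires the sample-level matrix and a different
null, and gene-set mode is the documented default here. Size filters
default to 15–500. Enrichment is declared at q < 0.25, the conventional
threshold for this statistic.

`overlap_test()` is the upper-tail hypergeometric test of a gene list
against each set over an *explicit universe* — the universe a web
overlap tool uses is rarely stated, so it is a required argument here —
with BH adjustment and a configurable significance cutoff defaulting to
q < 0.005.

## Flow I/O

FCS support is deliberately dialect-narrow: list-mode, single-dataset
files, datatypes F/D/I, both byte orders on read; FCS 3.1 float32
little-endian on write. Everything else fails loudly naming the keyword.
This buys bit-exact round-trips (write∘read∘write is byte-identical),
which matter more for a testable pipeline than coverage of historical
dialects. Gates are closed rectangles (boundary events kept, matching
common gating-software behaviour); log10 transforms floor non-positive
values at one tenth of the smallest positive measurement and record their
state per channel so a transform is never silently applied twice;
`downsample_equal()` samples without replacement to a common event count,
as done before pooled embeddings.

## Known limitations

* The deconvolution assumes well-separated, lattice-spaced Gaussian
  peaks; dyes with strongly generation-dependent CV or heavy floor
  pile-up across several generations will bias the last retained
  generations.
* The built-in DEG test is approximate by design at very small n.
* Under `assignment = "multinomial"` the expected-event identity holds
  only in distribution (tested within 3 Monte-Carlo SDs), not exactly.
* Curated gene-set collections are user-supplied GMT files; none ship
  with the package.

## A worked round trip

```{r example}
lab <- labeling_model(log10_initial_sd = 0.06, instrument_cv_log10 = 0,
                      autofluorescence_floor = -Inf)
truth <- division_profile(c(0.40, 0.25, 0.20, 0.10, 0.05))
events <- simulate_cohort(truth, 10000, lab, seed = 42)
fit <- fit_generations(events)
fit
percent_undivided(fit)      # recovers 100 * 0.40
proliferation_indices(fit$X)
```
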