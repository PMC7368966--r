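---
title: "Waveband optimization for NIR calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waveband optimization for NIR calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The calibration problem

Near-infrared (NIR) spectroscopy predicts an analyte concentration (here
modeled after protein content in animal-feed meal, in wt.%) from a
reflectance spectrum measured on hundreds of wavelength channels. Most
channels carry overlapping matrix absorption and noise rather than
analyte-specific signal, so the central chemometric task is variable
selection: find the contiguous waveband(s) whose channels support the best
regression, then refine the representation inside those bands.

`nirwaveband` implements a three-stage optimization around a partial least
squares (PLS) core:

1. **Grid-search moving window (GSMW).** A window is a contiguous waveband
   parameterized by width `N` (number of channels) and 1-based start index
   `S`, admissible when `S + N - 1 <= P` for `P` channels. Every window of
   a width grid is scored by fitting a PLS model on the calibration part
   and computing the root mean square error on the held-out validation
   part (RMSEV); the wavebands with the lowest RMSEV win. On the
   full-scale axis (`P = 700`) with the default width grid
   (`1:1:100, 110:10:300, 320:20:700`) the admissible set has exactly
   78,790 windows.
2. **Latent principal components (LPC).** Each selected waveband's channels
   are transformed to principal components of the calibration rows, sorted
   by descending explained variance. With more calibration samples than
   channels, all `N` components are retained (no truncation by default);
   validation and testing spectra are always projected with the
   calibration-fitted basis, never refit.
3. **Genetic algorithm (GA) over LPC subsets.** A binary chromosome flags
   which components enter a least-squares regression with intercept; the
   fitness of a chromosome is the validation RMSEV of that regression. The
   GA scans a small grid of crossover and mutation probabilities
   ("parametric scaling") and returns the cell and subset with minimum
   RMSEV. The waveband whose post-GA RMSEV is lowest becomes the final
   model, evaluated once on a testing set never used during selection.

## Data model and conventions

* The wavelength axis is `(start_nm, step_nm, count)`; channel `S` sits at
  `start_nm + (S - 1) * step_nm` and wavebands are closed intervals, so
  1446–1520 nm at 2 nm spacing holds 38 variables. The default axis is
  1100 nm start, 2 nm step, 700 channels (last channel 2498 nm). An axis
  is never reconstructed from a printed end wavelength; the channel count
  is authoritative.
* Spectra are preprocessed by standard normal variate (SNV): each spectrum
  is centered and scaled to unit sample SD (denominator `n - 1`). This
  removes multiplicative scatter differences between samples and is the
  first pipeline stage, before any splitting or model fitting.
* Samples are split testing-first: a uniformly random holdout (so the
  testing set cannot be influenced by any model decision), then SPXY
  selection of the calibration part from the remaining modeling samples.
  SPXY is Kennard–Stone on the joint distance
  `d(i,j) = d_x(i,j)/max d_x + d_y(i,j)/max d_y` with Euclidean `d_x` on
  the SNV-preprocessed spectra and `d_y = |y_i - y_j|`; normalizers are
  taken over the pool being split, and ties break to the lowest sample
  index. The default split is 90 calibration / 50 validation / 54 testing
  for a 194-sample dataset.
* Evaluation metrics: RMSE with denominator `n` (the NIR reporting
  convention, not `n - 1`) and the Pearson correlation `R`. Degenerate
  variance yields an explicit `r_defined = FALSE` flag rather than NaN.

## PLS details

PLS1 is computed by NIPALS with deflation of `X` only; for a univariate
response the weight vector per component is closed-form, so the
decomposition is exact and deterministic. Predictors and response are
mean-centered; column autoscaling is off by default because SNV has already
normalized each spectrum (it is available as an option). The window scan
extracts up to `min(lv_cap, N, n_cal - 1)` latent variables in a single
NIPALS pass and accumulates validation predictions component by component,
so the RMSEV of every latent-variable count comes from one decomposition;
the count minimizing RMSEV is reported per window. The default cap of 15
latent variables is a conventional chemometric ceiling that also bounds the
cost of the exhaustive window scan.

Correctness is cross-checked in the test suite against an independent
route: PLS1 predictions equal least squares on the orthogonalized Krylov
basis `span{X'y, (X'X)X'y, ...}`, and full-rank PLS equals the ordinary
least-squares solution.

## GA details

* Chromosomes are 0/1 vectors over the LPC candidates; evaluated
  chromosomes always have at least one flag set (all-zero offspring are
  repaired by setting one random bit; the all-zero fitness sentinel is
  `Inf`).
* Population size defaults to `max(20, 2 * chromosome length)`, rounded up
  to even — it scales with the input dimension and is bounded below for
  narrow wavebands.
* Selection is tournament of size 2 on RMSEV (rank-based and scale-free);
  crossover is single-point, applied per parent pair with probability
  `p_crossover`; mutation flips each bit with probability `p_mutation`.
  Probabilities are configured in percent (defaults 50% and 1.2%, the
  conventional settings; the parametric scan tries crossover 40/50/60% and
  mutation 0.8/1.2/1.5%).
* Elitism carries the best individual unchanged, so the best-so-far RMSEV
  trace is non-increasing — asserted on every run.
* One offspring is kept per tournament pair, and a child identical to an
  individual already placed in the new generation is regenerated (at most
  10 retries). Without this standard diversity safeguard, small
  populations fill with copies of the elite and stop exploring well before
  the stall rule closes; with it, the GA reliably attains the
  exhaustive-enumeration optimum on instances small enough to enumerate
  (checked in the acceptance tests over 20 seeds).
* Two stopping rules: a hard cap (default 500 iterations) and an adaptive
  stall stop when the best RMSEV changes by at most `1e-6` wt.% for 20
  consecutive iterations. A constant-fitness run therefore stops at
  iteration `stall_window + 1`; setting a negative stall tolerance
  disables the adaptive stop. All randomness flows from the configured
  seed; the parametric scan derives per-cell seeds (`seed + 1000 * cell`)
  and the pipeline derives per-waveband seeds (`seed + 10000 * rank`), so
  every run is bit-reproducible.
* GA fitness uses the held-out validation set, consistent with the window
  search; because LPC scores are orthogonal on the calibration set, the
  least-squares fitness regression is stable and coincides with full-rank
  PLS on the same columns.

## Top-window selection

The wavebands carried into the GA stage are chosen greedily by ascending
RMSEV, skipping any window whose channel range overlaps an
already-selected window; ties break to smaller `N`, then smaller `S`. The
non-overlap constraint makes the selected set a disjoint coverage of
distinct spectral regions rather than five near-copies of the single best
window, which is how published selections of this kind are structured.
Whether a global top-k or a per-region choice is "correct" is not
determined by the method itself; greedy-disjoint is the documented,
reproducible choice here.

## What the synthetic generator emulates — and what it does not

Since real reference datasets of this kind are rarely deposited, the
package ships a generator with known ground truth. Each spectrum is a
Beer–Lambert-style superposition: component concentrations times Gaussian
absorption bands, plus a fixed matrix background, a per-sample linear
baseline, and additive white noise:

* **Concentrations.** The analyte targets mean 60.7 and SD 4.36 wt.%,
  truncated to [53, 67]. No normal distribution truncated to that interval
  can reach an SD of 4.36 (the supremum is the uniform limit,
  `14/sqrt(12) ≈ 4.04`), so the generator solves for the parent normal
  whose truncated moments come closest — the mean is matched exactly and
  the SD reaches ≈3.99 — and samples by inverse CDF. Interferent
  concentrations are jointly normal with the analyte at a configurable
  correlation (default 0.3), emulating co-varying matrix constituents such
  as moisture or ash.
* **Bands.** The default analyte band is centered at 2015 nm with
  sigma 15 nm, so its informative region spans roughly 1980–2050 nm; two
  interferent bands sit at 1450 and 2180 nm. The signal-to-noise ratio is
  defined as (analyte peak amplitude × concentration SD) / noise SD and is
  10 at the defaults.
* **Matrix background.** A fixed set of broad absorption bands
  (`nir_matrix_background()`) common to every sample. This is essential,
  not cosmetic: SNV divides each spectrum by its own SD, and if the
  analyte band dominates that SD the division removes the concentration
  signal exactly (`(c·g - c·ḡ)/(c·sd(g))` is concentration-free). Real
  diffuse-reflectance spectra are dominated by composition-independent
  matrix absorption, which is precisely the regime in which SNV is
  information-preserving; the background reproduces that regime.
* **Not modeled:** instrument line shape, wavelength-dependent noise,
  nonlinear detector response, scattering physics beyond the per-sample
  offset/slope baseline, and band shapes other than Gaussian. Passing the
  recovery tests therefore shows the pipeline recovers planted structure
  under realistic additive conditions — it does not certify performance on
  any particular instrument's data.

Three standard fixtures cover the test pyramid: `planted_band` (194 × 700,
full realism, SNR ≈ 10), `tiny` (30 × 20, small enough for brute-force
oracles over all 210 windows and all 1023 LPC subsets), and `rank1`
(noise-free, single component; PLS must fit it exactly with one latent
variable).

## Problem sizes used by the tests and acceptance script

The full 78,790-window grid is enumerated exactly (it is a pure counting
operation). Model-fitting scans run on the planted-band fixture with a
reduced width grid, `N ∈ {10, 20, ..., 60}` (3,996 windows on the 700
channel axis): the planted band is 30–70 channels wide, so this grid
brackets it while keeping a ten-seed recovery study inside a few minutes of
CPU. Recovery is asserted as: the top-1 window overlaps 1980–2050 nm in at
least 9 of 10 seeds, and the GA does not worsen the selected waveband's
RMSEV in the majority of seeds. Determinism is asserted by byte-comparing
the complete artifact directories of two identical runs.

## Numerical choices

* LPC basis: SVD of the mean-centered calibration window; components kept
  while the singular value exceeds `1e-10` of the largest; loading signs
  fixed so each column's largest-magnitude entry is positive.
* NIPALS stops early if the residual covariance norm falls below `1e-12`
  (rank exhaustion); the window evaluator then falls back to the
  intercept-only prediction for degenerate windows.
* Ties: window ranking breaks RMSEV ties by smaller `N` then smaller `S`;
  SPXY breaks max–min ties by lowest index; the parametric scan takes the
  first minimal cell in row-major order.
* RMSE uses denominator `n`; SNV and SPXY use sample SD / Euclidean
  distance as stated above. These conventions are fixed so results are
  bit-reproducible across machines.

## Known limitations

* The exhaustive window scan is O(windows × LV cap × n × N); the full
  default grid at `P = 700` is practical but slow in pure R — use a
  reduced width grid for exploratory runs, as the examples do.
* The full-spectrum GA-PLS baseline with the default population rule
  (`2P` individuals at `P = 700`) is expensive; bound it with
  `ga_population_size` when comparing against the pipeline.
* GA results, like all stochastic searches, are seed-dependent; the
  parametric scan reports the full per-cell grid so the spread is visible.
* Single-response calibration only (PLS1); no multi-analyte support.
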