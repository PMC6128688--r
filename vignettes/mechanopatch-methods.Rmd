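---
title: "Models and methods behind mechanopatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mechanopatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanopatch)
```

mechanopatch analyzes mechanosensitive (MS) channel recordings — whole-cell
currents evoked by membrane indentation ("poking") and single-channel currents
evoked by patch pressure — and ships a stochastic gating simulator that
generates such recordings with known ground truth. This vignette describes the
models, the estimators, and the numerical choices, in that order. Everything
quantitative stated here is computed by the package's test suite or its
acceptance script; nothing is quoted from elsewhere.

## The gating model

Channels follow a continuous-time Markov scheme, by default the linear
three-state chain

$$\mathrm{C} \underset{k_{OC}}{\overset{k_{CO}(s)}{\rightleftharpoons}}
  \mathrm{O} \underset{k_{IO}}{\overset{k_{OI}}{\rightleftharpoons}}
  \mathrm{I},$$

with rates in 1/ms. Only the opening rate is coupled to the mechanical
stimulus $s$ (one coupled rate keeps the presets identifiable — no published
activation-curve data constrain anything richer), through a
threshold-adjusted Boltzmann

$$k_{CO}(s) = k_{CO}^{\max}\,
  \frac{b(s) - b(0)}{1 - b(0)}, \qquad
  b(s) = \frac{1}{1 + e^{(s_{1/2} - s)/k_s}},$$

clipped at zero. The subtraction makes an unstimulated membrane exactly
silent, which is how resting patches behave on the timescale of a sweep, at
the cost of an activation threshold that a raw Boltzmann does not have. The
stimulus coordinate is abstract: poke depth (µm) and patch pressure (mmHg)
both map onto it directly, and no attempt is made to model indentation
mechanics — "depth" is a stimulus dial, not a force.

Two presets parameterize the scheme (`buildPreset()`), differing only in the
inactivation rates:

| preset | $k_{CO}^{\max}$ | $k_{OC}$ | $k_{OI}$ | $k_{IO}$ | behaviour |
|---|---|---|---|---|---|
| `canonical_fast` | 1 | 0.25 | 0.1 | 0.0005 | decay constant ≈ 13 ms; slow fraction ≈ 0.01 |
| `mes_slow` | 1 | 0.25 | 0.0074 | 0.002 | measured slow fraction ≈ 0.67 |

Both use a unitary conductance of 24.7 pS and a 0 mV reversal potential. The
Boltzmann midpoint is 3 µm (slope 0.4 µm) for poke protocols and 30 mmHg
(slope 4 mmHg) for pressure protocols; these are free choices of stimulus
scale, documented here rather than claimed as channel properties. The
`canonical_fast` rates were set so the slow relaxation eigenvalue of the
generator at saturation stays under 20 ms, the fast-inactivation regime of
canonical mechanosensitive channels. The `mes_slow` O→I rate was calibrated
in two passes: the master-equation oracle put the analytic 75-ms open
probability ratio at 0.67 for $k_{OI} \approx 0.0078$; because the measured
statistic sits a percent or two lower (the peak estimator rides noise and
occupancy-fluctuation maxima), $k_{OI}$ was then fixed at 0.0074 by a
calibration batch of 100 simulated cells on seeds disjoint from every seed
used in the tests. The calibration was run once and frozen.

## Simulation

`openProbabilityTimecourse()` solves the master equation by matrix
exponentials on piecewise-constant stimulus segments (pressure ramps at the
8.3 mmHg/ms clamp slew rate are discretized at the sampling interval). It is
the deterministic oracle against which the stochastic simulator is tested.

`simulateOccupancy()` runs an exact event-driven (Gillespie) simulation on
aggregated state counts: with three states and hundreds of channels the
propensity of each transition is `count × rate`, so cost scales with the
number of transition events, not channels × samples. Within each
constant-stimulus segment the simulation is exact. Each call consumes one
named seed, recorded in the sweep metadata; identical inputs and seed give
bit-identical traces, and the caller's RNG state is never disturbed.

`renderCurrent()` converts open counts to current,
$I(t) = N_O(t)\,\gamma(V - E_{rev})$ in pA (inward negative), adds Gaussian
recording noise *before* filtering, and applies a digital 4-pole Bessel-type
low-pass — the filter topology of patch-clamp amplifiers — built by bilinear
transform of the tabulated −3 dB-normalized Bessel prototype with cutoff
prewarping. The design contract is the −3 dB point (it lands within a
fraction of a percent of the 1 kHz default at a 20 kHz sampling rate), not
any specific design method. Defaults follow a standard acquisition chain:
1 kHz filter, 20 kHz digitization.

## Whole-cell metrics

All metrics are magnitudes over a pre-stimulus baseline (`estimateBaseline()`,
mean over a window that must end at or before stimulus onset):

* **peak** — maximum $|I - \text{baseline}|$ inside the stimulus window. The
  first 2 ms after onset are blanked (configurable) to skip the capacitive
  edge transient; the blanking width is a convention, as published records
  show but do not quantify the transient.
* **slow current** — $|I - \text{baseline}|$ read 75 ms after stimulus onset.
  Whether the 75-ms readout should be a point sample or a window average is
  genuinely open; the package averages over a 5-ms symmetric window for noise
  robustness and documents the choice. On a complete mono-exponential decay
  the windowed readout differs from the point value by under 0.3% for
  τ ≥ 12 ms.
* **slow fraction** — slow/peak. Values above 1 (current still growing) are
  reported and flagged, never clipped. **fast component** — peak − slow,
  flagged when negative.
* **inactivation fits** (`fitInactivation()`) — mono- or bi-exponential
  least squares from the time of peak to stimulus end, with positivity and
  generous τ bounds. MS current decays are often irregular, so every fit
  carries a quality flag (R² threshold, bound collisions) and flagged fits
  should not be reported as kinetics.

Stage summaries pool cells across independent differentiations without batch
terms and report mean ± SEM; whether published error bars of this kind are
SEM or SD is often unstated, so the summary keeps both derivable (n is
always attached). Group comparisons of slow fractions use the two-tailed
Welch test.

## Single-channel analysis

`buildHistogram()` bins a segment's samples but retains the raw values, so
level fitting is independent of bin width. `fitLevels()` fits a Gaussian
mixture with a common component variance (every level sees the same
recording noise) **plus one uniform component**: a 1 kHz filter smears each
gating transition across ~0.3 ms, and at realistic event rates a double-digit
percentage of samples lie between levels. Without the uniform component those
samples drag level means together and corrupt the order selection; with it,
level means recover the generating unitary current to within a few
hundredths of a pA. Model order (1…`maxLevels` Gaussian levels) is chosen by
BIC — an explicit criterion where a human would eyeball histogram peaks — and
the EM runs from two deterministic starts (kernel-density peaks, quantiles),
keeping the better likelihood. Level 0 (closed) is the extreme level with
the larger weight, which holds whenever the analyzed segment includes shut
periods; segments should therefore span the full sweep, not just the
stimulus.

`unitaryCurrent()` averages adjacent-level spacings weighted by the combined
occupancy of each pair — robust in multi-channel patches where several open
levels are populated. `conductanceFit()` regresses unitary current on
holding potential by OLS ($i = \gamma(V - E_{rev})$); command voltages carry
negligible error, so errors-in-variables machinery is unwarranted, and
$E_{rev}$ stays a free parameter so asymmetric solutions remain
representable. `ensembleAverage()` reconstructs the apparent macroscopic
current from repeated single-channel sweeps; `idealizeSweep()` assigns
samples to levels with a 0.25-spacing hysteresis. No dwell-time fitting or
missed-event correction is attempted.

## Selectivity biophysics

`nernstPotential()`, `ghkVoltage()` (monovalent constant-field),
`biIonicMonovalent()` and the Fatt–Ginsborg `biIonicDivalent()` implement the
standard relations; `estimateErev()` interpolates the zero-current crossing
linearly between the bracketing I–V points. `permeabilitySequence()` orders
permeability ratios and groups ties within a 10% default tolerance.

`hendersonLJP()` evaluates the Henderson equation with a bundled
limiting-mobility table (`defaultMobilityTable()`): classical
infinite-dilution equivalent conductivities for K⁺ (73.5), Na⁺ (50.1), Cl⁻
(76.3) and Ca²⁺ (59.5 per equivalent), with gluconate⁻ (24.4) and NMDG⁺
(28.0) taken from the junction-potential literature for large organic ions.
Activity coefficients are ignored (concentrations as activities) and
electro-neutral buffer components are excluded unless given an explicit
valence. The sign convention — bath minus pipette, corrected
$E_{rev} = E_{measured} - LJP$ — reproduces the signs of the standard
estimates for these solutions. Temperature defaults to 298.15 K. One
sensitivity worth knowing: at 25 °C the KCl/CaCl₂ junction computes to
8.7 mV; the same junction at a typical room temperature of 20–22 °C computes
to 8.6 mV, and junction potentials in the literature for these solutions are
often quoted slightly lower, consistent with room-temperature evaluation.
The package keeps 298.15 K as the default and leaves temperature
configurable rather than tuning the mobility table.

## Cohort statistics

Growth series are normalized per line to the line's own day-0 count by
default. A per-genotype day-1 anchor is available because both conventions
appear in practice and they answer slightly different questions; the anchor
is therefore an explicit option (`normalizeGrowth(anchor=)`), never silent.
Growth constants come from nonlinear least squares on
$N(t) = N_0 e^{kt}$ in natural scale — this weights late, large counts the
way published growth-curve R² values behave — with log-linear regression as
an option. `welchOneTailed()` is the unequal-variance two-sample t-test with
Welch–Satterthwaite degrees of freedom; the tail direction is a **required**
argument, because a silently defaulted one-tailed direction is the easiest
way to misreport such a test. Zero-variance degenerate inputs return p = 0.5
by convention, flagged. Dead-cell subtraction is assumed done upstream:
counts enter as live cells.

## What the simulator does and does not emulate

The generator reproduces: stimulus-coupled activation, single- or
multi-exponential-like inactivation, unitary currents of γ(V−E) scale with
up to a handful of channels per patch, occupancy fluctuation noise,
Gaussian instrument noise, and the 1 kHz/20 kHz acquisition chain. It does
not reproduce: cell-to-cell heterogeneity of expression (every simulated
cell has the same channel count), capacitive transients, seal drift, rundown,
series-resistance error, or any mechanical model of the indentation — so
passing recovery tests show the *estimators* are unbiased at realistic SNR,
not that real cells obey the three-state scheme. The simulated cohort used
in the tests (500 channels, −80 mV, saturating 150-ms step, 30 cells) has a
between-cell slow-fraction SD of about 0.03, far below the spread of real
cohorts, which reflects biological heterogeneity the generator deliberately
omits.

## Numerical choices and degenerate inputs

* Master equation via `Matrix::expm` (accurate to ~1e−15 in row sums;
  probabilities are clamped of −1e−12-scale round-off, never renormalized).
* Problem sizes in the test suite — 200 replicates for
  simulator-vs-master-equation agreement, 30-cell cohorts, 15 sweeps per
  voltage at five voltages, 500 null datasets for p-value uniformity — were
  chosen so statistical bounds (3 SE, KS at α = 0.01) have comfortable power
  while the whole suite stays around a minute.
* Ties and degenerates carry conventions, not errors, where a convention is
  defensible: zero-variance Welch → p = 0.5 flagged; constant growth series
  → k = 0 flagged; mixture fits refuse fewer samples than parameters.
* `fitLevels()` subsamples only the EM *initialization*; the fit itself
  always uses every sample.
* All randomness flows through explicit integer seeds; derived per-sweep
  seeds are generated by a fixed integer recurrence kept inside 32-bit
  range.

## Known limitations

* The Henderson calculation is concentration-based; ionic-strength
  corrections of a few percent (hence a few tenths of a mV) are out of scope.
* `ghkVoltage()` covers monovalent ions; divalent external solutions are
  handled through the bi-ionic Fatt–Ginsborg relation only.
* The idealizer is a hysteresis threshold, not an HMM; it is meant for
  inspection, and no dwell-time statistics are derived from it.
* The CLI reads the package's JSON container and CSV dialect only;
  proprietary acquisition formats need external conversion.
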