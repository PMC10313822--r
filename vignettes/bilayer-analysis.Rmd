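---
title: "Single-channel bilayer analysis: models, simulators and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel bilayer analysis: models, simulators and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayertools)
```

## Scope and intent

`bilayertools` implements the quantitative core of a planar-bilayer
characterisation of an anion-selective ER channel: electrodiffusion
selectivity math, reduction of gated current traces to open/closed events
and open probability, and dose-response/binding fits for a luminal Ca²⁺
modulator. The raw recordings behind such studies are typically not
deposited, so the package treats *parameter recovery on synthetic data* as
the primary validation route: every estimator is paired with a generator
whose truth it must recover under realistic noise. A green recovery test
establishes that the estimator is correct for data that match the model
assumptions below — it does not establish that any particular biological
recording meets those assumptions.

## Electrodiffusion model

Potentials follow the convention `V = V_cis − V_trans`, with the protein
added to the *cis* chamber (mapped to the ER-lumen face, "In") and *trans*
the cytoplasmic face ("Ex"). Under this convention the standard GHK voltage
equation for monovalent ions places cation *trans* and anion *cis*
concentrations in the numerator of the log ratio. This sign choice is fixed
by the observable anchors of the system: a 150/15 mM (cis/trans) KCl
gradient must give a Cl⁻ Nernst potential of +59.2 mV, an anion-selective
channel a reversal near +56.8 mV, and an inward (negative) unitary current
at 0 mV. (A bi-ionic form with a leading −(RT/zF) factor, sometimes quoted
for such measurements, yields the opposite sign for anions; we adopt the
standard voltage-equation convention throughout because the anchors above
determine it unambiguously.)

Concentrations are used as activities (no activity-coefficient
corrections), only |z| = 1 ions are supported, and temperature defaults to
298.15 K, overridable per call. The two-ion inversion
`permeability_ratio_from_reversal()` is closed-form — the restricted GHK
equation is linear in the ratio — and round-trips with `ghk_reversal()` to
1e−9 relative over ratios 0.01–1000. No solution exists when the requested
reversal exceeds the Nernst limit of the more permeant species; that case
is reported as a domain error rather than clamped.

The single-channel i–V is linear, `i = g (V − E_rev)`, in pA/pS/mV units
(`pS × mV = 10⁻³ pA`). Note one deliberate consequence: with g = 39.9 pS
and E_rev = 56.8 mV the line predicts +1.32 pA at +90 mV; a measured value
of ~1.6 pA at that voltage is not consistent with a single straight line
through (0 mV, −2.27 pA), and the package makes no attempt to reproduce
such a point with a piecewise fit.

## The stated world of the simulators

`simulate_trace()` draws a continuous-time two-state Markov path per
channel (exact exponential holding times), samples it on the acquisition
grid, sums channels, converts open counts to current through the linear
i–V, adds white Gaussian noise, and low-pass filters. Defaults, chosen once
and frozen:

* **Gating** — `k_open = k_close = 50 s⁻¹` (stationary Po 0.5, 20 ms mean
  dwells). Dwell times for this class of channel are not published; 20 ms
  keeps dwells ~60× the 1 kHz filter rise time (~0.34 ms), so the
  idealizer, not the filter, limits accuracy.
* **Sampling** — 10 kHz, 10× the 1 kHz hardware-style filter cutoff.
* **Noise** — 0.45 pA SD white noise before filtering, giving SNR ≈ 5 at
  the 2.27 pA wild-type open level at 0 mV.
* **Ca²⁺ inhibition** — scales `k_open` by `1/(1 + (C/IC50)^h)` with
  IC50 = 1.09 mM, h = 1. Inhibition acts on open probability only; the
  open-level amplitude is untouched, matching the observation that luminal
  Ca²⁺ suppresses Po rather than conductance. The Hill slope defaults to 1
  because no slope is reported for this system.
* **PIP2** — a discrete preset swap to (80.1 pS, faster opening); no
  continuous PIP2 dose dependence is modelled because none is published.
* **Dose grid** — `ca_dose_series()`: 12 log-spaced doses, 0.03–30 mM.
  Twelve points mirror the 12-concentration SPR series used in the same
  protocol, and the range brackets the full span of reported IC50s
  (1.09–19.20 mM). Chosen once, before any recovery thresholds were
  evaluated.
* **SPR kinetics** — `simulate_sensorgram()` uses the closed-form 1:1
  Langmuir solution with 90 s association / 90 s dissociation phases and
  the two-fold series 9.76 µM–20 mM (`spr_conc_series()`). Only K_D values
  are published for this system, so the kinetic truth is declared, not
  inferred: kd = 0.1 s⁻¹ (ka = kd/K_D), fast enough that every
  concentration equilibrates within the 90 s association window.

What the generators deliberately do **not** emulate: sub-conductance or
multi-open-state gating (a two-open-state scheme has been hypothesised for
this channel but is unparameterised), baseline drift, 50 Hz pickup,
mass-transport-limited SPR, bulk refractive-index jumps, and EGTA/Ca²⁺
speciation chemistry. Recovery tests therefore certify estimator behaviour
under idealised bilayer noise, not robustness to instrument artefacts.

## Trace reduction

* **Filtering** — the environment provides no DSP package, so the 1 kHz
  low-pass is realised in-package as a zero-phase FFT filter with the
  analytic magnitude response of a 4-pole Bessel filter (the
  bilayer-amplifier standard), reflective padding at the ends, and exact
  unit DC gain. Zero phase keeps event edges symmetric, which the
  half-amplitude threshold relies on.
* **Amplitude levels** — a Gaussian mixture is fitted to the all-points
  histogram by a weighted EM on 512 bins: deterministic (no random
  restarts; initialisation is histogram peak-picking with an exclusion
  zone, falling back to quantiles), with an SD floor of one bin width.
  Non-convergence is an error unless the components have collapsed onto a
  single level, which is reported as a degenerate-data warning with the
  merged levels. The closed level is identified as the component nearest
  0 pA — valid because baseline correction beyond a constant offset is out
  of scope.
* **Idealization** — half-amplitude threshold at the midpoint of the
  closed and open means, refused outright when the separation is below
  2× the larger component SD. Open events shorter than `min_open_ms`
  (default 0.5 ms, the lower end of the conventional 0.5–1.0 ms range) are
  merged into the flanking closed state; short *closed* gaps are
  deliberately not filtered, an asymmetry inherited from the convention of
  ignoring brief openings only. Raising the cutoff can only remove open
  time, so estimated Po is monotone non-increasing in `min_open_ms` — this
  is asserted as a property test.
* **Open probability** — `Po = t_open / T_total` over the full record;
  dwell summaries report per-state means and counts, with an absent state
  reported as undefined (`NA`), never zero.

## Fitting layer

All nonlinear fits share one engine: multi-start (three log-spaced starts
derived from the data, never hard-coded constants) weighted least squares
on log-transformed positive parameters, minimised by BFGS, with
Gauss–Newton standard errors mapped back to the natural scale by the delta
method. `stats::nls` was rejected because it fails on zero-residual data,
and noiseless generator output is a first-class test input here. Ties
between starts are broken in favour of the first.

* **i–V** — weighted linear least squares; `g` is 1000× the slope,
  `E_rev = −intercept/slope` with delta-method errors. Unbiasedness is
  checked by Monte Carlo (200 seeds, bias < 0.5%).
* **Hill IC50** — fitted to the mean relative Po per dose, with
  inverse-variance weights when replicate SDs are available (SDs floored
  at a third of their median so a lucky zero-variance dose cannot dominate).
  The Hill slope is free by default and always reported; `fix_hill = 1`
  exists because published IC50 tables for this system do not state the
  fitted model form, and the acceptance suite uses the fixed-slope mode to
  match the generator's h = 1 world. All-plateau dose sets are rejected as
  non-identifiable rather than returning a boundary estimate.
* **Langmuir steady state** — isotherm fit of plateau responses (mean of
  the final 10% of the association phase, a Biacore-style convention);
  warns when the top concentration is below the fitted K_D.
* **Langmuir kinetic** — one global fit of the closed-form
  association/dissociation exponentials across all concentrations sharing
  (ka, kd, R_max); `K_D = kd/ka`. Starts: kd from the log-linear slope of
  the largest dissociation phase, K_D/R_max from a steady-state pre-fit.
  Identical concentrations leave ka unidentifiable and are refused. On
  shared synthetic data the steady and kinetic routes agree on K_D within
  2%, which the acceptance suite asserts.

## Numerical and I/O choices

Fixed unit system throughout: ms, pA, mV, pS, mM, RU (s for sensorgram
time); conversions are internal. Traces, events, dose tables and
sensorgrams are plain CSV with unit-tagged headers; results are JSON with
a unit on every numeric field and explicit serialisation of `NaN`. Every
stochastic artefact records its seed, and a trace's JSON sidecar contains
enough metadata to regenerate it exactly. The CLI (`simulate`, `idealize`,
`iv`, `dose`, `spr`, `report`) is a thin wrapper over `run_pipeline()`;
errors in any stage surface as a non-zero exit with the stage named.

## Known limitations

* Two-state gating only; dwell distributions are single-exponential by
  construction, so the simulator cannot probe burst analysis or
  sub-conductance detection, which are out of scope.
* The closed-level convention (component nearest 0 pA) would mislabel a
  trace whose baseline offset exceeds half the unitary amplitude.
* Point-sampling of the Markov path means events shorter than one sample
  (0.1 ms at defaults) may be missed entirely before filtering is even
  considered; this mimics real acquisition but biases dwell statistics for
  rates approaching the sampling rate.
* The kinetic SPR fit assumes reaction-limited binding; transport-limited
  sensorgrams would bias ka downward with no warning.
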