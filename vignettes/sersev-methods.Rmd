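---
title: "Methods: Raman/SERS characterization of plasma EV fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman/SERS characterization of plasma EV fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersev)
```

## The problem

Plasma extracellular vesicles (EVs) are fractionated by differential
centrifugation at 5,000×g, 12,000×g and 120,000×g into crude EV-enriched
fractions (EV5, EV12, EV120); the remaining supernatant, after
ultrafiltration, is an EV-depleted free-circulating (fc) fraction. Two
label-free readouts are compared on each fraction: spontaneous Raman
spectra of dried pellets, and SERS spectra of droplets mixed with
KCl-aggregated silver nanoparticles (AgNPs) at a fixed 20:1 EV:AgNP mass
ratio. The discriminatory signal is carried by a set of SERS bands that are
strongly enhanced in cancer fractions; this package implements the
computation around that observation: quantitation, preprocessing,
map-spectrum selection, and difference-spectrum marker scoring — plus a
synthetic-spectrum generator that makes the whole chain testable.

## Quantitation model

The mass concentration of a fraction is approximated from its nanoparticle
tracking analysis (NTA) number concentration $N$ (particles/mL) and its
dynamic light scattering (DLS) diameter $d$ (nm), assuming spherical
particles of density $\rho$:

$$ c = N \cdot \tfrac{4}{3}\pi \left(\tfrac{d}{2}\right)^3 \cdot \rho $$

with $\rho = 1\,\mathrm{g/cm^3}$ (the standard EV approximation, close to
water/lipid). `mass_concentration()` returns mg/mL; `round_sigfig()` rounds
half-even to two significant figures for comparison against the tabulated
values, which are printed at that precision. The fc diameter is tabulated
only as an upper bound ("< 50 nm") and is evaluated at 50 nm, the only
reading consistent with the tabulated fc concentrations.

Two caveats, both visible in the test suite rather than hidden:

* Recomputing all 12 tabulated cells reproduces most printed values
  exactly at their printed precision, but not all. In particular the
  Pool A EV120 cell computes to 1.054 mg/mL, which rounds to 1.1 against a
  printed 1.0, and two fc cells are 4–8% off before rounding. The source
  table's own rounding chain is not documented; the package reports the
  faithful computation and does not adjust toward the printed digits.
* The published density is stated as "1 mg/mL", which is dimensionally a
  typo; only 1 g/mL (= 1 g/cm³) reproduces the tabulated concentrations,
  so that is the default.

Mixing arithmetic: AgNPs at 0.1 mg/mL are diluted 1:1 by the KCl addition
(`dilution(0.1, 1) = 0.05`), and `mixing_volumes()` solves
$v_{EV} c_{EV} = R\, v_{Ag} c_{Ag}$ with $v_{EV} + v_{Ag} = V_{tot}$
(defaults $R = 20$, $V_{tot} = 10\,\mu L$), refusing infeasible plans.

## Preprocessing

The chain is crop → smooth → baseline → normalize
(`preprocess_spectrum()`), with smoothing before baseline estimation so
noise does not destabilize the baseline weights. The upstream description
of this workflow names only the software environment, not algorithms or
parameters, so the defaults here are the package's own choices of
field-standard, parameter-transparent methods:

* **Crop**: fingerprint region 300–1800 cm⁻¹ (the default axis is
  300–1800 cm⁻¹ at 2 cm⁻¹, 751 points — a configuration choice, since the
  acquisition range is not documented).
* **Smoothing**: Savitzky–Golay, window 11 points, order 3
  (`signal::sgolayfilt`). Exact on polynomials up to the filter order;
  reduces white-noise variance.
* **Baseline**: asymmetric least squares (ALS), the Eilers scheme —
  minimize $\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$
  with $w_i = p$ above the baseline and $1-p$ below, iterated to weight
  convergence. Defaults $\lambda = 10^5$, $p = 0.01$, 20 iterations; the
  solver uses sparse banded algebra and is verified in the tests against a
  dense direct solve of the converged system. Non-convergence returns the
  last iterate with a warning.
* **Normalization**: division by the *maximum* intensity in a
  ±15 cm⁻¹ window around the band ("equal intensities of the band" read as
  peak height rather than area; the window tolerates small calibration
  shifts). Modes: amide I (1660 cm⁻¹) for spontaneous-Raman comparison,
  CH (1448 cm⁻¹) before Raman difference scoring, or none. SERS spectra
  are deliberately never normalized by default — signal *enhancement* is
  the readout — only baseline-corrected.

## Map selection

Raman images of dried films are reduced to "the most intense spectra".
That criterion is operationalized as the trapezoidal integral of the
(baseline-corrected) intensity over 600–1750 cm⁻¹, which is robust to
single hot pixels. `select_top()` takes the top *k* or top fraction
(default q = 0.25, configurable since no count is documented); ties break
by ascending row-major grid index so the selection is deterministic and
invariant to storage shuffling. Averaging uses the sample (n−1) SD,
appropriate for the five-replicate droplet protocol. Scoring happens on
baseline-corrected copies while the selected originals are averaged raw
and then preprocessed; the order is a package decision.

## Difference analysis

Differences are always cancer-mean minus control-mean, so cancer-elevated
bands are positive. Marker readouts:

* `integrate_band()`: trapezoidal area over the closed window
  center ± 10 cm⁻¹ minus the *chord* joining the window-endpoint
  intensities. Chord subtraction makes areas exactly invariant to offsets
  and linear tilts; windows are ±10 cm⁻¹ by default because band positions
  are quoted only as "near X cm⁻¹".
* `call_band_signs()`: a band is POSITIVE/NEGATIVE only if its area
  exceeds 3σ·f_w, where σ = 1.4826 × MAD of the difference over
  designated signal-free regions (defaults 360–370, 740–750,
  1700–1750 cm⁻¹ in the generator geometry; MAD resists residual band
  tails) and f_w is the exact noise-propagation factor of the
  chord-subtracted trapezoidal area over the window's axis points.
  No sign criterion is documented upstream; the 3σ rule is the package's.
* `positive_difference_score()`: the summed positive-marker area, the
  scalar that ranks fractions. `score_noise_sd()` propagates per-point
  noise through the summed functional exactly (overlapping windows, e.g.
  382/394, are accumulated before taking the norm).
* `band_ratio()`: window-maximum height ratio, default 1393/1450 cm⁻¹
  with ±8 cm⁻¹ windows.
* Raman difference scoring happens after CH-band (1448 cm⁻¹)
  normalization; SERS scoring on unnormalized, baseline-corrected spectra.
* The cancer group defaults to pooling both cancer pools; which pool
  underlies any given published difference spectrum is not documented, and
  the choice is overridable.

One sign-convention note: the Raman difference bands at 510, 935, 1315 and
1652 cm⁻¹ are biologically associated with *control*-elevated α-helix and
disulfide content, but this package follows the cancer-minus-control
positive/negative labeling used for the tabulated sign sets, and the
generator constructs its cancer Raman profile accordingly.

## The synthetic generator

`spectrum_profile()` defines, per (modality, fraction, group) cell, a
pseudo-Voigt band mixture (η = 0.7; FWHM 12 cm⁻¹ for SERS, 16 cm⁻¹ for
Raman), a smooth exponential fluorescence-like baseline
(offset + A·exp(−(ν−ν₀)/s)), additive Gaussian noise (σ = 4 counts) and a
per-replicate multiplicative amplitude jitter (SD 5%) for
replicate-to-replicate variation. Band positions come from the published
band lists; relative amplitudes within a panel are uniform (50 counts for
control bands, a 2.4× marker enhancement for cancer before fraction
scaling) because individual band intensities are not quantified — this
uniformity is documented as arbitrary. The control profile gives a
1393/1450 height ratio of 1.0 by construction; cancer profiles exceed it.
Cancer SERS marker amplitudes scale per fraction by
1 : 4.39 : 1.89 (EV5 : EV12 : EV120), the ratios of the published
integrated positive-difference intensities (153,163 / 672,261 / 290,069),
which are meaningful only as ratios since the underlying intensity scales
were not identical. Raman difference features scale by 1 : 1.93 : 2.39,
the ratios of the CH-normalized difference integrals (7,205 / 13,908 /
17,251). The fc profiles contain protein bands only (Tyr 643/826/850,
Phe 622/1003/1209, backbone 940/1300/1655, aliphatic 1340/1450), with
carotenoid bands 1157/1523 in controls only — so the fc cancer-marker
score is null by construction, mirroring the absence of the markers in
fc fractions.

Seeding: a cohort has one master seed; the k-th spectrum of the fixed
enumeration gets sub-seed `(seed + 7919·k) mod (2³¹−1)`, so cohorts are
bit-identical regardless of generation order. Maps place full-amplitude
signal inside a disk (the dried-film area, radius 0.45·min(rows, cols) in
pixels by default) and 5% amplitude outside, with baseline and noise
everywhere.

What the generator does *not* emulate: plasmonic SERS physics, instrument
response, cosmic rays, Poisson shot noise, wavenumber miscalibration, and
correlated biological variation between bands. Tests passing on synthetic
cohorts therefore validate the *pipeline logic* — sign recovery,
ordering, null behavior, noise thresholds — not clinical performance on
real plasma.

## Numerical choices and degenerate inputs

* Axes are stored ascending; descending files are reversed on read;
  duplicate wavenumbers are errors.
* Subtraction requires bit-identical axes (tolerance 1e-9 relative);
  resampling is an explicit, provenance-logged step and refuses to
  extrapolate.
* Crop and band windows are closed intervals.
* Normalization fails loudly on a non-positive window maximum (a baseline
  failure signal) rather than returning infinities.
* ALS weights are binary-converged (weight vector fixed point); the
  returned baseline solves the final weighted system to solver precision.
* Selection tie-breaks are deterministic (row-major grid order).
* JCAMP-DX support is read-only and limited to uncompressed
  `(X++(Y..Y))` data; compressed encodings fail with an explicit error.

## Problem sizes used in validation

The bundled validation runs use the default 751-point axis, 5 replicates
per group, and 100-seed Monte-Carlo repetitions for the noisy claims
(marker recovery, fraction ordering, fc null behavior) — sizes chosen to
give stable pass/fail statistics for property checks while keeping a full
run convenient on a laptop.

## Known limitations

* The printed-table rounding mismatch described under *Quantitation*.
* Difference analysis assumes a shared axis across groups; instrument
  drift between sessions must be handled upstream (resampling is provided
  but calibration transfer is out of scope).
* No multivariate classification (PCA-LDA etc.) — scoring is deliberately
  the published band-integral statistic.
* Peak fitting/deconvolution and cosmic-ray removal are out of scope.
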