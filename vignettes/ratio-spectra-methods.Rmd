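---
title: "Resolving overlapped binary mixtures by ratio-spectra manipulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving overlapped binary mixtures by ratio-spectra manipulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiospec)
```

## The model

Two non-interacting absorbers obey Beer–Lambert additivity: the mixture
absorbance is `A(λ) = c_x a_x(λ) + c_y a_y(λ)`, with `a_x`, `a_y` the
unit-concentration absorptivity curves. When the two curves overlap across
the whole usable range — as for bisoprolol fumarate (BPL, a weak absorber
peaking near 223 nm) and telmisartan (TST, a strong broad absorber out to
~330 nm) — no wavelength isolates either analyte and direct calibration
fails.

Division by a divisor standard of analyte *y* at concentration `c_d`
produces the ratio spectrum

$$P(\lambda) = \frac{A(\lambda)}{c_d\,a_y(\lambda)}
  = c_x \frac{a_x(\lambda)}{c_d\,a_y(\lambda)} + \frac{c_y}{c_d},$$

in which the interferent appears only as the additive constant
`c_y / c_d`. Any linear functional that annihilates constants therefore
yields a signal exactly proportional to `c_x`. The package implements the
three standard choices:

* **ratio difference (RD)** — `P(λ₁) − P(λ₂)`;
* **first derivative (¹DD)** — `D(λ) = k · [P(λ+Δλ) − P(λ−Δλ)] / (2Δλ)`;
* **mean centering (MC)** — `P(λ) − mean(P)` over a working window.

All three are linear operators on spectra sharing a grid, mask and
divisor, so mixture signals decompose into pure-component signals and a
pure sample of the divisor analyte gives a signal of exactly zero; the
test suite asserts both to 1e-9 on noise-free synthetic spectra.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| grid | 1 nm over 200–400 nm | benchtop UV–Vis export convention; 0.1/0.5 nm grids supported |
| divisor (for BPL) | TST 16 µg/mL | denominator standard; larger concentrations reduce `mean(1/A_d)` noise amplification |
| divisor (for TST) | BPL 10 µg/mL | |
| `epsilon` | 0.01 AU | division guard: samples with `|A_d| < ε` are masked, never emitted as huge ratios |
| RD pairs | 210/224 nm (BPL), 255/265 nm (TST) | analysis wavelength pairs |
| `delta_lambda` | 4 nm | half-width of the symmetric-difference stencil |
| `scaling_factor` | 10 | cosmetic multiplier on the derivative; cancels in calibration but keeps amplitudes comparable with instrument software |
| ¹DD wavelengths | 232 nm (BPL), 243 nm (TST) | |
| MC window | 200–305 nm | mean-centering range, both analytes |
| MC wavelengths | 223 nm (BPL), 245 nm (TST) | |

The derivative operator deserves a note: instrument software names only a
Δλ and a scaling factor without defining the operator. The symmetric
difference over ±Δλ is the standard reading; it is exact for locally
quadratic signals (asserted to 1e-12 in the tests), and a Savitzky–Golay
first-derivative option (`method = "savgol"`, window and order
configurable) is provided for noisier data but is not the default.
Whether Δλ counts nanometres or grid points is likewise unstated in
instrument conventions; nanometres are assumed, and `first_derivative()`
refuses a Δλ that is not a multiple of the grid step.

Signals are kept signed (the BPL RD and ¹DD slopes on the bundled system
are negative); calibration handles negative slopes, and `lod()`/`loq()`
use `|S|`.

## Calibration and limits

`fit_calibration()` is unweighted ordinary least squares of signal on
concentration, returning a classed fit with `print`, `summary`, `coef`,
`predict`, `plot`, `residuals` and `simulate` methods. σ is the residual
standard deviation with n−2 degrees of freedom, matching the
residual-standard-deviation convention of `LOD = 3.3σ/S`; the
SD-of-intercept alternative from the ICH family is available via
`sigma_method = "intercept"` but is not the default. r² is the squared
Pearson correlation, identical to the coefficient of determination for
simple OLS. Inverse prediction outside the calibrated range warns but
returns the value — a QC analyst needs the number together with the flag.
A printed-precision caveat: published LOD/LOQ tables are computed from
unrounded internals, so recomputing one from the other's printed value can
differ in the last digit (±0.0002 is the agreement band used in the
acceptance tests).

## Validation statistics

Recovery is `100·found/taken`; summaries use the sample SD (n−1) and
`RSD = 100·SD/mean`. Standard addition is computed on the added amount,
`100·(spiked − base)/added`, so matrix contributions cancel. The method
comparison uses the pooled-variance *t* (the critical value 2.306
corresponds to df = 8 = 5+5−2, fixing the pooled rather than Welch
convention) and the larger/smaller variance-ratio *F* (critical
F(0.05; 4, 4) = 6.388). When a published panel prints per-level mean
recoveries, summaries are reproduced from those five printed means;
pipeline mode (`validate_study()`) summarizes all raw determinations.

`select_signal_wavelengths()` scores every candidate (pair) by
calibration r², |slope| and interferent leakage (max |signal| of the pure
interferent), selecting the best r² subject to leakage below 1 % of the
target's mid-range signal, ties broken by |slope|; it equals an exhaustive
search by construction and is tested against an independent `lm()`-loop
oracle. `divisor_scan()` ranks candidate divisors by r² (rounded to 1e-9
so noise-free ties resolve deterministically) and then by the noise
amplification index `mean(1/|A_d|)` over the method's working window —
which is why higher divisor concentrations rank first on noise-free data.

## The synthetic system

No digitized spectra of the two drugs are published, so the generator
uses Gaussian band profiles as clearly-labelled synthetic stand-ins:

* BPL-like: bands (223 nm, 8 nm, 0.065 AU/µg/mL) and (271, 15, 0.006);
* TST-like: bands (212, 11, 0.020), (235, 16, 0.026), (296, 15, 0.030).

These were fixed once, from the published overlap geometry: BPL's maximum
below 240 nm, negligible BPL absorbance above ~290 nm (TST dominates
≥10-fold at 296 nm), strong TST absorbance at the BPL pair 210/224 nm,
and top-of-range peak absorbances around 1.0–1.3 AU — typical benchtop
values. Consequences to keep in mind: **absolute slopes and LOD/LOQ values
of the synthetic system are not comparable to published instrument
values** — only structural and statistical properties (linearity,
selectivity, noise propagation, recovery statistics) are meaningful.

Noise is additive white Gaussian on absorbance (default SD 0.002 AU),
optionally with a constant baseline offset; multiplicative/shot noise and
instrument artifacts (stray light, wavelength miscalibration) are out of
scope, consistent with the additive-noise assumption of the methods'
theory. Excipients default to non-absorbing, so the tablet matrix is
spectrally silent. Every stochastic call takes an explicit seed and
restores the caller's RNG state; `generate_validation_study()` derives
per-file seeds from the study seed, making studies byte-identical across
runs.

What passing tests on this generator do show: the transforms' exact
selectivity and linearity, correct error propagation, and end-to-end
recovery under realistic SNR. What they cannot show: robustness to
baseline curvature, wavelength-axis errors, or absorptivity nonlinearity
at high absorbance, none of which the generator emulates.

## The Monte-Carlo recovery study

`recovery_performance()` quantifies end-to-end accuracy/precision: each
reported recovery is the mean of three noisy determinations (the usual
replicate-determination convention), pooled over 200 replicate runs of
the five-mixture panel (BPL 2–4 µg/mL against TST 16–32 µg/mL, the 1:8
dose ratio). The calibration line is fitted on noise-free reference
standards by default (`calibration_noise_sd = 0`): recovery RSDs are
conventionally quoted against a fixed validated curve, so the spread
isolates determination repeatability; folding a single simulated noisy
calibration into the study would instead measure the intercept drift of
that one curve, which at the 2 µg/mL panel level dominates everything
else. With these defaults the bundled system reproduces the expected
bands: mean recovery within 100 ± 0.1 %, pooled RSD 0.4–1.8 % depending
on method (the BPL ¹DD is the noisiest — the derivative stencil amplifies
white noise by √2·k/(2Δλ) on top of the 1/A_d division).

## Numerical choices and edge cases

* Wavelength windows are inclusive at both ends, matching how ranges such
  as "200–305 nm" are quoted.
* Masked samples (divisor below `epsilon`) propagate: a derivative value
  whose stencil touches a masked point is masked; `amplitude_at()` raises
  a masked-signal error rather than interpolating, and off-grid reads of
  derived signals are refused outright.
* MC and regridding: the MC signal subtracts an equal-weight mean of grid
  samples (exactly what matrix mean-centering software does), which
  shifts at O(h) through the window endpoints and the divisor-guard
  boundary when the grid is refined. RD and ¹DD signals are invariant to
  1 nm → 0.5 nm regridding within 0.1 % on the bundled smooth spectra; MC
  signals can move by a few percent when the guard boundary cuts through
  the window (the TST configuration, whose BPL divisor falls below 0.01 AU
  near 300 nm). Comparisons across grids should therefore fix the grid
  for MC work.
* A zero OLS slope is detected relative to the data spread (an exactly
  degenerate fit lands at ~1e-17 in floating point); such fits refuse
  inversion and LOD/LOQ.
* `divisor_scan()` r² ties are broken on noise amplification; r² is
  rounded to 1e-9 first so that floating-point dust does not override the
  documented tie-break.
* Problem sizes in the shipped tests and acceptance computations — 200
  Monte-Carlo replicates, 10,000 null simulations for the *t* type-I-error
  check, ≤2 nm selection grids — were chosen as the smallest sizes at
  which the assessed statistics are stable to well within their assertion
  bands.

## Known limitations

Binary mixtures only: double-divisor and successive-derivative variants
for ternary mixtures are not implemented. No baseline correction or
smoothing beyond the ¹DD definition; no JCAMP-DX or vendor binary I/O
(two-column CSV/TSV with `# key=value` headers is the interchange
format). Calibration is unweighted simple OLS — no weighted, nonlinear or
errors-in-variables regression. Published-table reproduction is limited
to arithmetic recomputation from printed inputs; one published *t* cell
(BPL ¹DD) is not reproducible from its printed means and SDs by the
pooled formula and is documented as an inconsistency rather than matched.
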