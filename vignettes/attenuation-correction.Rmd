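---
title: "Guidewire-referenced blood-attenuation correction: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guidewire-referenced blood-attenuation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirfcorr)
```

## The model and its assumptions

Intravascular NIRF signals traverse two media before detection: the
water-filled gap between the rotating sensor and the outer catheter sheath
wall (path $d_s$, coefficient $C_w$), and the intraluminal medium between
the sheath wall and the target (path $d$, coefficient $C_b$ for blood,
$C_w$ for a water control). The package models both losses as one-term
exponentials,

$$I = I_0\,e^{-C_w d_s}\,e^{-C_b d},$$

with $I_0$ the source intensity *referenced at the outer sheath wall*.
Everything downstream rests on four assumptions:

1. **One-term exponential attenuation.** Combined excitation + emission
   loss over the optical path is summarised by a single effective
   coefficient per medium. Two-term (Twersky-type) scattering models are
   deliberately out of scope.
2. **Equal incident intensities.** The guidewire imaged during calibration
   and during the blood measurement is the same physical object with the
   same coating, so the sheath-wall-referenced $I_0$ fitted in water equals
   the one present in blood. Practically this means the calibration must be
   *reference-matched*: calibrate with the coated guidewire (50 µM) before
   guidewire-referenced pullbacks, or with the 27 µM reference capillary
   before capillary-phantom runs. Mixing them biases every frame-wise
   coefficient by $\ln(I_0^{cal}/I_0^{ref})/d$.
3. **Frame-wise stationarity.** Within one cross-sectional frame the blood
   between sheath and wall is homogeneous enough for a single $C_b$; across
   frames it may vary freely (that is the point of the method).
4. **Linear fluorescence.** Source intensity is proportional to fluorophore
   concentration. ICG self-quenches above ~50 µM, so the linear
   concentration map `to_concentration()` is only trusted up to the coating
   concentration; all simulated scenes stay at or below it.

### Sign and reference convention

Flattened typography makes the printed exponent signs of the correction
equations ambiguous. The package adopts the single self-consistent
convention in which *attenuation multiplies by $e^{-Cd}$ and correction by
$e^{+Cd}$*, with all calibration look-ups referenced at the outer sheath
wall. Under this convention the estimator

$$C_b = \frac{\ln\big(I_{\mathrm{ref}}(d)/I_{GW}^{*}\big)}{d} + C_w,
\qquad I_{\mathrm{ref}}(d) = I_0 e^{-C_w d},$$

recovers the *generating* coefficient exactly on noiseless input — the
criterion that fixes the convention. Note the $+C_w$ term: because the
look-up already contains the water decay $e^{-C_w d}$, adding $C_w$ makes
$C_b$ the **total** coefficient of the blood path, not the excess over
water. This is forced by requiring the blood correction $e^{+C_b d_T}$ to
cancel against a water-referenced ground truth; an excess-over-water
definition would double-count water attenuation on one side of the
comparison. A water-filled lumen correctly returns $C_b = C_w$.

### The unit question

The reference system reports coefficients of 0.0009 mm⁻¹ (water) and
0.0028/0.0034 mm⁻¹ (50%/75% blood). Taken literally these imply < 0.6%
signal loss over the ≤ 1.6 mm paths involved, which is hard to reconcile
with the strong attenuation the method exists to correct; a per-µm
misprint (i.e. 0.9/2.8/3.4 mm⁻¹) is plausible. The package takes no side:
simulator defaults reproduce the printed numbers verbatim, and a single
`unit_scale` factor on the scene (default 1) rescales both coefficients
coherently when the per-µm reading is wanted. Quantities that only make
sense under substantial attenuation — the distance-error sensitivity
analysis, the noisy-recovery and fold-improvement checks — use the per-µm
reading (e.g. $C_b = 3.4$ mm⁻¹); exact-recovery checks use the printed
values unchanged. Nothing is rescaled silently.

## Calibration

`run_calibration()` summarises each frame's guidewire sector by the mean of
its five highest angular samples (the top-five rule; with fewer than five
samples, all are used with a warning) and fits

$$\log I = \log I_0 - C_w\,(d_s + d)$$

by ordinary least squares on the log scale. Two numerical choices matter:

- **Folding the sheath referencing into the fit.** Referencing each sample
  to the sheath wall requires $C_w$, which is the quantity being fitted.
  Regressing on the *total* water path $d_s + d$ is algebraically identical
  to referencing first and fitting on $d$ alone, and is exactly solvable in
  one pass. The diagnostic table is re-expressed at the sheath wall after
  the fit.
- **Centred regressor.** The design is centred before solving, making the
  intercept numerically exact; noiseless recovery of $(I_0, C_w)$ is then
  limited only by the Jensen gap of averaging five samples across the
  angular in-sheath profile (relative error ~10⁻¹⁰, far below every stated
  tolerance).

The fit is log-linear (unique, closed-form) rather than iterative nonlinear
least squares; a `refine = TRUE` flag runs an `nls` polish initialised at
the log-linear solution, but defaults off because on log-normally
distributed noise the log-scale fit is also the statistically natural one.
$R^2$ is reported on the log scale. The look-up is evaluated analytically
from the fitted model at any distance, not interpolated from the raw table.

## The correction pipeline

Per frame, `correct_pullback()`: water-corrects each guidewire sample with
its own $d_s$, takes the top-five mean ($I_{GW}^{*}$) and the mean distance
of the contributing samples ($d_{GW}$); estimates $C_b$; water- and
blood-corrects every tissue sample with its own $d_s$ and $d_T$; and
converts to concentration against the reference propagated to the
zero-distance plane, $I_{GW}^{*} e^{+C_b d_{GW}}$, at the coating
concentration `c_ref`.

Degenerate inputs are handled explicitly:

- intensities are floored at $10^{-12}$ before logarithms;
- a negative estimated $C_b$ (possible under noise when the guidewire
  appears brighter than the water reference) is returned as-is with a
  warning — clamping to zero is opt-in (`clamp_cb = TRUE`) because silent
  clamping biases the pullback mean upward;
- frames without guidewire samples reuse the nearest *preceding* frame's
  reference with a warning (configurable to a hard error); the first frame
  has no fallback and errors;
- tissue samples at $d_T = 0$ receive only the in-sheath correction.

The in-sheath ("sheath") correction can be ablated for tissue samples
(`sheath_correct = FALSE`) to quantify its contribution; the guidewire
reference always keeps its sheath correction because the coefficient
estimate is undefined without it. Under ablation the per-target accuracy
loss is $1 - e^{-C_w d_s}$, exactly ordered by each sector's
sensor-to-sheath path — the qualitative ordering the phantom experiment
demonstrates.

## Evaluation metrics

The reference publication reports accuracies and variances without stating
formulas, so the definitions here are the package's own and are used
consistently:

- **accuracy**: per-sample $100\,(1 - |x - t|/t)$, clamped at 0; summarised
  by the mean and the *population* variance (divide by $n$) of the
  per-sample accuracies, in %². The population form is fixed by the
  package's worked two-point example (mean 90, variance 100).
- **fold improvement**: mean absolute relative error of the uncorrected
  series divided by that of the corrected series. Uncorrected intensities
  live on an arbitrary scale, so a single least-squares gain
  $g = \langle u,t\rangle/\langle u,u\rangle$ puts them on the truth scale
  first — without it the ratio would mostly measure the scale mismatch.
  Exact recovery reports `Inf`.
- **agreement**: $100\,(1 - \mathrm{mean}(|c_i - f_i|/c_i))$ between
  frame-calculated and fit-extracted coefficients
  (`validate_cb_fit()` produces both from one pullback).
- **sensitivity**: both the sheath-to-guidewire and sheath-to-tissue
  distances *fed to the correction* are perturbed jointly by the same
  signed delta (the conservative reading of "altered both"), the geometry
  generating the data stays untouched, and accuracy is computed per delta;
  the summary averages the nonzero deltas. A delta driving any distance
  non-positive is skipped with a warning. The response is asymmetric in
  $\pm\delta$ because the error factor is exponential.

## The simulator's stated world

`phantom_scene()` encodes the three experimental scenes with their stated
geometry: calibration ramp 0.1–1.0 mm over 80 frames (20 mm at 0.25 mm/s,
60 rpm); capillary phantom with a fixed 27 µM reference jittering inside
0.43–0.53 mm and three slanted targets (6.8/27/13 µM) spanning
0.55–1.0 mm; artery scene with the guidewire at 0.5–0.85 mm, tissue at
0.09–0.4 mm and a Gaussian concentration bump peaking at 38 µM (the bump
centre snaps to an actual frame so the stated peak is attained). Choices
the source leaves open, fixed once:

- 256 angular samples per frame (typical rotational-catheter sampling);
- intensity yield 20 a.u./µM — arbitrary units; every check is scale-free;
- in-sheath path: per-angle sinusoid 0.1–0.6 mm emulating catheter bending
  (per-sector constants 0.15–0.5 mm in the capillary phantom, where the
  sector-wise differences drive the ablation experiment);
- noise: multiplicative lognormal with median 1 (log-sd `sigma`, realistic
  runs use 0.05) plus an optional half-normal background floor; both
  default 0 so acceptance runs are noiseless and exactly invertible;
- targets are angularly uniform within their sectors.

That last simplification has a visible consequence: under multiplicative
noise the top-five rule selects the upper noise tail of an otherwise flat
sector, biasing $I_{GW}^{*}$ up and the recovered $C_b$ down by ~3% at
`sigma = 0.05`. Real guidewire sectors have a bright specular core, so the
real bias is smaller; the package reports the honest simulated value rather
than tuning it away.

What a green test does **not** establish: performance on real blood
(spatially heterogeneous, pulsatile), on IVUS segmentation errors beyond
the rigid distance offsets of the sensitivity protocol, under fluorophore
diffusion or photobleaching, or near quenching concentrations. The
published ex-vivo accuracies (89%/9.6%, 91%/4.3%, 2.2-/4.5-fold) depend on
undeposited experimental data; the synthetic analogues here substitute
exact round-trip identities plus seeded noisy-recovery bounds.

## Containers and provenance

Pullbacks are stored as a directory of plain CSV matrices (one per array,
written at full `%.17g` round-trip precision) with a JSON metadata sidecar
and a YAML scene descriptor — inspectable with any text tool, and the only
text-native container in the supported stack (no HDF5 bindings). Every
stochastic path requires an explicit integer seed; identical configuration
and seed reproduce output files bit-for-bit, including through the CLI
(`simulate`, `calibrate`, `correct`, `evaluate`, `sensitivity`).

## Known limitations

- The frame-wise estimator needs a usable guidewire sector in (almost)
  every frame; long guidewire shadowing degrades to the stale-reference
  fallback.
- The linear concentration map ignores ICG self-quenching; concentrations
  approaching the 50 µM coating are reported but increasingly biased in
  reality.
- `fold_improvement`'s gain normalisation makes the metric blind to a pure
  scale error in the uncorrected data — intended, but worth remembering
  when comparing against publications that normalise differently.
- The per-µm vs per-mm coefficient reading is unresolved by the source
  text; results that depend on it are always computed under an explicitly
  stated `unit_scale`.
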