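# nirfcorr

Blood-attenuation correction for hybrid intravascular NIRF–IVUS imaging,
using a fluorophore-coated guidewire as an in-situ reference.

## The problem

Intravascular near-infrared fluorescence (NIRF) imaging reads out
fluorophore signals (e.g. indocyanine green, ICG) from the vessel wall
through whole blood, whose attenuation varies strongly with the
catheter-to-wall distance and with blood composition. Without correction,
the same fluorophore concentration can produce wildly different intensities
from frame to frame of a helical pullback. Co-registered intravascular
ultrasound (IVUS) provides the distances; the missing quantity is the
effective attenuation coefficient of the blood actually present in each
frame.

The approach implemented here coats the clinical guidewire with a known
fluorophore concentration (50 µM ICG in epoxy), so every frame contains a
reference target of known brightness at a known (IVUS-measured) distance.
Comparing the measured guidewire signal with a water-phantom calibration
yields a fresh blood attenuation coefficient for *every frame*, which is
then applied to the tissue signals of that frame.

## The model

Light from a source of intensity $I_0$ referenced at the outer sheath wall
is attenuated exponentially over the in-sheath water path $d_s$ and the
intraluminal path $d$:

$$I = I_0 \, e^{-C_w d_s} \, e^{-C_b d}$$

with $C_w$, $C_b$ the effective one-term attenuation coefficients of water
and blood (mm⁻¹). The pipeline is:

- **S1 — calibration** (`run_calibration`): a water-phantom pullback of the
  coated guidewire at distances 0.1–1.0 mm; log-linear least squares gives
  $(I_0, C_w)$ and an analytic look-up $I_{\mathrm{ref}}(d) = I_0 e^{-C_w d}$.
- **S2/S3 — water referencing** (`water_correct_to_sheath`): per frame, the
  top-five-mean guidewire intensity and all tissue intensities are
  multiplied by $e^{+C_w d_s}$ to remove the in-sheath loss
  ($I_{GW}^{*}$, $I_T^{*}$).
- **S4 — frame-wise coefficient** (`estimate_cb_frame`):
  $C_b = \ln\!\big(I_{\mathrm{ref}}(d_{GW}) / I_{GW}^{*}\big)/d_{GW} + C_w$,
  the total blood coefficient that explains the observed guidewire loss.
- **S5 — correction and quantification** (`blood_correct`,
  `to_concentration`): tissue samples become
  $I_T^{**} = I_T^{*} e^{+C_b d_T}$ and concentrations
  $c = c_{\mathrm{ref}} \, I_T^{**} / (I_{GW}^{*} e^{+C_b d_{GW}})$.
- **Ground truth** (`ground_truth_pullback`): a paired control pullback
  through water, fully water-corrected via $e^{+C_w (d_s + d_T)}$.

A seeded simulator (`phantom_scene` + `simulate_pullback`) generates the
three experimental scenes (slanted-guidewire calibration phantom,
four-capillary target phantom, blood-perfused artery) as the test bed, and
`accuracy`, `fold_improvement`, `sensitivity_analysis`, `validate_cb_fit`
and `agreement_metric` reproduce the evaluation protocol.

## Worked example

```r
library(nirfcorr)

# water calibration of the coated guidewire (noiseless phantom)
calib <- run_calibration(simulate_calibration_phantom(
  phantom_scene("calibration", cw_true = 0.9)))

# noisy artery pullback through blood (5% multiplicative noise)
scene <- phantom_scene("artery", cb_true = 3.4, cw_true = 0.9,
                       noise = list(sigma = 0.05, floor_frac = 0),
                       seed = 2026)
pb <- simulate_artery_pullback(scene)
cs <- correct_pullback(pb, calib, c_ref = 50)
print(cs)
#> NIRF correction series (blood-corrected): 80 frames
#>   mean Cb: 3.28965 mm^-1 (sd 0.0301)
#>   concentrations: 3.61 - 44.2 uM at 4800 samples

tis <- pb$label == LABEL_TISSUE
truth <- pb$truth$intensity[tis]
a <- accuracy(cs$it_star2[tis], truth)
fold <- fold_improvement(pb$nirf[tis], cs$it_star2[tis], truth)
sprintf("accuracy %.1f%% (variance %.1f), fold improvement %.1f",
        a$mean, a$variance, fold)
#> "accuracy 95.5% (variance 10.9), fold improvement 7.2"
```

The mean recovered coefficient (3.29 mm⁻¹ vs the generating 3.4 mm⁻¹)
carries the small downward bias induced by the top-five-mean rule under
multiplicative noise; corrected tissue intensities agree with the
attenuation-free ground truth to ~95% on average, a 7-fold error reduction
over the uncorrected signals.

A command-line interface covers the same pipeline
(`inst/cli/nirfcorr simulate | calibrate | correct | evaluate |
sensitivity`).

## Documentation

The methods vignette (`vignettes/attenuation-correction.Rmd`) describes the
model and its assumptions, the simulator's stated world, all metric
definitions, numerical choices and known limitations.
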