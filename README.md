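# pulseoxmc

Monte Carlo simulation of reflectance pulse-oximeter signal strength in
a three-layer head phantom with a pulsatile artery.

## The problem

Reflectance pulse oximetry reads arterial oxygenation from the
pulsatile modulation of backscattered light, with source and detector
on the same skin surface. How strongly an artery modulates the signal
depends on its depth: detected photons travel a banana-shaped path
between source and detector, so the most superficial artery is *not*
the most visible one. `pulseoxmc` quantifies this for a skin (1.5 mm) /
skull (5.0 mm) / brain (semi-infinite) phantom at 910 nm with a
cylindrical blood-filled artery at configurable depth, an 11 mm
source–detector separation and a 7.5 mm² detector, and computes the
pulsation amplitude — the oscillation of the detected flux as the
artery throbs between its relaxed (0.4 mm) and 4 %-dilated diameter —
in ppm of the injected flux.

## The model

- **Transport** (`run_simulation`): weighted photon-packet Monte Carlo
  (MCML-style) in C++. Exponential free paths s = −ln(u)/μₜ truncated
  at material boundaries; albedo weighting w ← w·μₛ/(μₐ+μₛ) per
  collision; Henyey–Greenstein scattering with g = 0.95; Russian
  roulette below 10⁻⁴ with exact bookkeeping, so
  injected = detected + absorbed + escaped to float rounding on every
  seed. Per-packet RNG substreams make runs bit-reproducible and
  batch-invariant. Analytic (implicit) geometry by default; a 0.05 mm
  voxelized mode mirrors the reference discretisation.
- **Pulsation pipeline** (`sweep_diameters`, `fit_signal_vs_diameter`,
  `pulsation_amplitude`, `depth_profile`): sweep the artery diameter
  over 0.30–0.50 mm, fit the detected fraction linearly against
  diameter, evaluate the fitted line at 0.400 and 0.416 mm. The default
  estimator is perturbation Monte Carlo: one baseline run of the
  homogeneous layered medium records per-packet path lengths ℓ and
  collision counts k inside every candidate artery cylinder, and each
  diameter's detected fraction follows from the exact likelihood ratio
  w → w·(μₛᵇ/μₛʰ)ᵏ·exp(−(μₜᵇ−μₜʰ)ℓ) — exact because all materials share
  one anisotropy factor, so no phase-function correction appears. That
  is what makes a sub-ppm
  differential measurable with ~10⁶ packets instead of the reference
  3.5×10⁸.
- **Calibration** (`adc_lsb_current`, `sensitivity_from_points`,
  `area_scaled_flux`, `current_to_flux`, `flux_to_ppm`): the
  direct-converting oximeter arithmetic — 5 700 nA full scale over 17
  noiseless bits (LSB 43.49 pA ≈ 44 pA), 0.71 A/W photodiode
  sensitivity, 92.16 → 7.5 mm² area scaling, ppm normalisation to the
  1.8 mW source.

## Worked example

```r
library(pulseoxmc)
sw  <- sweep_diameters(3.7, photons = 2e5, seed = 7)   # artery 3.7 mm deep
print(sw)
fit <- fit_signal_vs_diameter(sw)
pulsation_amplitude(fit)
```

```
Diameter sweep at depth 3.70 mm (perturbation, 200,000 packets, seed 7)
 diameter_mm      ppm   se_ppm
        0.30 113.1525 12.36446
        0.35 110.8504 12.20643
        0.40 107.8054 12.02975
        0.45 104.6210 11.83048
        0.50 101.3394 11.63076
Pulsation amplitude at depth 3.70 mm: 0.478 ppm (s.e. 0.095 ppm)
  baseline 0.400 mm, dilation 4.0% -> dilated 0.416 mm
```

Reading: about 108 ppm of the injected flux reaches the detector with a
0.4 mm artery; widening the artery absorbs more light (the fractions
fall), and the fitted 4 % dilation swing, halved to the waveform
amplitude, gives ≈ 0.5 ppm at this packet count (s.e. 0.1 ppm; the
0.32 ppm reference value is recovered as the statistics tighten). The
full depth profile and its maximum:

```r
profile <- depth_profile(photons = 1e6, seed = 1)  # depths 1.2 ... 9.6 mm
print(profile)
profile$argmax_depth_mm   # 2.5 — the strongest signal is NOT the shallowest artery
plot(profile)
```

A thin CLI over the same functions ships in `inst/cli/pulseox`
(`simulate`, `sweep`, `profile`, `calibrate`, `fixture` verbs), and
`load_phantom_config()` reads the YAML phantom description in
`inst/extdata/phantom_default.yaml`.

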