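---
title: "Photon transport in a pulsatile-artery head phantom: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon transport in a pulsatile-artery head phantom: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseoxmc)
```

## The problem

A reflectance pulse oximeter places a light source and a photodiode on
the same tissue surface, about a centimetre apart, and reads the
oxygen-dependent modulation that arterial pulsation imprints on the
backscattered light. How strong that pulsatile component is depends on
where the artery sits: too superficial and the photon paths ("banana")
pass below it; too deep and few detected photons ever reach it.
`pulseoxmc` simulates this situation for a three-layer head phantom —
skin (1.5 mm), skull (5.0 mm) and a semi-infinite brain layer — with one
cylindrical artery of blood-like liquid embedded at a configurable
depth, and computes the pulsation amplitude, in parts per million of the
injected flux, as a function of artery depth.

All optical properties refer to 910 nm and are held in one constants
table (`phantom_constants()`): absorption / reduced scattering of
0.37/16 cm^-1 (skin), 0.15/18 (skull), 0.4/21 (brain) and 11/19
(blood), anisotropy factor g = 0.95 for every material. The source and
detector sit 11 mm apart; the detector has the 7.5 mm^2 active area of
the reference photodiode; the artery axis runs perpendicular to the
source–detector line beneath its midpoint.

## Transport model

The kernel (`run_simulation()`) is a weighted photon-packet Monte Carlo
in the MCML tradition, written in C++:

- free paths are exponential, `s = -log(u) / mu_t`, truncated at
  material boundaries (layer planes and the artery cylinder in the
  analytic default; voxel faces in the 0.05 mm voxelized mode), with the
  remaining path resampled after each crossing — exact for the
  memoryless exponential;
- each collision multiplies the packet weight by the single-scattering
  albedo `mu_s / (mu_a + mu_s)` and deflects the direction by an
  inverse-CDF sample of the Henyey–Greenstein phase function;
- packets below a weight of 1e-4 play Russian roulette (survival 0.1)
  with bookkeeping arranged so that
  injected = detected + absorbed + escaped holds to floating-point
  rounding on every run, not just in expectation;
- weight crossing the top surface inside the detector aperture is
  detected; all other exits (surface outside the aperture, lateral and
  bottom domain walls) are tallied as escaped.

Packets carry weights rather than being absorbed analytically because
the quantity of interest — the change in detected flux under a 4%
artery dilation — is of order 0.1–1 ppm of the injected flux, far below
what analog scoring can resolve at desk-scale packet counts.

Random numbers come from per-packet xoshiro256++ substreams seeded by a
splitmix64 hash of (global seed, packet index). Packet *i* therefore
sees the same stream regardless of how a run is partitioned into
batches, which makes runs bit-reproducible, batch-invariant, and gives
common random numbers across scenario variants for free.

Two boundary models are provided. The default treats the surface as
refractive-index matched (n = 1 everywhere); a Fresnel mode assigns the
tissue n = 1.4, applies the specular entry loss and reflects internally
with the Fresnel coefficient (total internal reflection included). The
reference simulation does not state its boundary treatment; we measured
the difference (a few percent on the detected baseline, within Monte
Carlo error on the amplitudes) and kept the matched model as the
default.

## From diameter sweeps to a pulsation amplitude

Following the reference procedure, the artery diameter is swept over
0.30–0.50 mm in 0.05 mm steps, the detected fraction is fitted linearly
against diameter, and the pulse is evaluated on the fitted line between
the relaxed diameter (0.400 mm) and the 4%-dilated diameter (0.416 mm) —
never by rounding to the simulated grid. The peak-to-peak swing on the
fitted line is `-slope * 0.4 * 0.04`; `pulsation_amplitude()` reports,
by default, half that swing, i.e. the amplitude of the oscillating
component in the harmonic-waveform sense. That convention choice
deserves a paragraph.

The reference study reports the "amplitude of the pulsating component"
of a periodic signal: the artery throbs between the relaxed and dilated
states at 50–70 beats per minute and the photodiode current oscillates
between a maximum (relaxed) and a minimum (dilated). For a periodic
waveform that amplitude is conventionally half the peak-to-peak
excursion. Empirically, our full-swing values exceed the reference
depth-profile values by a uniform factor of 2.1 ± 0.1 at every depth
spanning a sixty-fold amplitude range, while reproducing the shape and
ordering of the profile exactly; the half-swing values agree within
roughly 10% everywhere the reference statistics are sound. A uniform
factor of two across such a range is a reporting convention, not a
transport effect, so the half-swing reading is the default and the full
swing remains available via `convention = "peak_to_peak"` (and is
always reported as `peak_to_peak_ppm`).

## Variance reduction: why perturbation reweighting

The 4% dilation changes the detected fraction by ~0.1–1 ppm while a
10^6-packet run determines the detected fraction only to ~5–10 ppm.
Independent runs per diameter are therefore hopeless at desk scale, and
even common random numbers (`method = "direct"`, the same per-packet
substreams across diameters) only help to the extent that detected
packets never touch the lumen.

The default (`method = "perturbation"`) removes the noise at its
source. One simulation of the *homogeneous* layered medium records, per
detected packet, the geometric path length and the collision count
inside every candidate artery cylinder (each depth and each diameter of
the sweep — pure geometry, since the medium is artery-free). The
detected fraction with a blood-filled artery of radius r then follows
by likelihood-ratio reweighting of the same packets:

    w -> w * (mu_s_blood / mu_s_host)^k * exp(-(mu_t_blood - mu_t_host) * l)

Because every material shares one anisotropy factor, no phase-function
correction appears and the ratio is the exact Radon–Nikodym derivative
of the blood-artery path measure with respect to the host-medium one:
the estimator is unbiased for any perturbation size (its variance, not
its mean, grows with the contrast). The unit tests verify it against
direct re-simulation. All diameters and all depths share one set of
packets, so a single baseline run yields the entire depth profile, and
the sweep-to-sweep differences that define the slope are estimated with
per-packet correlations taken into account: the slope standard error is
computed packetwise from the per-packet slope contributions, not from
the (strongly correlated) residuals of the five fitted points.

`perturbed_detection()` exposes the same machinery for a single
recorded artery region, e.g. to ask what a small change of blood
absorption would do to a recorded baseline without re-simulating.

The requirement that a candidate cylinder lie within a single layer is
checked (`method = "direct"` handles the general case); all reference
depths satisfy it.

## Numerical choices

- Coordinates: z is depth below the surface (z = 0), lengths in mm,
  coefficients converted from the published cm^-1 once, at
  construction.
- Artery depth refers to the cylinder *axis* (the symmetric reading of
  "artery at depth d"); the axis runs along y beneath the
  source–detector midpoint, where the photon banana is widest.
- Domain: 60 × 60 mm laterally, 60 mm deep; packets crossing the
  lateral or bottom walls are terminated as escaped. At 11 mm
  separation the far-field contribution lost this way is negligible
  compared with the tallies' statistical error.
- Boundary nudges of 1e-7 mm avoid re-intersecting the surface just
  crossed; a 10^6-step cap per packet (never reached in practice;
  reported as `n_lost`) guards against pathological geometry.
- The voxelized mode snaps material queries to 0.05 mm voxel centres
  and steps voxel-by-voxel, mirroring the reference discretisation; it
  agrees with the analytic mode within Monte Carlo error and is kept
  for cross-checking, since the analytic mode is faster and carries no
  discretisation bias.
- Saturated two-point fits report a residual sd of 0 (the interpolating
  line); degenerate designs (a single distinct diameter, a measured
  amplitude of zero in `compare_to_measurement()`) are rejected with
  errors.

## What the generator emulates — and what it does not

The synthetic configurations (`build_default_phantom()`,
`make_fixture()`) encode the study conditions: the published layer
structure, coefficients, artery depths (1.2, 2.5, 3.7, 5.3, 6.8, 9.6,
11.8 mm), the 0.4 mm relaxed diameter, the 4% dilation, 11 mm
separation and 7.5 mm^2 detector. The test fixtures
(`beer_lambert_slab`, `conservative_halfspace`, `invisible_artery`)
exist because they have closed-form or symmetry-forced answers.

Features of the physical phantom that the model deliberately omits: the
silicone tube wall around each artery (its absorption and scattering
were neglected in the reference too), the presence of the *other*
static arteries while one is pressurised (the model embeds exactly one
artery; shadowing by the remaining cylinders plausibly accounts for
part of the residual ~10% differences at intermediate depths), the real
LED's ±55° emission cone (available as `source_spec(type = "cone")`;
the reference simulation injected vertically, which is the default
here), surface curvature, and any wavelength dependence beyond the
single 910 nm property set. Passing tests therefore demonstrate
agreement with the reference *simulation* conditions, not with every
aspect of the physical phantom.

## Problem sizes

The packaged analyses run at desk scale by design: the full-fidelity
reference used 10^7 packets per diameter and depth (3.5 × 10^8 total),
where the shared-baseline perturbation route needs one run of a few
million packets for the entire profile. The shipped acceptance script
uses 6 × 10^6 packets (amplitude standard errors of ~0.02 ppm at
shallow depths); the test suite uses 10^6 for the profile and 10^4–10^5
for the property checks. The deepest profile point (9.6 mm) remains
statistically delicate at any desk scale — few detected packets cross
that artery — and its reference value, at 10^7 packets with ~3 ppm
detection noise, is itself likely noise-dominated (the reference
discards its 11.8 mm entry for exactly that reason).

## A worked profile

```{r profile, eval = FALSE}
profile <- depth_profile(photons = 1e6, seed = 1)
print(profile)
plot(profile)
write_profile_csv(profile, "profile.csv")
```

At this packet count the run takes a couple of minutes and reproduces
the characteristic non-monotonic shape with its maximum at 2.5 mm: the
most superficial artery does *not* give the strongest signal, because
the detected photon paths dive below it on their way from source to
detector.

## Instrument arithmetic

The calibration module carries the instrument-side algebra of the
reference oximeter: least-significant-bit current
(`adc_lsb_current(5700e-9, 17)` = 43.49 pA, printed as 44 pA),
photodiode sensitivity by linear regression of current on flux
(`sensitivity_from_points()`, 0.71 A/W in the reference calibration),
area-ratio flux scaling between the 92.16 mm^2 power-meter probe and
the 7.5 mm^2 photodiode, and the ppm normalisation to the 1.8 mW source
(`flux_to_ppm(0.46e-9, 1.8e-3)` = 0.256, printed as 0.26 ppm). One
published pair (44 pA = 61.25 pW) is inconsistent with the rounded
0.71 A/W (which gives 61.97 pW); the sensitivity implied by the pair,
0.7184 A/W, is surfaced as
`phantom_constants()$sensitivity_implied_A_per_W` and never silently
substituted.

## Known limitations

- Single artery only; multi-cylinder shadowing is out of scope. This
  matters for one conclusion in particular: in the single-artery model
  the converged amplitudes at 2.5 mm and 3.7 mm are statistically tied
  (equal within ~0.02 ppm), so the depth of maximum amplitude can come
  out as either of the two on a given seed. The reference model kept
  all seven arteries in place while sweeping one; the static arteries
  above 3.7 mm shadow it more strongly than the 2.5 mm artery is
  shadowed, which plausibly produces the clearer reference maximum at
  2.5 mm.
- One anisotropy factor across materials (true of the reference
  conditions; the perturbation machinery relies on it).
- No time-resolved transport, polarisation or fluorescence.
- The Fresnel mode applies index mismatch at the free surface only;
  internal layers are index-matched.
- Perturbation sweeps require the artery to sit within one layer;
  arteries straddling a layer boundary fall back to direct simulation.
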