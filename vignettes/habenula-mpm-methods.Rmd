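---
title: "Methods: synthetic multi-parameter mapping of the habenula"
author: "habmpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic multi-parameter mapping of the habenula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habmpm)
```

## Why a synthetic cohort

Multi-parameter mapping (MPM) characterises brain tissue through four
quantitative parameters: the longitudinal relaxation rate R1 (1/s), the
effective transverse relaxation rate R2* (1/s), proton density PD
(percent units, p.u.) and the magnetization-transfer saturation MTsat
(p.u.). Applying MPM to the habenula — an epithalamic nucleus of roughly
19 mm³ wedged between the mediodorsal thalamus and the third ventricle —
stresses every stage of a quantitative pipeline: with 0.8 mm isotropic
voxels the structure spans only ~38 voxels per side, partial-volume
effects dominate its boundary, and spatial normalisation cannot be
assumed to align it across subjects.

In-vivo cohort data of this kind are generally not shareable, so this
package builds the entire analysis chain on a *digital phantom cohort*
whose habenula tissue model is calibrated to published in-vivo 3T cohort
statistics (R1 = 0.86 ± 0.03 1/s, R2* = 19.11 ± 1.87 1/s,
PD = 76.21 ± 1.52 p.u., MTsat = 1.05 ± 0.08 p.u.; per-side volume
19.26 ± 2.03 mm³). The pipeline must then *recover* those calibration
values end to end, which turns every published number into a testable
recovery target rather than an unverifiable citation.

## The phantom

`build_template()` constructs a deterministic desk-scale geometry: a WM
ellipsoid shell, two thalamic GM blocks, a CSF slab for the third
ventricle between them, and two ellipsoidal habenulae abutting the
ventricle dorso-posteriorly. Habenula masks are realised by ranking
voxels by ellipsoid distance and keeping exactly
`round(volume / voxel_volume)` of them, so mask volumes are exact by
construction and ROI means of the truth maps equal the calibration
values identically.

`sample_subject()` derives each cohort member by

* a smooth random deformation (sum of Gaussian displacement bumps,
  maximum displacement `deformation_amplitude`, default 1.5 mm, stored
  with a fixed-point-iterated inverse and verified to round-trip within
  0.1 voxel);
* per-tissue parameter jitter drawn from the between-subject SDs (the
  habenula row uses the published cohort SDs directly; WM/GM/CSF use
  literature-typical 3T values chosen once — WM 1.10/21/69/1.90,
  thalamic GM 0.70/16/83/0.90, CSF 0.25/1.5/100/0 for
  R1, R2*, PD, MTsat);
* one habenula volume draw per subject, scaling both ellipsoids (left
  and right are therefore equal within a subject — a deliberate
  simplification; real cohorts show mild asymmetry);
* smooth multiplicative transmit (f_T in [0.9, 1.1]) and receive
  (c_RX in [0.7, 1.3]) fields built from low-frequency cosine modes.
  The mode wavelengths are kept at or above the field of view, matching
  the smoothness of real coil-sensitivity and B1 variations over a
  ~40 mm thalamic window; wigglier fields would make the 8 mm receive
  calibration unsolvable in principle, not just in practice.

Everything is a pure function of `(master_seed, subject_index)`.

The default grid is 48×64×48 at 0.8 mm — a thalamic field of view, not a
whole head. One consequence is accepted openly: the brain-normalised
habenula volume (habenula / brain, in %) is reported by the same
arithmetic as in a whole-head analysis but its numerical value is a few
×10⁻²% here instead of the ~8×10⁻³% a ~460 cm³ brain yields, simply
because the phantom brain is small. The normalised-volume *computation*
is exact and tested; its whole-head magnitude is not reproducible at
desk scale.

## Forward model

Each weighting w ∈ {T1w, PDw, MTw} is an RF- and gradient-spoiled
multi-echo 3D FLASH acquisition in steady state:

S_w(TE) = c_RX · A · sin(a_w) · (1 − d_w) (1 − E1) / (1 − (1 − d_w) cos(a_w) E1) · exp(−TE·R2*)

with E1 = exp(−TR·R1), a_w = f_T·α_w the transmit-scaled flip angle, and
d_w the fraction of longitudinal magnetisation removed per TR by the MT
pulse (d = 0 for T1w/PDw). The defaults are α = 21°/6°/6°, TR 25 ms,
echoes from 2.30 ms in 2.314 ms steps (so the sixth echo lands on
13.87 ms), 8 echoes for PDw/T1w and 6 for MTw. The published echo
description (2.30→13.87 ms "in steps of 2.30 ms") is internally
inconsistent with both endpoints, so the spacing is a documented,
configurable choice rather than verbatim.

Two modelling decisions deserve emphasis:

* **MT transmit dependence.** The saturation actually delivered at a
  voxel scales with the local transmit field,
  d = δ·(1 − 0.4 f_T)/(1 − 0.4). This is exactly the empirical
  dependence that the standard MTsat transmit-bias correction divides
  out; modelling it makes the corrected estimator consistent under the
  generator, and switching it off (`mt_transmit_model = "none"`)
  exposes the residual ±5% bias one would otherwise incur at
  f_T = 0.9/1.1. An estimator-correction and a generator must agree on
  the physics or the correction is noise.
* **Noise.** Magnitude images get Rician noise (magnitude of the
  complex signal plus independent Gaussian noise per quadrature
  channel); `noise_model = "gaussian"` is available for estimator
  oracles. The default level is derived from a target SNR of 100 on the
  mean brain signal of the first PD-weighted echo. The receive
  calibration pair receives 0.5% relative Gaussian noise.

The receive-calibration pair emulates the array/body-coil scans: the
true receive field sampled on an 8 mm grid plus a unit-field companion,
with a two-voxel margin beyond the imaging FOV (as real calibration
scans cover more than the high-resolution volume; without the margin,
upsampling would extrapolate at the brain edge and corrupt the PD
calibration by several percent).

## Estimation

`estatics_fit()` solves, per voxel, the joint log-linear model
ln S_w(TE) = ln S_w(0) − R2*·TE with one shared decay across all echo
trains and one intercept per weighting — pooled ordinary least squares
with a closed-form solution, clamping negative decays to zero and
masking non-positive signals. It is tested to agree with a generic
per-voxel least-squares solver to 1e−10.

`compute_r1()` and `compute_amplitude()` apply the dual-flip-angle
rational approximations

R1 = ½ (S_T1 a_T1/TR − S_PD a_PD/TR) / (S_PD/a_PD − S_T1/a_T1),
A = S_PD S_T1 (TR a_T1/a_PD − TR a_PD/a_T1) / (S_T1 TR a_T1 − S_PD TR a_PD)

with B1-corrected angles a = f_T·α. Against the exact signal equation
the bias is below 2% for R1 ∈ [0.5, 1.5] 1/s at the default protocol
(established by forward-model oracles before freezing the test bounds).

`compute_pd()` removes the receive field (clamped tricubic upsampling of
the calibration ratio) and applies the toolbox convention of scaling PD
so that the WM-mask mean equals 69 p.u. — a convention, recorded in
provenance and configurable; the phantom's WM truth uses the same 69 so
the convention is self-consistent here.

`compute_mtsat()` computes δ = (A a_MT/S_MT − 1) R1 TR − a_MT²/2 and the
empirical transmit-bias correction δ·(1 − 0.4)/(1 − 0.4 f_T), reported
×100 in p.u.; bias ≤ 3% for δ ∈ (0, 0.02]. Whether a given study applied
the correction is rarely stated; it is on by default and switchable
(`b1_correction = FALSE`).

## Native-space analysis

The manual-delineation workflow is emulated structurally: ground-truth
masks replace hand drawing (no rater model is attempted), but the AC–PC
machinery is implemented because the published workflow computes
statistics on masks that made a reorientation round-trip. The
convention is fixed as: AC–PC midpoint to the origin, AC→PC direction
onto −y, minimal rotation. A property test bounds the statistical cost
of the nearest-neighbour round-trip at <2% on ROI means;
`habmpm_config(acpc_roundtrip = TRUE)` enables it in the pipeline,
while recovery targets use the masks directly.

ROI statistics use the population SD (divide by n; configurable). CNR
is exactly (mean(habenula) − mean(surround GM)) / SD(habenula) — the
noise term uses the habenula SD only, as published, although pooling
both ROIs would be the textbook choice. The surrounding-GM ROI is the
one-voxel "spherical" dilation of the habenula minus the habenula,
intersected with GM probability > 0.9; a radius-1 Euclidean ball on the
voxel lattice contains only face neighbours, so the default structuring
element is 6-connected (26-connected available). The brain mask for
normalised volume reads "WM, GM or CSF probability > 0.9" as the summed
probability exceeding 0.9 (per-class union implemented as an
alternative), since a three-way tissue mixture can be certain brain
without any single class crossing 0.9.

Because the phantom assigns each tissue a single value per subject,
within-ROI variance is almost purely noise-driven, so synthetic CNR
magnitudes are much larger than in vivo; only the *ordering* (R1 the
highest signed CNR, PD the only negative map) and its stability are
meaningful comparisons, and only those are asserted. In particular the
phantom's PD maps are cleaner than real ones (no residual receive-field
error), so the *magnitude* of the negative PD contrast can rival R1's —
in vivo it does not, but that gap is noise structure the phantom
deliberately does not model.

## Group-space analysis

Nonlinear registration is not re-estimated: each subject's ground-truth
deformation is known, and registration error is modelled as a seeded
random rigid perturbation (translation SD 0.4 mm per axis) composed
with it. This reproduces the phenomenon of interest — imperfect overlap
of a 19 mm³ structure across subjects — without simulating any
particular registration algorithm's internals. Maps are interpolated
trilinearly, masks nearest-neighbour and then carried as weight images;
both are smoothed with an isotropic Gaussian (0.8 mm FWHM by default,
reading the published "0.8 mm³ kernel" as FWHM).

The probability atlas is the voxelwise mean of the warped mask weights.
With zero misalignment and no smoothing its maximum is exactly 1 (every
subject covers the core); with 0.4 mm misalignment the maximum drops
below 1, qualitatively matching the published finding that no voxel was
habenula in all 26 participants (maximum 0.77). No attempt is made to
match 0.77 numerically — it depends on real anatomy and real
registration error.

The threshold sweep re-binarises the atlas at thresholds 0.05–0.95
(step 0.05; the published grid is not stated), recording ROI volume
(non-increasing by construction) and the CNR of each cohort-average map
against a fixed GM ROI (ring around the atlas support ∩ average
GM > 0.9). Empty-ROI thresholds are recorded as missing. On the
calibrated cohort R1 tops the CNR curves and CNR rises with threshold,
asserted as a Spearman trend rather than pointwise monotonicity.

## Numerical choices and degenerate inputs

* TE/TR are carried in ms in protocols and sidecars and converted to
  seconds inside every estimator, so all rates are 1/s.
* Voxels failing any stage (non-positive signal, degenerate
  denominator, receive estimate ≤ 0, MTsat outside −0.5..10 p.u.) are
  masked NA and counted, never filled.
* Interpolation snaps coordinates within 1e−9 of a voxel centre so
  identity resampling is bit-exact; Catmull-Rom cubic uses clamped
  borders; trilinear/nearest treat outside as zero.
* Deformation inversion iterates x ← y − D(x) (a contraction for the
  amplitudes and 7 mm bump widths used) and every subject's field is
  verified to round-trip within 0.1 voxel, with seeded redraws on
  failure.
* Ties in the exact-count habenula selection break deterministically by
  voxel index.

## Problem sizes and determinism

The shipped analyses run at the 48×64×48 desk-scale grid: the full
26-subject recovery cohort (simulation, fitting, ROI analysis) takes a
few minutes on one core; property tests use single subjects or small
cohorts (4–8). The entire pipeline is reproducible from
`(config, master_seed)`; per-subject seeds are derived deterministically
and all tabular outputs are byte-stable across reruns.

## What passing tests do and do not show

The phantom validates the *estimation and analysis machinery*: equation
consistency, unit discipline, ROI and atlas logic, and the qualitative
structure of the published results (CNR ordering, imperfect atlas
overlap, threshold-sweep behaviour). It does not model anatomy beyond
labelled geometry, rater variability, motion, GRAPPA reconstruction,
imperfect spoiling, segmentation error (tissue probabilities are truth),
or a real registration algorithm — so passing tests say nothing about
those failure modes in vivo. Published group-space numbers that depend
on real anatomy (maximum probability 0.77, 20.2 mm³ at threshold 0.3,
normalised volume 8.3×10⁻³%) are deliberately not targets.

One fragility is worth stating explicitly. Cohort-mean recovery of the
habenula calibration values is checked at a few-percent tolerance, but
two effects each contribute about half of such a budget for MTsat: the
rational-approximation estimator bias (≈ +1.5% at δ = 0.0105) and the
sampling error of 26 between-subject jitter draws at the published SD
(0.08/√26 ≈ 1.5% of the mean). A given cohort realisation can therefore
land marginally outside a 3% band around the calibration value without
any implementation defect — the per-subject recovery bias stays inside
its documented bound. The jitter SDs are part of the emulated study
conditions and are not shrunk to make cohort means look tighter.

## A short example

```{r example, eval = FALSE}
cfg <- habmpm_config(spec = phantom_spec(cohort_size = 8))
report <- run_all(cfg, out_dir = "habmpm_demo")
report            # cohort summary: map means, volumes, CNR ranking, atlas
plot(report$sweep)
```
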