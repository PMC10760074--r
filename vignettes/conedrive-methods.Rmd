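---
title: "Measuring cone-driven post-retinal responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cone-driven post-retinal responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`conedrive` implements the computational chain used to measure
cone-driven responses beyond the retina in the dog: spectral stimulus
design by silent substitution, pupillometry response estimation, and
BOLD fMRI forward-model fitting, together with a synthetic-data
generator that emulates wild-type and retinal-degeneration disease
models. This vignette explains each model, its assumptions, the
parameters that matter, and the design choices made where the design
was genuinely open.

## Photoreceptor model

Canine vision is dichromatic. We model four spectral mechanisms — the
L/M ("L") cone, the S cone, rhodopsin, and melanopsin — with peak
sensitivities at 555, 429, 506 and 480 nm. Spectral sensitivities are
generated from the standard A1 visual-pigment nomogram: a
log-exponential-sum alpha band plus a Gaussian beta band, evaluated at
`x = lambda_max / lambda` and peak-normalized. The template constants
are stored as data (`pigment_template_constants()`) and can be
overridden, keeping the provenance of every curve explicit.

Pre-receptoral filtering by the canine crystalline lens multiplies each
sensitivity pointwise. The measured canine curve is not tabulated in
accessible form, so the shipped default is parametric: unit
transmittance in the long-wave visible with a sigmoidal short-wave
cutoff, half-height 400 nm and slope 10 nm. A measured curve can be
supplied as a `wavelength_nm,value` CSV. All shipped results use the
parametric default so they are self-contained. Filtering deliberately
does **not** re-normalize the curve: absorption changes the effective
peak, and excitation ratios must reflect that.

Excitation is the usual inner-product receptor model,
`e_p = sum_l S_p(l) Phi(l) dl`, on a 380–780 nm grid at 2 nm
(rectangular summation; refinement invariance is tested). Contrast of a
bipolar modulation between arms `Phi+` and `Phi-` around a background is
reported in two conventions, because printed stimulus contrasts in the
field are sometimes one and sometimes the other:

* bipolar Weber contrast `(e+ - e-) / (2 e_bg)` (the package default),
* unipolar contrast of each arm against the background.

Melanopsin is treated as an ordinary pigment; its slow intrinsic
kinetics matter for response interpretation, not for contrast
arithmetic. Photopigment bleaching and rod saturation dynamics are out
of scope.

## Silent-substitution stimulus design

The stimulus device is a multiprimary light engine,
`Phi(w) = nu (P w + Phi_0)` for settings `w` in `[0,1]^n`. The shipped
synthetic device has 56 Gaussian primaries spanning 400–700 nm with
16 nm FWHM and equal peak power — a stand-in for an unpublished
spectral synthesis engine; it is labelled synthetic throughout. The
neutral-density factor `nu` scales luminance only and cancels in every
contrast.

A modulation is a symmetric settings pair `w0 +/- d` around the half-on
background (`w0 = 0.5`). Because the background is fixed, every bipolar
contrast is *linear* in `d`, so the design problem — silence some
mechanisms, maximize the minimum contrast on the targeted ones — is a
max–min linear program over the gamut box intersected with the
silencing null space. `design_modulation()` solves it with a seeded
multi-start projected-gradient ascent of a smooth (log-sum-exp) min
surrogate inside the null space, followed by alternating projections
onto the box and the null space, plus two deterministic warm starts.
The max–min criterion and the silencing tolerance (default contrast
1e-3) are package choices; the search is deterministic under its seed,
and a property test verifies it dominates 10,000 random feasible
modulations on a toy device. In practice silenced contrasts come out at
numerical precision (~1e-16), far below the tolerance, and the default
L+S design reaches ~45% contrast on both cone classes while the
light-flux design reaches 100% on all four mechanisms.

Temporal profiles follow the two experimental protocols: a 1/6 Hz
sinusoidal exchange over 360 s for pupillometry, and 12 s flicker
blocks alternating with 12 s of steady background over 432 s for fMRI,
with 1.5 s half-cosine onset/offset windows and flicker rates of 32, 4
and 16 Hz for the L+S, L−S and light-flux stimuli.
`validate_modulation()` propagates multiplicative primary-output noise
through the contrast calculation to bound the inadvertent contrast a
calibration error could produce.

## Pupillometry

Pupil border points are fit with a direct least-squares conic
(numerically stabilized scatter-matrix decomposition), preceded by a
robust radial prefilter (median center, MAD of radial distance) and
followed by iterative trimming that sheds at most the worst 10% of
points per refit. The prefilter matters: a single least-squares conic
can be pulled so far by an eyelash or Purkinje-reflex cluster that the
inliers look worse than the outliers. A frame is "poor" when fewer than
5 border points survive or the fit rmse exceeds 2 px (the source video
software's criterion is not quantified; 2 px is our documented choice).
Acquisitions with more than 50% poor frames are excluded — strictly
more, so exactly half poor is retained.

Ellipse area over time, expressed as percent change about the
acquisition mean (re-meaned to zero after masking), is regressed on an
intercept, sine and cosine at the stimulation frequency. Amplitude is
`sqrt(bs^2 + bc^2)`; phase is `atan2(bc, bs)` in (−pi, pi] — the polar
convention is arbitrary but fixed and documented. No drift regressors
are used by default. Uncertainty comes from an exhaustive bootstrap:
all multisets of the condition's acquisitions drawn with replacement
(35 for n = 4), each frame-wise averaged and refit; the SEM is the SD
of the resampled amplitudes (and of phases after rotation to their
circular mean). The point estimate uses the unresampled average
("average-then-fit"); fitting each acquisition and averaging parameters
is also possible but is not the default, as averaging first suppresses
frame noise before the nonlinear amplitude transform.

## BOLD preprocessing

The pipeline starts from preprocessed-geometry volumes (bias
correction, skull stripping, distortion and motion correction, template
registration are upstream and out of scope) and applies, in order:

1. **Linear detrend**, per voxel, mean-preserving.
2. **Spike detection**, two-stage MAD rule: a voxel sample is an
   outlier when at least 6 raw MADs (no 1.4826 consistency constant)
   above the voxel's temporal median — one-sided, matching the
   upward-going arcing artifact, with a two-sided switch; a TR is
   flagged when its outlier-voxel count is at least 25 MADs above the
   median count. The count MAD is floored at one count (the counter's
   resolution): without the floor, near-null data whose counts are
   mostly zero would have MAD 0 and a degenerate threshold that flags
   every nonzero count. Each flagged TR gets an indicator confound.
3. **Motion confounds**: 6 rigid-body parameters expanded to 24
   (originals, backward-difference derivatives, squares of both),
   centered, reduced by PCA to the smallest set explaining 95% of
   variance.
4. **Confound regression**, per-voxel OLS with intercept, mean
   restored.
5. **Hemispheric mirror averaging**, `(v + flip_x(v))/2` about the
   volume's x midpoint (template space is assumed already symmetric;
   the registration between original and flipped images is identity
   here, a documented simplification). The result is exactly
   symmetric and the operation idempotent.

## BOLD forward model

For each stimulus type the 6 acquisitions (3 per stimulated eye) are
concatenated. Per voxel the model is a unit square wave over the 12 s
on/off blocks — the 1.5 s stimulus ramps are deliberately not in the
regressor; their effect is absorbed by the kernel — convolved, per
acquisition so nothing bleeds across boundaries, with a hemodynamic
kernel built from three unit-norm components: a canonical double-gamma,
its temporal derivative and its dispersion derivative (the basis is
user-replaceable via CSV). Three kernel weights are shared across
acquisitions; one amplitude (beta, % signal change) is free per
acquisition.

The model is bilinear in (weights, betas), so the L2 search alternates
exact least-squares updates of each given the other — deterministic,
testable, and convergent to a stationary point. The beta–kernel scale
degeneracy is resolved by renormalizing the kernel's dominant extremum
to +1 each iteration; betas then carry sign and magnitude, and negative
(e.g. thalamic) responses are representable.

Two statistical details matter for unbiased amplitudes:

* Data are centered per acquisition (a per-acquisition intercept).
* After sequential confound regression, the task regressors are
  residualized against the *same* per-acquisition confound set
  (including the detrending line) inside the fitter. By the
  Frisch–Waugh–Lovell theorem this makes the sequential pipeline
  exactly equivalent to a joint GLM of task plus nuisance; without it,
  chance overlap between confounds and the task span shrinks
  amplitudes by 1–2% systematically.

`r2_map()` computes the coefficient of determination of the fit to the
across-acquisition average series; zero-variance voxels get 0 with a
degenerate flag. `define_rois()` thresholds and binarizes the map
(default: top 0.5% of positive values, minimum component size 10 —
the threshold is unstated in the source protocol and configurable),
labels 26-connected components and names them by decreasing size
(cortex, then LGN). The reference in-vivo ROI sizes (143 and 27 voxels)
are metadata, not reproduced. `roi_response()` averages betas over ROI
voxels per acquisition, then reports mean and SEM (SD/sqrt(n)) across
acquisitions.

## Synthetic data generator

The generator is first-class, tested code; it produces every input the
pipeline consumes, deterministically under a seed.

**Disease presets** are multiplicative mechanism gains, nominal by
necessity (the disease literature is qualitative): WT 1/1/1/1,
RCD1 1/1/0.05/1 (severe rod loss, cones spared), XLPRA2 0.4/0.4/0.3/1,
CRD2 0/0/0.05/1 (near-complete cone loss), and CRD2_treated with the
treated (left) eye restored and the fellow eye at the CRD2 baseline.

**Pupil sessions** (12 acquisitions: L+S, Rod+Mel, light flux per eye
order, 4 per condition) synthesize percent area change as a 1/6 Hz
sinusoid whose amplitude is the light-flux amplitude (default 8% in WT,
a mid-range value for consensual responses under photopic backgrounds)
scaled by mechanism drive: `sum_m eff_m gain_m |C_m|`, with efficacy
(L 1, S 1, rod 0.05, mel 0.02) encoding rod saturation at photopic
levels and melanopsin's sluggishness at 1/6 Hz. The `amplitude_ratio`
argument pins the generative L+S : light-flux ratio directly when a
session must embody a known ratio. Noise is 1/f (pink, default SD 2% of
mean area) — chosen over white noise because pupil records are strongly
low-frequency — plus Poisson blink events masking 0.3 s windows, which
stress the masked regression.

**BOLD sessions** place HRF-convolved block responses (zero-meaned
within acquisition: amplitudes are % signal change as measured,
relative to the acquisition mean) in mirror-symmetric cortical
(positive) and LGN (negative, reflecting the observed sign reversal
under anesthesia) regions, over a 1000-unit baseline with AR(1) noise
(rho 0.3), per-voxel linear drift, scheduled single-TR global spikes
(the arcing morphology), and motion-correlated nuisance driven by
quasi-periodic cardiopulmonary motion parameters. Ventilation
frequencies whose TR-aliased image lands on the stimulus fundamental or
its second harmonic are excluded, as the experimental protocol itself
avoided respiratory rates at stimulus harmonics. Default volumes are
24 x 24 x 16 x 144 per acquisition (desk scale), TR 3 s, 6
acquisitions.

What the generator does **not** emulate: anatomically realistic canine
geometry, spatially correlated physiological noise, registration error,
partial-volume effects, or session-to-session animal variability.
Passing recovery tests therefore demonstrates correctness of the
estimation chain under the stated noise model, not robustness to every
property of real data.

## Numerical choices and degenerate inputs

* Wavelength grid 380–780 nm / 2 nm; halving the step changes
  excitations by < 0.1% for smooth spectra (tested).
* Optimizer: 20 seeded starts, L-BFGS-B on the smooth surrogate
  (sharpness 100, then 3000), 400 alternating projections; silencing
  tolerance 1e-3 contrast.
* Forward model: convergence when the total SSE changes by < 1e-8 of
  the total SST, max 200 alternations; flat voxels are masked out and
  reported as NA; R² of a zero-variance voxel is 0.
* Spike rule degeneracies: constant series produce no flags; the count
  MAD is floored at one count.
* Ellipse fits need >= 5 points; collinear points raise a degenerate-fit
  error.
* Bootstrap with identical acquisitions yields SEM exactly 0.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run at desk scale: the full
synthetic study completes in well under ten minutes on one CPU. The
pupil ratio recovery uses 100 seeded sessions (4 acquisitions per
condition, 360 s at 60 Hz); the treated-eye recovery uses 50 seeded
BOLD sessions at the default volume; Monte-Carlo property checks (spike
specificity/sensitivity) use 25 seeds on reduced volumes, where the
binomial bounds are still conclusive.

## Known limitations

* The lens default and device primaries are parametric stand-ins;
  absolute excitations (and the luminance metadata) are therefore
  nominal, though contrasts are insensitive to uniform scalings.
* The alternating L2 fit finds a stationary point; with the canonical
  start this has been adequate in all tested regimes, but a
  pathological voxel could in principle converge to a local optimum
  (flagged voxels carry their best-found parameters).
* Phase SEMs use the circular SD, which is biased for very dispersed
  phase distributions (low-amplitude conditions).
* ROI labelling by size assumes the cortical region is larger than the
  LGN, which holds for the shipped geometry and the in-vivo reference
  sizes.
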