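---
title: "Methods: CBCT dose accumulation on synthetic pelvis phantoms"
author: "doseAccum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CBCT dose accumulation on synthetic pelvis phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In fractionated pelvic radiotherapy the plan is designed once, on a
planning CT (pCT), but delivered over five to six weeks to an anatomy that
changes daily — most visibly the bladder and rectum, whose filling can
differ from the planning scan by factors of two or three. Weekly cone-beam
CT (CBCT) verification scans show the anatomy of the day, but they have a
limited field of view (here 465 mm transverse diameter and 160 mm
longitudinally), degraded soft-tissue contrast, noise and shading, so they
cannot directly replace the pCT for dose calculation.

`doseAccum` implements the full workflow that turns those weekly CBCTs
into an estimate of the *cumulative* dose actually absorbed by each organ:

1. **Merged CBCT (mCBCT).** Each weekly CBCT is deformably stitched into
   the pCT: within the CBCT body (the *limiting contour*) the CBCT voxels
   are kept; outside it the pCT, deformed to match the CBCT anatomy,
   supplies the missing anatomy. The result is a full-FOV volume on the
   pCT grid.
2. **Two cumulative-dose pathways.** The *recalculated* dose (ecD) runs
   the frozen treatment plan on each mCBCT, so it responds to the anatomy
   of the day. The *deformed* dose (mdD) instead maps the planning dose
   through the registration displacement field. Comparing the two is the
   scientific point of the workflow: when they agree, dose warping is an
   acceptable shortcut; where they disagree, the anatomy change genuinely
   altered the delivered dose.
3. **Spatial accumulation.** Week 1 is the reference anatomy. Every other
   week's dose is deformed onto it and the five weekly doses are summed,
   each weighted by the five fractions it stands for, giving 25-fraction
   cumulative doses for both pathways.
4. **Evaluation.** Geometric quality is scored with the Dice similarity
   coefficient (DSC) and landmark target registration error (TRE);
   dosimetric agreement with DVH metrics (D2cc, Dmax, Dmean, D50, D90,
   D98, V45), signed percent differences banded at ±2% and ±5%, exact
   Wilcoxon signed-rank tests, and 3D gamma analysis (3%/2 mm, 20%
   low-dose threshold, 90% pass criterion).

Because clinical image sets cannot be redistributed, every stage is
exercised on a synthetic deformable pelvis phantom with *analytic* ground
truth, and the per-patient summary tables of a published 20-patient study
are shipped as plain-text fixtures so that its reported summary statistics
(within-threshold counts, mean gamma pass rates) can be recomputed
exactly from printed per-patient values.

## The phantom and what it emulates

`phantomConfig()` / `generatePlanningCT()` build a voxelized pelvis:
an elliptical body with a fat rind and muscle interior, a bony ring
(cortical shell, trabecular core), a bladder ellipsoid scaled to a target
volume, a rectum tube, a uterus/cervix target, and the PTV as an isotropic
expansion of the target. HU values default to ROI measurements from a real
planning CT (bladder 11.4, muscle 46.9, fat −97.9, cortical bone 851.0,
trabecular bone 143.1 HU); the default bladder (89 cc) and rectum (~70 cc)
sit inside the 27–320 cc and 42–177 cc ranges observed across the study's
20 patients.

The weekly deformation is deliberately simple and fully analytic: a radial
bladder expansion/contraction about the bladder centre — uniform scaling
inside the bladder core, Gaussian falloff (default 45 mm) beyond —
composed with a small rigid setup shift. The map, its inverse (by
monotone 1-D bisection) and its Jacobian are available in closed form, so
warped masks, displaced landmarks and volume changes have exact reference
values. Inside the core a weekly `bladder_scale` of *k* multiplies the
bladder volume by exactly *k*. The default schedule (scales 1.6, 1.3,
0.75, 1.45, 0.85 with shifts of a few mm and two rectal gas pockets) keeps
peak displacements near 10 mm — large enough to matter dosimetrically,
small enough to remain diffeomorphic, and of the same character (bladder
filling dominating week-to-week change) as the clinical series, whose
printed volume changes are nevertheless far wilder (−100% to +344%).

CBCT degradation is an image-domain model, not projection physics: a
multiplicative contrast scale (0.9), a radial quadratic shading field
(25 HU), additive Gaussian noise (15 HU), and field-of-view truncation to
a cylinder (465 mm diameter × 160 mm, padded with −1000 HU). What the
phantom does *not* emulate: scatter and beam-hardening streaks, motion
artifacts, couch structures, sliding interfaces, and genuinely new
anatomy (gas that appears in one scan only is painted in intensity but
does not alter the deformation). Passing tests on the phantom therefore
demonstrate the *mechanics* of the pipeline against known truth — they do
not certify registration accuracy on clinical CBCT, where contrast is
worse and deformation is not a smooth radial field.

## The registration engine

The commercial engine used clinically is proprietary; `doseAccum`
implements a transparent substitute of the same class: rigid
initialization followed by multi-resolution, demons-style free-form
registration.

**Rigid stage.** Normalized cross-correlation over the fixed image,
maximized by a deterministic coordinate sweep plus per-axis line
refinement. By default the metric is restricted to bony anatomy (voxels
above 200 HU, dilated 6 mm so the metric sees bone *edges*): bone moves
rigidly, whereas soft-tissue deformation (a filling bladder) otherwise
biases the fit by several millimetres. If the bone region is degenerate
(numerically constant), the full mask is used instead.

**Deformable stage.** Classic demons forces with a symmetric
(fixed + warped-moving) gradient, Gaussian-smoothed update (fluid-like)
and total field (elastic-like), on a four-level image pyramid. Intensity
mismatch between CT and CBCT is handled by a 7-knot quantile match of the
moving onto the fixed foreground with linearly extrapolated tails; a
local-normalization (LNCC-style) mode is available for multiplicative
intensity fields. Two details matter more than any parameter:

* *The registration disregards data beyond the limiting contour.* Both
  images are blanked to background outside the (dilated) restriction
  region and wherever the fixed image carries FOV padding. Without this,
  the FOV cut edge is the strongest "feature" in the image and the
  registration aligns it instead of the anatomy.
* *Coarse pyramid masks are strict.* A downsampled block receives updates
  only if all its fine voxels lie inside the restriction; boundary blocks
  mix out-of-region intensities and otherwise drive a drift that fine
  levels cannot undo (homogeneous interiors give them no gradient to
  correct against).

**Defaults and why.** `registrationParams()` defaults to 4 levels,
150/150/100/80 iterations (coarse to fine), update smoothing 10 mm, field
smoothing 2 mm, maximum step 2 mm, stopping when the mean-squared
intensity difference improves by less than 1e−6 over 15 iterations. These
were chosen on the default phantom battery: smaller update kernels chase
noise in the 13–22 HU-contrast soft tissue; larger ones suppress the
bladder-edge forces the recovery depends on. On that battery the engine
achieves mean bladder DSC ≈ 0.90 (per-week minimum ≈ 0.84), mean DSC over
bladder/rectum/target ≈ 0.85, mean landmark TRE ≈ 2.9 mm at 5×5×4 mm
voxels, with positive Jacobian on >99.9% of body voxels. The low-contrast
uterus/cervix target (13 HU against muscle, under 15 HU noise) is the
consistent weak spot — deliberately so, since that is exactly the regime
in which the clinical study needed physician-adjusted contours. For the
same reason the landmark-recovery test asserts a 2× improvement over
rigid-only where the image supports it (the bladder-surface fiducial) and
only strict improvement of the mean over all fiducials.

**Field algebra.** Displacement fields use the pull-back convention in mm
on the fixed grid (the output voxel at x samples the input at x + u(x)).
Composition interpolates the second field at the displaced positions;
inversion is the standard fixed-point iteration with a residual report;
the Jacobian uses central differences of I + ∇u. Masks warp by linear
interpolation thresholded at 0.5, which biases curved-organ volumes less
than nearest-neighbour sampling.

## The dose engine

The clinical algorithm (AAA) cannot be reimplemented from its public
description; `computeDose()` is a deliberately simplified, *anatomy-
responsive* stand-in with closed-form testability — the property the
recalculated-dose pathway exists to exercise. Per beam of a four-field box
(gantry 0/90/180/270°): HU → relative density by a piecewise-linear
lookup (−1000 → 0.0, 0 → 1.0, 1000 → 1.6); water-equivalent depth (WED)
by ray sums along the beam axis; depth dose = linear build-up ramp over
the first 15 mm times exp(−0.005/mm · WED); lateral profile = a sigmoid of
the signed distance to the rectangular aperture (PTV projection + 7 mm
margin), width 6 mm. The normalization is frozen at planning so the
isocenter receives exactly the per-fraction prescription (1.8 Gy of the
45 Gy / 25-fraction regimen) on the pCT, and is never re-derived on later
anatomy — mirroring fixed monitor units. The constants are megavoltage-
like orders of magnitude, not clinical beam data.

Dose deformation is plain trilinear pull-back resampling (0 Gy outside),
without Jacobian energy weighting; the co-warping test (DVH of warped
dose over warped mask vs original over original) bounds the distortion
this introduces to ~2% on Dmean at phantom deformation strengths.
Accumulation is the weighted sum of deformed weekly doses with 5 fractions
per weekly CBCT.

## Evaluation choices

* **DVH metrics** use the voxel-boundary convention: voxel doses sorted
  descending, Dx / D2cc read at the first voxel whose cumulative volume
  reaches the requested volume. V45 is reported in cc (the unit is
  ambiguous in the source material; percent differences are unaffected
  only for fixed structure volume, hence the explicit choice).
* **Banding** of |percent difference| is inclusive downward: ≤2 → first
  band, ≤5 → second, else third. This is the unique total rule consistent
  with the published within-threshold counts.
* **Wilcoxon signed-rank** drops zero differences, mid-ranks ties, and
  computes the exact null by the shift algorithm (generating polynomial
  over realized ranks — equivalent to enumerating all sign patterns) for
  n ≤ 25, with a tie-corrected normal approximation beyond. The base-R
  test is not used because it abandons exactness in the presence of any
  tie or zero, while the fixture data are printed to one decimal and tie
  frequently; it serves instead as an independent cross-check on tie-free
  cases.
* **Gamma analysis** normalizes globally to the reference maximum,
  evaluates reference voxels inside the mask at ≥20% of that maximum, and
  minimizes over a lattice of step dist/10 within radius 3×dist with
  trilinear interpolation of the evaluated dose. The search proceeds over
  shells of increasing radius and drops a voxel once the spatial term
  alone exceeds its running minimum — exact for the lattice, typically
  ~10× faster than the dense search it provably equals (an exhaustive
  oracle is part of the test suite).

## Degenerate inputs and tie-breaks

Organ placement is checked for pairwise overlap (error naming the
colliding pair); a weekly deformation whose analytic Jacobian is not
positive everywhere is rejected ("deformation too strong"); D2cc on a
structure of ≤2 cc is an error; empty-vs-empty masks have DSC 1, empty vs
non-empty 0; two equal-band boundaries resolve downward; the DSC category
boundaries (0.6, 0.9) both fall in "medium".

## Problem sizes

The shipped tests and the acceptance script run the phantom battery at
the default 96×96×48 grid (5×5×4 mm — ~0.44 M voxels, five weekly
registrations, ≈4 min on one CPU core) and the identity-consistency
pipeline at the same size (≈3 min); unit tests use a coarser 48×48×26 /
8 mm phantom. These sizes were chosen so the whole suite exercises every
stage at realistic anatomy scales while remaining convenient to run
routinely; halving the spacing quadruples cost without changing any
qualitative behaviour we tested.

## Known limitations

* The registration is intensity-driven; in 10–20 HU-contrast regions it
  under-recovers deformation (target DSC ~0.7–0.85 on the battery). This
  is a faithful, not incidental, limitation — it reproduces why DIR
  contours need physician review.
* The dose engine is not a clinical algorithm; absolute OAR doses are
  internally consistent, not clinically meaningful.
* The phantom's deformation family is smooth and radial; sliding organs,
  independent rectum motion and newly appearing anatomy are out of scope.
* Dose warping without Jacobian weighting does not conserve integral dose
  under volume change; the two-pathway comparison is the designed
  safeguard, not a correction.
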