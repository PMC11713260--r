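# doseAccum

Cumulative-dose evaluation for fractionated pelvic radiotherapy from
weekly cone-beam CT (CBCT), built so that every stage is testable against
analytic ground truth.

## The problem

A pelvic radiotherapy plan (45 Gy in 25 fractions of 1.8 Gy) is designed
once on a planning CT (pCT), but bladder and rectum filling change from
week to week, so the delivered dose can differ from the planned one.
Weekly verification CBCTs show the anatomy of the day but have a limited
field of view and degraded HU fidelity. `doseAccum` implements the full
workflow that estimates the dose actually accumulated by each organ:

1. **Merged CBCT** — each weekly CBCT is deformably stitched into the pCT
   through a *limiting contour* (the CBCT body): CBCT voxels inside,
   deformed pCT outside, a linear blend between.
2. **Two cumulative-dose pathways** — the *recalculated* dose `ecD`
   (frozen plan re-run on each merged CBCT by a simplified
   anatomy-responsive four-field engine) and the *deformed* dose `mdD`
   (planning dose mapped through the registration displacement field).
3. **Spatial accumulation** — weeks 2–5 deformed onto the week-1
   reference and summed, 5 fractions per weekly CBCT:
   `ΣD = Σᵢ wᵢ · (Dᵢ ∘ φᵢ→ref)`.
4. **Evaluation** — Dice similarity `DSC = 2|A∩B|/(|A|+|B|)` and landmark
   target registration error (TRE) for geometry; DVH metrics (D2cc, Dmax,
   Dmean, D50, D90, D98, V45), signed percent differences banded at ±2% /
   ±5%, exact Wilcoxon signed-rank tests, and 3D gamma analysis
   (3%/2 mm, 20% threshold, 90% pass criterion) for dose.

The registration engine is a multi-resolution demons-style free-form
registration (rigid bony-anatomy initialization, quantile intensity
matching, Gaussian fluid/elastic regularisation) with full displacement-
field algebra: apply, compose, invert, Jacobian QA.

Because clinical image sets cannot be redistributed, the package
generates synthetic deformable pelvis phantoms whose weekly deformations
are closed-form (radial bladder expansion with Gaussian falloff composed
with a rigid shift), so ground-truth masks, landmarks, inverse fields and
Jacobians are exact. The per-patient summary tables of a published
20-patient cervical-cancer study are shipped as plain-text fixtures
(`loadStudyTable()`), letting its reported summary statistics be
recomputed exactly.

## Worked example

```r
library(doseAccum)

## published per-patient tables: recompute summary statistics exactly
t3 <- loadStudyTable("T3")   # bladder DVH-metric percent differences
t6 <- loadStudyTable("T6")   # per-patient gamma pass rates
countWithin(t3, c("D2cc_ecd_pd", "D2cc_mdd_pd"), 5)   # 19 (of 20)
round(mean(t6$bladder_pd_ecd))                        # 94 (%)
wilcoxonSignedRank(t3$D2cc_ecd_pd, rep(0, 20))$p      # 0.0080

## a coarse synthetic pelvis with five deformed, degraded weekly CBCTs
cfg <- phantomConfig(grid_shape = c(48L, 48L, 26L), spacing_mm = c(8, 8, 8),
                     cbct_fov = c(transverse_mm = 380, longitudinal_mm = 160))
p   <- generatePlanningCT(cfg)
ser <- generateWeeklySeries(p$image, p$structures, cfg)
p$structures
#> StructureSet <ground_truth>
#>   grid: 48 x 48 x 26, spacing 8 x 8 x 8 mm, origin -188, -188, -100 mm
#>   body        12300.3 cc
#>   bones         933.9 cc
#>   bladder        91.1 cc
#>   rectum         98.3 cc
#>   ...

plan <- planNormalize(generatePlan(p$structures), p$image)
pd   <- computeDose(p$image, plan, role = "pD")      # 1.8 Gy/fraction at iso
blad <- structureMask(p$structures, "bladder")
dvhMetric(pd, blad, "D2cc")                           # 1.07 Gy per fraction
volumeStats(lapply(ser$truth$masks, structureMask, name = "bladder"),
            blad, gridSpacing(p$image))$percent_diff[1]   # +53 (%) in week 1
```

The numbers mean: 19 of the study's 20 patients kept the bladder D2cc of
both cumulative pathways within 5% of the planning dose; the mean
planning-vs-recalculated gamma pass rate for bladder is 94%; on the
phantom, the hottest 2 cc of the bladder receives 1.07 Gy per 1.8 Gy
fraction and week 1 inflates the bladder by about half its planning
volume.

`runPipeline(phantomConfig())` executes the entire workflow (phantom →
registration → merge → contour propagation → ecD/mdD → accumulation →
evaluation) and returns the cumulative dose grids, the metric report and
the gamma results; `inst/cli/doseaccum.R` wraps it for shell use.

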