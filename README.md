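# lvatlas

Automated left-ventricular (LV) shape-atlas construction from cine cardiac
MRI, built for the kind of legacy gradient-echo acquisitions found in
large epidemiological archives: short-axis (SAX) stacks plus two- and
four-chamber long-axis (LAX) views, modest contrast, and contour files
that lost their 3D header information along the way.

The pipeline, end to end:

1. **Landmark detection** — VGG-style convolutional networks regress the
   two mitral-valve hinge points on each LAX view and the two
   right-ventricular insertion points on SAX slices, trained with a
   *cyclic cross-view transfer* schedule: one view trained from scratch,
   each next view initialized from the previously trained weights, cycling
   until no view improves.
2. **Segmentation** — a 3-class U-Net labels SAX pixels as background,
   myocardium or LV cavity; contours are extracted at subpixel precision
   and converted to 3D patient coordinates through the per-slice imaging
   geometry.
3. **Model customization** — a two-surface (endo/epi) tensor-product
   B-spline LV model is fitted to the 3D contours by regularized least
   squares,

   min<sub>θ</sub> (1/n) Σᵢ ‖S(uᵢ,vᵢ;θ) − xᵢ‖² + λ‖D(θ−θ₀)‖²,

   with a two-pass breath-hold correction: a highly regularized
   (shape-preserving) fit, an in-plane (2-DOF) shift of every SAX slice
   onto the model-intersection centroid, and a low-regularization refit.
4. **Clinical measures** — slice-summation volumes, 1.05 g/mL mass,
   ejection fraction, body-surface-area indexing (Du Bois), with
   Bland–Altman, Pearson and ICC(2,1) agreement statistics.
5. **Shape atlas and risk association** — 512 corresponding points per
   surface at end-diastole and end-systole concatenated into a
   12N = 6144-coordinate shape vector S = [x₁,y₁,z₁,…], generalized
   Procrustes alignment (position and orientation removed, size kept),
   PCA, and per-factor logistic regression on the first 20 PC scores under
   10-fold cross-validation with the PCA rebuilt inside every fold; AUCs
   of two pipelines are compared with DeLong's paired test.

Since clinical images cannot ship with the package, a first-class
synthetic module generates truncated-ellipsoid LV phantoms with full slice
geometry, analytic volumes, ground-truth contours and landmarks, injected
breath-hold shifts, and populations whose shape varies along known
deformation modes linked to binary risk labels. Every stage is validated
against those closed forms; see `vignettes/lvatlas-methods.Rmd` for the
models, parameter defaults and limitations.

## Worked example

Render a noiseless phantom, inject up to 8 mm of per-slice breath-hold
misregistration, recover it, and compute clinical measures:

```r
library(lvatlas)
spec <- phantomSpec(noiseSd = 0, seed = 8L)          # 25x25x60 mm endo, 8 mm wall
r <- renderCineStudy(spec, imagingParams(nFrames = 2))
r$study
#> CineStudy: 10 SAX slice(s), 2 LAX view(s), 2 frame(s)
r$truth
#> GroundTruth: EDV 132.5 mL, ESV 50.9 mL, ED myocardium 118.5 mL

sh  <- applyBreathholdShifts(r$study, maxShift = 8, seed = 9L, truth = r$truth)
res <- fitLV(sh$study, r$truth@contours, r$truth@landmarks)  # two-pass correction
res$fit
#> FittedLV: 8x6 control grid per surface, RMS residual 0.637 mm
mean(abs(res$shifts - sh$shifts))   # shift recovery error, mm
#> [1] 0.62

g  <- r$study@slices[[1]]$geometry
ed <- contourAreas(r$truth@contours, res$phases$ed, g@pixelSpacing)
es <- contourAreas(r$truth@contours, res$phases$es, g@pixelSpacing)
clinicalMeasures(sliceSummationVolume(ed$cavity_mm2, 6, 4),
                 sliceSummationVolume(es$cavity_mm2, 6, 4),
                 lvMass(sliceSummationVolume(ed$myo_mm2, 6, 4)),
                 heightCm = 172, weightKg = 74)
#> LVEDV 132.6 mL, LVESV 51.0 mL, mass 124.4 g, BSA 1.87 m2,
#> LVEDVi 70.9, LVESVi 27.3 mL/m2, LVMi 66.4 g/m2, LVEF 61.5 %
```

The analytic truth for this phantom is EDV 132.5 mL and EF 61.6%: the
recovered measures agree to well under a percent of volume and ~0.1
percentage point of EF despite the injected misregistration. Cohort-level
use goes through `generatePopulation()` → `runPipeline()`, which adds the
Procrustes/PCA atlas (`AtlasModel`) and the cross-validated association
(`cvAssociation()`, `compareAuc()`).

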