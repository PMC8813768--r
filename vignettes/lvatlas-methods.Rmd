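---
title: "Methods: automated LV shape-atlas construction from cine MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated LV shape-atlas construction from cine MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`lvatlas` implements a fully automated analysis chain for legacy
gradient-echo cine cardiac MRI: detect mitral-valve (MV) hinge points on
two- and four-chamber long-axis views and right-ventricular (RV) insertion
points on short-axis slices with convolutional coordinate-regression
networks trained under a cyclic cross-view transfer schedule; segment
short-axis slices into background / myocardium / LV cavity with a U-Net;
convert 2D contours to 3D patient coordinates through the per-slice imaging
geometry; customize a two-surface parametric LV model to the contours by
regularized least squares, correcting in-plane breath-hold misregistration;
derive slice-summation clinical measures; and build a Procrustes/PCA shape
atlas over concatenated end-diastolic (ED) and end-systolic (ES) surfaces
whose principal-component scores are related to binary risk factors by
cross-validated logistic regression.

Because no patient data can ship with the package, every stage is
exercised against a synthetic phantom cohort with analytic ground truth.
This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not establish.

# The phantom and what it stands for

The phantom LV is a truncated prolate ellipsoid: the endocardial surface
has semi-axes $(a, b, c)$ mm (default $25 \times 25 \times 60$) cut by a
basal plane at a fraction $f$ (default 0.5) of $c$ above the equator, so
the default LV length is $(1+f)c = 90$ mm; the epicardial ellipsoid adds a
wall thickness (default 8 mm at ED). The cavity volume has the closed form

$$V(f) = \pi a b c \left(\tfrac{2}{3} + f - \tfrac{f^3}{3}\right),$$

which is the package's primary oracle: the default ED cavity is 132.5 mL,
and with 30% short-axis contraction and 35% systolic wall thickening at ES
the ejection fraction is ~62% and ED mass ~124 g — mid-normal adult
values. An RV half-annulus spanning azimuths 120°–240° abuts the septum;
its arc ends define the RV insertion points, and the intersections of each
long-axis plane with the basal endocardial rim define the MV hinge points.

Rendering evaluates the implicit surfaces at pixel centers on planes with
full imaging-header geometry (origin, direction cosines, 2 mm pixels,
6 mm slices with 4 mm gaps — the legacy protocol), producing three
piecewise-constant intensity bands plus Gaussian noise. This emulates
tissue contrast and acquisition geometry, *not* MR physics: no coil
shading, flow, or wrap artefacts, and the anatomy is smooth and convex.
Passing tests therefore demonstrate correctness of the geometry, fitting,
statistics and learning machinery under known truth — not performance on
clinical images.

Breath-hold misregistration is injected by translating each short-axis
slice origin in-plane by an independent uniform 2-vector in
$[-8, 8]^2$ mm (uniform rather than Gaussian so the maximum is controlled;
the real distribution of breath-hold offsets is not well characterized, so
8 mm is a configurable ceiling). The image content is untouched: the
header lies about where the tissue was, which is exactly what
misregistration does to contour-to-3D conversion.

Population variation uses three linearized deformation modes
(wall thickening, sphericalization, dilation) with an N(0,1) per-subject
score; a binary label shifts the score by a standardized effect size, and
labels are assigned by stratified draw so prevalence is exact. Remaining
parameters get small relative jitter (default SD 3%) and each subject a
random rigid pose (≤15°, ≤20 mm).

# Coordinate conventions

Pixels are 0-based, coordinates at pixel centers, `(row, col)` order. The
patient-space position of pixel $(r, c)$ is
$\mathbf{o} + c\,s_c\,\mathbf{u}_{row} + r\,s_r\,\mathbf{u}_{col}$, where
$\mathbf{u}_{row}$ is the direction of increasing *column* index — the
standard imaging-header affine. All transforms are exact; round trips are
tested to $10^{-9}$ mm.

Contours are extracted from label masks at subpixel precision by marching
squares on the label indicator at level 0.5 (the largest connected
component per label), ordered counter-clockwise; mask reconstruction tests
pixel centers against the closed polygons. Cine stacks are ordered apex to
base by projecting slice origins onto the stack normal, resolving the apex
end from the MV side when landmarks are available, else from the
smaller-cavity end. Geometry-free legacy contour files are matched to
slices by apex-to-base ordering plus an integer offset maximizing
contour/mask overlap; a slice-count mismatch beyond 2 excludes the study
for review, and unmatched leading/trailing slices are flagged.

# Landmark and segmentation networks

Both networks run on the package's own compact CNN engine (RcppArmadillo:
3×3 convolutions via im2col + GEMM, ReLU, 2×2 max-pooling,
nearest-neighbour upsampling, dense layers, Adam). Training is
deterministic given a seed.

The landmark network regresses four values $[r_1, c_1, r_2, c_2]$
(normalized by the input size) from a whitened, zero-padded square image.
Whitening is per image over original-content pixels; padding offsets are
returned so predictions map exactly back to the original frame. The loss
is mean squared error on normalized coordinates (a convention of this
implementation; nothing deeper hangs on it). Landmark pair order is fixed
by construction — anterior/lateral hinge first on LAX, the 120° insertion
first on SAX — because 4-value regression requires a consistent
convention.

Two presets exist. The *full* preset mirrors the published design
(256×256 input, 16 convolutional layers, 2048-feature head). The *scaled*
preset — used by the test suite and benchmarks so everything runs on one
CPU core in minutes — uses 64×64 inputs, three conv blocks (8/16/32
channels), a 64-unit head, Adam at 3e-3, batch 8. On the 500-image
phantom benchmark it reaches ≈2–3 px mean validation error (≈6–9 mm at
the 3 mm rendering spacing — looser than the paper-scale networks, as
expected at 1/16 the capacity; the *direction* of results, not their
magnitude, is what the desk scale preserves).

Cyclic transfer training follows the published schedule: one view trained
from scratch, each next view initialized from the previously trained
weights, views visited in a seeded random order, repeating until no view
improves its validation distance by more than 0.05 px over a full cycle
(cap 10 cycles). Best-per-view weights are kept, so a later cycle can
never degrade a view's final model. On the benchmark the transferred
models beat independently trained baselines on all three views.

The U-Net (two encoder levels + bottleneck + skips, base width 8 at the
scaled preset) predicts the three classes per pixel with softmax
cross-entropy; augmentation (flip, zoom 0.9–1.1, brightness ±0.1,
contrast 0.9–1.1) doubles the training set, spatial ops applied jointly to
image and mask. Each image is segmented independently — no temporal or
multi-slice context. Held-out Dice on the 500-image benchmark is ≈0.93
(myocardium) and ≈0.98 (cavity); the 0.85 acceptance floor is the
desk-scale analogue of published full-scale performance. The both-empty
Dice case is defined as 1 and flagged, so empty apical slices do not
poison means.

# LV model customization

The model is two tensor-product cubic B-spline surfaces (endo, epi) over a
periodic circumferential × clamped longitudinal parameter domain, 8×6
control vertices per surface, with the apex row collapsed to a single
shared vertex so the surface closes. This basis is this package's design;
the published pipeline cites an external finite-element description that
is not restated there, so equivalence is not claimed — only the fitting
*strategy* is reproduced.

The pose places a canonical template in patient space: long axis from the
MV centroid (basal plane origin) toward the apex, septal azimuth from the
RV-insertion midpoint, length scaled to the MV-centroid-to-apex distance.
The apex is estimated from the contours as the most apical endocardial
centroid extended by half a slab. Fitting works in the normalized
pose-local frame, which makes the whole fit exactly equivariant to rigid
motion of the study (tested to $10^{-6}$ mm).

Each surface is fitted by iterated linear least squares: data points are
assigned the parameters of their closest surface point (dense grid search
plus local refinement), then control vertices solve

$$\min_\theta \tfrac{1}{n}\sum_i \|S(u_i, v_i; \theta) - x_i\|^2 +
\lambda \left(\|D(\theta - \theta_0)\|^2 + 10^{-3}\|\theta - \theta_0\|^2\right),$$

where $D$ is the second-difference operator on the control grid and
$\theta_0$ the pose-placed template. Penalizing *displacement from the
template* (rather than the absolute grid) makes the $\lambda \to \infty$
limit the template itself — the "highly regularized" first pass that
preserves overall shape. Defaults: $\lambda_{high} = 10^3$,
$\lambda_{low} = 10^{-1}$ on normalized coordinates, at most 8 outer
iterations, 0.01 mm convergence tolerance. The objective is non-increasing
across iterations and clean phantom contours fit to <0.5 mm RMS.

Breath-hold correction is the two-pass scheme: fit at $\lambda_{high}$;
per short-axis slice, translate all contours in-plane (two degrees of
freedom, none longitudinal) so the endocardial contour centroid lands on
the area-weighted centroid of the model–plane intersection polygon; refit
at $\lambda_{low}$. Slices without a model intersection keep zero shift
and are flagged. One fit–shift–refit pass is performed.

One robustness choice deserves emphasis. With 8 mm uniform shifts on a
10-slice stack, *any* long axis re-estimated from the shifted short-axis
centroids inherits ≈1.4–2 mm of average in-plane error, which would
consume the entire shift-recovery budget. The pass-1 alignment therefore
anchors the long axis at the MV centroid (long-axis views are immune to
short-axis breath-hold shifts) along the short-axis stack normal whenever
that normal is within 15° of the MV-to-apex direction — short-axis planes
are prescribed orthogonal to the LV axis at acquisition, and in-plane
shifts carry no longitudinal information, so the acquisition geometry is
the one shift-free estimate of axis direction available. Outside that cone
the MV-to-apex axis is used unchanged. With this anchor the correction
recovers injected uniform ≤8 mm shifts with <1 mm component-wise mean
absolute error over 50 studies and produces <0.5 mm spurious shift on
unshifted studies.

ED is the earliest-trigger frame; ES the frame with minimum summed cavity
area; the ES fit inherits the ED pose and initializes from the ED
solution. Long-axis contours are not used in the surface fit (quality
control only).

# Clinical measures

Volumes are slice summations: cavity area × (thickness + gap) over slices
with endocardial contours, no partial-voxel basal correction. Mass is
myocardial volume × 1.05 g/mL. BSA uses Du Bois
($0.007184\,W^{0.425} H^{0.725}$; Mosteller selectable) — the published
analysis does not name its formula, so the choice is isolated behind one
function. EF is $(EDV - ESV)/EDV \times 100$ and is BSA-invariant by
construction. Agreement statistics are Bland–Altman (mean difference,
mean ± 1.96 SD limits) and Pearson correlation; ICC is the two-way
random-effects, single-rater, absolute-agreement variant ICC(2,1),
computed from ANOVA mean squares (the published text says only "two-way
random effects", so the absolute-agreement variant is a declared choice).

# Shape atlas and association

Each fitted model is sampled at N = 512 points per surface on a fixed
parameter grid (32 circumferential × 16 longitudinal, apex to base), and
the four surfaces (endo/epi at ED/ES) are concatenated into a 12N = 6144
coordinate shape vector, preserving shape *and* motion. Generalized
Procrustes alignment removes position and orientation only — scale is
retained, because ventricular size is cardiac signal; the no-scaling
choice is configurable in principle but is the package default. ED and ES
blocks share a single per-subject transform so phase-to-phase motion
survives alignment.

PCA is computed through the SVD of the n × 12N centered matrix (the dual
route when n ≪ 12N), eigenvalues are variances summing to the total
(tested to $10^{-8}$), and component signs follow a fixed convention
(largest-magnitude loading positive) for run-to-run reproducibility. On a
200-subject single-mode cohort PC1 explains >99% of variance and aligns
with the generative mode to |cos| > 0.99.

Association uses one logistic regression per binary factor on the first
20 PC scores, under 10-fold stratified cross-validation with the PCA
rebuilt from scratch inside every fold (no test subject ever influences
the training atlas — asserted programmatically before each fit). The
headline AUC is computed from pooled out-of-fold probabilities; the
fold-averaged AUC is also reported, since the published table does not say
which pooling it used. Fold assignment is keyed to stable subject ids, so
row order cannot change results. Unpenalized ML fitting is the default
with a ridge-penalized IRLS fallback (λ = 0.01) under detected
separation. Two pipelines on the same subjects are compared with DeLong's
paired test on the pooled out-of-fold predictions (the published
comparison does not name its test; DeLong is the field standard). Null
calibration (AUC ≈ 0.5, type-I rate ≈ 0.05) and power at effect size 2
(AUC > 0.85; the single-mode theoretical ceiling at that effect is
$\Phi(\sqrt{2}) \approx 0.92$) are part of the acceptance suite.

# Problem sizes and numerical choices

The test and acceptance runs use: the default 10-slice, 96×96, 2 mm
phantom for geometry oracles; 50 studies for shift recovery; 200 subjects
(N = 512) for atlas recovery; 400 subjects (N = 64 analytic shape
vectors) for association calibration; 500 images per view for the network
benchmarks; and a 20-subject rendered cohort for the end-to-end run.
Association calibration samples the generative surfaces directly rather
than rendering and refitting 400 studies — the analytic route is the
oracle for those statistics, and the rendered route is exercised
end-to-end at smaller n.

Degenerate inputs have defined behaviour throughout: constant images are
centered but not scaled; empty masks yield no contour plus a flag;
coincident endo/epi contours give zero myocardium with a warning; an
endocardium outside its epicardium, a missing class in training masks, an
apex coincident with the MV centroid, or a rank-deficient fitting system
are errors that name the offending input. Subject-level failures in the
pipeline are isolated: the subject is excluded with a reason code and the
cohort stages proceed with the survivors.

# Known limitations

* The phantom is convex, smooth, and noise-stationary; none of the
  networks' robustness to papillary muscles, trabeculation, low-contrast
  gradient-echo blood pools, or arrhythmic frame ordering is tested here.
* The surface basis and regularization weights are stand-ins for the
  published finite-element model; fitted shapes are comparable within this
  package, not with atlases built elsewhere.
* The scaled network presets are deliberately small; their errors are
  desk-scale analogues, not clinical performance claims.
* Breath-hold correction assumes in-plane, per-slice rigid offsets; true
  respiratory motion has through-plane components this model ignores.
* The axis anchor assumes short-axis planes were prescribed near-orthogonal
  to the LV axis; grossly oblique stacks fall back to the landmark axis
  and lose the anchored accuracy.
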