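---
title: "Methods: neonatal brain morphometry and outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal brain morphometry and outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Infants born very preterm are at elevated risk of cognitive and motor
impairment, conventionally defined as a Bayley-III composite score below
85 (one standard deviation below the population mean of 100) at two years
of corrected age.  Structural MRI acquired around 30 and 40 weeks
postmenstrual age carries prognostic information, but turning images into
a prediction requires (i) reducing each segmented image to a small number
of quantitative descriptors, (ii) building per-subject feature vectors,
and (iii) evaluating a classifier honestly on cohorts of less than two
hundred subjects.  `neopredict` implements that pipeline as reusable,
tested components, together with synthetic data whose ground truth is
known analytically.

## Inputs and the tissue code scheme

The pipeline starts from 8-class tissue segmentations, not from raw MRI:
each voxel of a NIfTI label volume carries one of the codes 1 uWM
(unmyelinated white matter), 2 mWM (myelinated white matter), 3 cGM
(cortical grey matter), 4 vCSF (ventricular CSF), 5 eCSF (extracerebral
CSF), 6 CB (cerebellum), 7 BGT (basal ganglia and thalami), 8 BS (brain
stem), with 0 as background (`tissue_classes()`).  Foreign code schemes
can be remapped on read (`read_label_volume(path, remap = ...)`).
Neonatal acquisitions are strongly anisotropic (e.g. 0.34 x 0.34 x 2 mm
voxels); all geometry downstream is computed in physical millimetres.

## The fourteen descriptors

`compute_descriptors()` reduces one label volume plus the gestational age
at birth to the canonical descriptor vector, in fixed order: GA, the
eight relative tissue volumes (CB, mWM, BGT, vCSF, uWM, BS, cGM, eCSF,
as fractions of intracranial volume), inner cortical surface area (ISA),
global mean curvature (MC), gyrification index (GI), median cortical
thickness (MT), and brain volume (BV, the total intracranial volume).

Volumes are voxel counts times voxel volume on the native grid.  The four
cortical measures are mesh-based and deserve detail, because the
numerical choices matter at neonatal scale:

1. **Isotropic resampling.**  The label grid is resampled to 0.5 mm
   isotropic voxels by nearest neighbour, so that surface extraction is
   not biased along the low-resolution axis.
2. **Interior mask.**  The cerebral interior is the union of uWM, mWM,
   BGT and vCSF; including the ventricles and deep grey keeps the inner
   cortical surface from being punctured at the ventricle walls.  The
   largest 6-connected component is kept and internal cavities are
   filled, so the boundary is a single closed surface.  The outer
   cortical surface additionally includes cGM.
3. **Surface extraction.**  The binary mask is smoothed with a Gaussian
   (sigma of 1 voxel) and the level-0.5 iso-surface is extracted by
   marching tetrahedra on a Kuhn subdivision of each grid cell.  Because
   the six tetrahedra of neighbouring cells agree on shared faces, the
   mesh is watertight by construction; this is asserted, not assumed.
   Smoothing first is essential: the iso-surface of a raw binary mask is
   a voxel staircase whose area overestimates the true area by a large,
   resolution-independent factor.  Interpolation positions along
   tetrahedron edges are clamped away from the endpoints (to [0.05,
   0.95]) so that no degenerate sliver triangles are produced.
4. **ISA** is the summed triangle area of the inner surface.
5. **GI** is inner surface area divided by the area of the convex hull of
   its vertices; a convex brain has GI 1, folding raises it.  The hull is
   computed by incremental insertion; for large meshes the candidate set
   is first reduced to the support points of several thousand uniformly
   distributed directions, which reproduces hull areas of smooth bodies
   to well under 0.5%.
6. **MC** is the area-weighted mean of the signed discrete mean
   curvature: the cotangent-Laplacian mean-curvature normal with
   barycentric vertex areas, signed against the outward vertex normal,
   after 10 passes of uniform Laplacian smoothing (step 0.5).  The signed
   average is used deliberately — voxelization noise then cancels instead
   of accumulating, and a sphere of radius r recovers 1/r to well within
   a percent.  An unsigned average would be biased upward by whatever
   mesh noise survives smoothing.
7. **MT** is the median over inner-surface vertices of the Euclidean
   distance to the nearest outer-surface vertex (nearest neighbours via a
   k-d tree).  The median is robust to the regions where inner and outer
   surfaces fuse (e.g. around the interhemispheric fissure).

```{r}
library(neopredict)
vol <- read_label_volume("subject42_40wk_labels.nii.gz")
desc <- compute_descriptors(vol, ga_birth = 26.9)
```

## Feature tables and labels

`build_arm()` joins subject metadata with per-timepoint descriptors into
one of three modelling arms: the 30-week scan, the 40-week scan, or the
serial change (40-week minus 30-week difference of the 13 image
descriptors, with GA passed through).  Outcomes are labelled low when the
designated Bayley score is strictly below 85; subjects missing the
required scan or score are dropped with a message, never silently.

## Classification and evaluation

The classifier is a linear-kernel SVM (L1 hinge loss, C = 1) on min-max
scaled descriptors, with scaling fitted on the training rows only.
Probabilities are obtained by Platt scaling: a two-parameter sigmoid
fitted to decision values produced by 3-fold cross-validation inside the
training split.  Evaluation uses repeated random subsampling: in each of
500 repeats (by default), 5% of subjects — at least one — form the test
set; all test predictions are pooled into a single ROC curve, whose
trapezoidal AUC equals the Mann–Whitney statistic under the rank-average
tie convention.  Repeats whose training split would contain a single
class are redrawn once and otherwise skipped and counted.

The SVM is trained by dual coordinate descent with shrinking and
randomised (deterministically seeded) coordinate order; the Platt sigmoid
by a regularised Newton method.  A hand-rolled solver is used because the
exhaustive search refits the classifier hundreds of thousands of times;
its decision ordering and AUCs are cross-checked against an independent
SVM implementation in the test suite.

```{r}
des <- cv_design(n_repeats = 500, seed = 1)
res <- evaluate_subset(tab, c("GA", "GI", "ISA"), des)
plot(res)
```

## Exhaustive subset search

`run_search()` evaluates every non-empty subset of the 14 descriptors —
16383 of them — under one shared list of splits, so that subset rankings
are not confounded by split-sampling noise.  Subsets are ranked by pooled
AUC (ties broken deterministically by the subset's binary counter value),
descriptor presence is counted over the top-10 subsets, and seven
predefined comparison subsets (all image descriptors, volumes,
morphology, each with and without GA, and GA alone) are evaluated on the
same splits.  `write_search_report()` writes the ranking, the presence
counts and per-subset ROC curves as CSV.

## Synthetic data

Real images and outcome scores cannot be redistributed, so the package
ships two generators whose ground truth is known exactly.

**Geometric phantom.**  `make_phantom()` rasterises an 8-class brain-like
geometry: a BGT core (radius 6 mm), vCSF shell (6–8 mm), uWM out to the
inner cortical radius with an embedded mWM sphere, a cortical ribbon of
constant 3 mm radial thickness, eCSF to 26 mm, and separate cerebellum
and brain-stem spheres below.  The inner cortical radius is
$r(\theta,\varphi) = 20 + a\,\sin(k\theta)\sin(k\varphi)$ mm, so the
unfolded phantom ($a = 0$) has closed-form descriptors (ISA $= 4\pi
20^2$, GI 1, MC 1/20, MT 3 mm, class volumes from sphere shells), and
increasing $a$ produces controlled folding whose area, hull area and
enclosed volume are obtained from a dense parametric mesh of the analytic
surface (`phantom_surface_truth()`), independently of any voxel
processing.  One rasterisation detail is deliberate: the brain centre is
placed at a fixed irrational sub-voxel offset, because spheres centred
exactly on (or exactly between) lattice points are the degenerate worst
cases of voxel counting — a 2.5 mm sphere rasterised at half-voxel phase
miscounts its volume by over 5%, while in generic position all phantom
structures count to within 2%.

**Simulated cohorts.**  `simulate_cohort()` draws an exact number of
positive subjects, gives each descriptor a configurable standardised
class shift (optionally with inter-descriptor correlation), and generates
Bayley scores consistent with the drawn labels around the 85 threshold,
so printed prevalence counts (e.g. 37/153 = 24%) are reproduced exactly.
For a single shifted descriptor the theoretical AUC is
$\Phi(\delta/\sqrt{2})$ (`theoretical_auc()`), giving a closed-form
target for the whole evaluation chain.  Cohort simulation and split
drawing seed their RNG streams through a component-specific hash, so
passing the same integer seed to both does not couple their draws.

## Known limitations

- **Pooled AUC of an uninformative classifier is biased below 0.5.**  If
  no descriptor carries signal, the hinge-loss optimum is the majority
  rule and the calibrated probability collapses to the training base
  rate.  Pooling such per-repeat constants anti-correlates with the test
  labels (a test set rich in positives leaves a positive-poor training
  set), giving pooled AUCs around 0.45 rather than 0.50.  This is a
  property of pooling calibrated probabilities over subsamples of a fixed
  finite cohort, not of the implementation; per-repeat AUCs and
  uncalibrated decision-value pooling do not show it.
- Nearest-vertex cortical thickness slightly underestimates thickness on
  strongly folded surfaces; the median and the 0.5 mm working resolution
  keep the bias small at neonatal folding scales.
- Uniform Laplacian smoothing before curvature estimation shrinks convex
  surfaces slightly; with 10 passes at step 0.5 the effect on MC is well
  below the across-subject variation the descriptor is meant to capture.
- Relative volumes of very small structures (the brain stem is ~2.5 mm in
  radius) carry lattice-counting error of order 1% at 0.5 mm voxels, and
  proportionally more at clinical slice thickness.
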