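---
title: "Quantitative alpha autoradiography and microscale dosimetry: models and methods"
author: "alphamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative alpha autoradiography and microscale dosimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphamap)
```

# Scope

`alphamap` implements a complete analysis chain for quantitative digital
alpha-particle autoradiography of tissue sections in alpha-emitter
radiopharmaceutical therapy (aRPT) research: list-mode events to calibrated
activity maps, geometric distortion correction, histology co-registration,
serial-section 3D reconstruction, compartment-resolved spatial uptake
statistics in kidney, and near-cellular dose-rate maps with dose-volume
histograms. This vignette documents the underlying models, the tunable
parameters and their defaults, the numerical choices, and what the bundled
synthetic-data generators do and do not emulate.

# Activity quantification from list-mode data

A position-sensitive scintillation camera records every detected alpha as a
centroid position plus timestamp ("list mode"). Images are formed by binning
events into square pixels (default 26.5 um, the camera grid), exactly as a 2D
histogram with half-open bins. Counts relate to activity through radioactive
decay: with decay constant $\lambda$ and $N_0$ radioactive atoms at reference
time 0, the counts collected over acquisition windows $(t_{i,1}, t_{i,2})$
are

$$ \mathrm{Counts}_{total} = f\, N_0 \sum_i
   \left(e^{-\lambda t_{i,1}} - e^{-\lambda t_{i,2}}\right), $$

where $f$ is the camera sensitivity factor (detected events per primary
decay; it exceeds 1 for decay chains emitting several alphas). Inverting with
$A_0 = \lambda N_0$ gives the per-pixel activity at the reference time,
`activity_at_reference()`. This treatment is exact for acquisitions that are
long relative to the half-life and for recordings spliced from several
sessions (`merge_sessions()`); no constant-activity approximation is
involved.

`constant_activity_error()` quantifies what the naive alternative (average
activity = mean of the endpoint activities) would cost: with
$x = \lambda T$ the relative error is $(x/2)\coth(x/2) - 1$, verified in the
tests against direct numerical integration of the decay exponential. For
Ac-225 (half-life fixed at 9.920 d) it is ~0.25% for a 60-h acquisition, ~2%
at one week, and just under 8% at two weeks — negligible for short scans,
decidedly not for long ones.

## Calibration

`fit_sensitivity()` regresses measured counts of dried activity standards
onto their primary-decay totals, through the origin: zero activity must give
zero counts, so a free intercept would only absorb noise. Primary decays are
computed with the same decay-weight machinery as the imaging model, never a
constant-activity shortcut. Weights default to the Poisson choice
(variance proportional to expectation), under which the slope is the pooled
ratio of total counts to total primaries; an unweighted fall-back is
available. The fit is returned as a classed object with `print`, `summary`,
`coef`, `predict` and `plot` (identity-line) methods. Detector efficiency
follows from the one-sided counting geometry: the section touches the
scintillator on one face, so only half of all emissions can reach it, and an
Ac-225 primary decay yields 4 chain alphas; hence
`efficiency = f / (0.5 * 4)`.

# Geometric distortion correction

Wide-field optical detectors show barrel-type distortion, largest in the
corners. The correction is calibrated from lattice phantoms (circles,
squares, dots) whose idealized images are generated digitally
(`render_phantom()`).

* **Global isotropic scale** (`estimate_isotropic_scale()`): element
  centroids are matched between measured and ideal images and the robust
  median of paired centered-radius ratios is taken — invariant to rotation
  and translation. Both images pass through the *same* centroid extractor so
  that its small systematic biases cancel in the ratio.
* **Warp field** (`estimate_warp_field()`): matched centroid displacements
  are decomposed into a closed-form least-squares rigid part plus a smooth
  free-form residual fitted with penalized tensor-product B-spline smooths
  (`mgcv`), whose smoothing penalty plays the role of a bending-energy
  regularizer. Because the phantom supplies exact, dense landmarks, this
  correspondence-based fit is preferred over intensity-metric optimization:
  it is deterministic, has no capture-range limitation, and its residual at
  the dot centroids directly reports the achieved accuracy (well below half
  a pixel on the synthetic barrel phantom).

The resulting `deformation_field` maps corrected to raw coordinates.
`apply_correction()` resamples bilinearly and multiplies by the Jacobian
determinant of the map (central differences on the dense field, one-sided at
borders), so local area changes do not create or destroy counts; the image
total is preserved to well under 0.5% for content away from the frame edge.
Fields with non-positive Jacobian (folding) are rejected at construction.
The correction is applied to autoradiography images *before* any
cross-modality registration, so that the pixel grid downstream is physically
calibrated and no further scaling is permitted.

# Histology integration and 3D reconstruction

The same sections are imaged on the camera and, after staining, on a slide
scanner, so a true rigid 1:1 mapping exists. Registration is two-step:
closed-form least-squares landmark initialization from three or more manual
point pairs (`landmark_rigid_fit()`, SVD of the cross-covariance; collinear
configurations are rejected), then a rigid transform optimized against
histogram-based mutual information (32 bins on min-max-normalized images).
The optimizer is Nelder-Mead over (rotation, translation), preceded by a
coarse MI sweep (+-12 degrees, +-8 px) that removes capture-range failures;
convergence is declared when the objective plateaus (relative change below
1e-6 over the trailing 10% of evaluations). Slides carry three sections with
fixed relative positions; registering the slide *as one rigid body* adds the
geometric leverage that resolves rotations which a single, near-symmetric
section cannot (`register_histology_to_autoradiography()`; demonstrated on
synthetic symmetric-section trials in the test suite).

Serial sections (28 um apart by default) are stacked to the middle reference
section by `stack_sections()` using either strategy:

* `activity_only`: rigid then similarity transform fitted on the activity
  maps by mutual information; the transforms are applied to the anatomy
  images for evaluation.
* `anatomy_guided`: rigid transform fitted on the anatomy images, then a
  free-form stage — local normalized-cross-correlation block matching
  produces a field of displacement samples, smoothed into a dense
  displacement field by the same penalized B-spline fit used for the warp
  correction (fields that fold are rejected); identical transforms are
  applied to the activity maps.

Alignment quality is scored with the Dice similarity coefficient between
anatomy masks of adjacent sections (`dice()`; the two-empty-masks case is
defined as 1 and flagged), and the strategies are compared over repeated
synthetic stacks with `compare_stacking()` (mean relative improvement plus a
paired two-sided t-test). Activity in antibody-mediated aRPT is sparse and
hot-spot dominated, which is exactly why activity-driven registration
underperforms anatomy guidance on morphologically rich sections.

# Kidney compartments and distance profiling

Stained kidney sections are segmented into tissue, blood vessels and
glomeruli. Tissue is Otsu foreground (256-bin between-class variance, via
EBImage) with hole filling and a minimum component area of 0.05 mm^2.
Candidate structures are low-intensity lumina inside the tissue (inverted
Otsu restricted to the tissue mask); connected components are classified by
shape statistics. Defaults — glomeruli: equivalent diameter 50-150 um and
circularity >= 0.7; vessels: equivalent diameter > 150 um or bounding-box
aspect ratio > 3 — reflect murine renal microanatomy (only larger vessels
are segmented, by design) and are fully configurable
(`compartment_rules()`); the bands are declared choices, not fitted values.
Classification is deterministic and invariant to global linear intensity
scaling.

`distance_map()` is the exact Euclidean distance transform (EBImage) in
micrometres; `uptake_vs_distance()` bins tissue pixels by distance to a
reference structure (tissue edge, vessels or glomeruli) and reports mean
activity per bin relative to the mean over the profiled pixels, so the
pixel-count-weighted profile mean is exactly 1. Activity maps are resampled
bilinearly from the 26.5-um camera grid onto the finer anatomy grid (4:1 by
default); the default bin width of 5 um deliberately oversamples the camera
resolution because sub-pixel profile structure (a peak tens of micrometres
from the glomeruli) is the object of interest. When profiling distance from
vessels, the vessel lumen itself is excluded so the zero-distance band
reports blood pool separately.

Replicates (by default 3 sections x 3 kidneys per condition) are combined
per bin as mean +- t-quantile x SEM at 95% (a seeded percentile bootstrap is
available). Significance between conditions uses the interval-exceedance
rule: a direction flag wherever one condition's mean falls outside the
other's interval. The published rule is stated in one direction only; this
implementation raises the headline `significant` flag when *both* directions
exceed, because simulation of null (flat-uptake) phantoms puts that
symmetric reading at just under a 10% per-bin false-positive rate at n = 9,
while the one-directional "either" reading is markedly more liberal
(~15%). Both flags are exported, everything is per-bin and unadjusted — no
multiple-testing correction is applied, matching the published procedure —
and outputs are labelled accordingly.

# Near-cellular dosimetry

Dose-rate maps are the 3D convolution of the activity volume (decays per
hour per voxel) with a dose-voxel kernel (DVK): the mean absorbed dose per
voxel per primary decay placed uniformly at random inside the central voxel.
`generate_dvk()` produces the kernel by Monte-Carlo transport in the
continuous-slowing-down approximation (CSDA): each primary emits the chain
alphas isotropically (Ac-225: exactly 4, at 5.830, 6.341, 7.067 and
8.375 MeV — the dominant Ac-225/Fr-221/At-217/Po-213 lines, the 2.1% Bi-213
branch folded into Po-213), and each alpha travels in a straight line
depositing energy according to the Bragg-Kleeman range-energy relation
$R(E) = kE^{1.75}$ in unit-density water, $k$ calibrated so that
$R(8.375\,\mathrm{MeV}) \approx 85$ um (checked against tabulated CSDA
ranges: ~45 um at 5.8 MeV). Energy straggling, delta rays, scattering,
recoil nuclei and non-alpha emissions are neglected; alpha tracks in water
are nearly straight and the medium is treated as water throughout, so this
is a transparent, documented transport model with exact energy bookkeeping —
total deposited energy per primary equals the chain energy sum by
construction, asserted to 1% in every run together with central-voxel
maximality and axis mirror symmetry.

Defaults: voxels 26.5 x 26.5 um in-plane; dz = 14 um (the section
thickness) for single-section work, while stacked volumes built on a 28-um
section spacing use dz = 28 um under the stated assumption that each section
represents its slab — both are supported, the choice is configurable and
recorded. The deposition step is min(voxel min-dimension / 4, 1 um). The
kernel extent defaults to the maximum alpha range and errors out, listing
the required extent, if set smaller. With a 3-section stack and an ~85-um
range the kernel necessarily extends beyond the measured planes;
`dose_rate_map()` warns that dose at the outer sections is edge-truncated
rather than silently extrapolating. Convolution is exact (direct shifted
accumulation), linear in activity, and refuses mismatched grids.
`cumulative_dvh()` reports the fraction of masked voxels at or above each
threshold on a uniform grid from 0 to the maximum, closed by a zero point
just above the maximum. Dose *rates* (Gy/h at the activity reference time)
are reported; time-integrated absorbed dose is out of scope.

# Synthetic data: what it does and does not emulate

All generators are pure functions of their parameters and a seed (R's
default Mersenne-Twister stream), and every truth artifact — fields,
transforms, masks, enrichment profiles — is returned alongside the data so
tests never re-derive truth from outputs.

* `simulate_listmode()` inverts the counting model exactly: per-pixel,
  per-window Poisson counts with the correct decay weighting, uniform
  positions within the pixel, timestamps from the truncated exponential.
* `generate_distorted_phantom()` renders ideal and distorted lattice images
  under isotropic scale + radial (barrel) distortion + optional smooth
  bumps, with the analytic corrected-to-raw truth field (the rendering
  inverse is found by fixed-point iteration; the returned truth is exact).
* `generate_kidney_phantom()` builds an elliptical cortex/medulla section
  with non-overlapping glomeruli confined to a cortical band and elongated
  vessels, stain-like contrast, and an activity map with a raised-cosine
  annular enrichment (peaking at the annulus center) around a chosen
  reference structure; the coarse camera-grid activity is the block mean of
  the fine truth, optionally Poisson-noised. Defaults (360 x 280 px at
  6.625 um; 20 glomeruli of 60-120 um; 3 vessels; 400-um cortex) match the
  scale of murine kidney sections.
* `generate_tumor_stack()` slices a lobed 3D tumor with rich internal
  texture and sparse Gaussian hot-spot activity, then perturbs each section
  by a known random rigid motion (defaults +-4 degrees, +-120 um — typical
  sectioning misalignment) and optionally a smooth warp. The benchmark
  stacks used in the tests are 128 x 128 anatomy pixels at 13.25 um with
  64 x 64 activity grids; the kidney phantom keeps the finer 4:1
  anatomy-to-activity ratio of microscope versus camera grids.

These phantoms emulate geometry, counting statistics and misalignment; they
do not emulate histological texture realism, staining variability, freezing
or sectioning artifacts (tears, folds), detector dead time or spatially
varying sensitivity. Tests passing on them validate the mathematics and the
pipeline plumbing, not the biology of real sections.

# Numerical choices and limitations

* Bilinear interpolation for images, nearest-neighbour for masks (topology
  preservation for Dice); out-of-support samples are zero-filled.
* Half-open binning `[lo, hi)` with 0-based physical origins; events on the
  outer top/right edge are dropped and counted.
* Time is seconds throughout; half-lives given in days pose no precision
  issues at second resolution.
* Mutual information uses 32 histogram bins; the binning is a choice, not a
  published value.
* The free-form registration stage needs enough image structure for block
  matching; on structureless inputs it degrades gracefully to the rigid
  result.
* Registration accuracy at the microscale has no in-vivo ground truth; the
  synthetic stacks are the benchmark, which is exactly their limitation.
* Problem sizes in the tests (e.g. 1e5 DVK primaries, 20 benchmark stacks,
  100 null-phantom repetitions) were chosen as the smallest sizes at which
  the assertions are statistically comfortable; the generators scale to
  larger studies unchanged.
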