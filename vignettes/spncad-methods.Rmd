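---
title: "Methods: PET/CT nodule CAD with a marker-controlled watershed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET/CT nodule CAD with a marker-controlled watershed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spncad` implements a computer-aided detection (CAD) pipeline for solitary
pulmonary nodules (SPNs) on paired 2-D PET/CT slices. A solitary pulmonary
nodule is a single, roughly round lung lesion; on FDG-PET, malignant
nodules typically show elevated tracer uptake, and a maximum standardized
uptake value (SUVmax) of 2.5 or more is the conventional malignancy
criterion. The pipeline runs five stages consecutively:

1. lung parenchyma segmentation on CT (iterative dynamic threshold),
2. rigid PET-to-CT registration by mutual-information maximisation
   (Powell's direction-set method),
3. PET-guided candidate delineation on CT with a marker-controlled
   immersion watershed,
4. feature extraction (five GLCM texture features on CT, SUVmax on PET),
5. RBF-SVM classification with scan-grouped 10-fold cross-validation, and
   detection-level evaluation (sensitivity; false positives per scan).

Because no clinical dataset ships with the package, a deterministic
digital thorax phantom generates paired CT/PET slices with full ground
truth; every quantitative claim made by the test suite and by
`scripts/acceptance.R` is computed on that phantom.

## Coordinate and transform conventions

Images are R matrices indexed `[row, col]`, 1-based, with pixel centers at
integer indices. A rigid transform `(tx, ty, theta)` rotates by `theta`
degrees about the image center `((nrow+1)/2, (ncol+1)/2)` and then
translates by `(tx, ty)` pixels. Warping is a pull-back:
`out[q] = img[T(q)]`, so warping by the inverse transform moves image
content by `+T`. The CT (256 px) and PET (128 px) grids share one field of
view; fractional position `f` maps to pixel index `f * n + 0.5` on a grid
of size `n`, which makes the two grid centers coincide and translations
scale with the grid spacing. All registration results are reported in CT
pixels.

## The digital phantom

`generate_slice()` renders a thorax slice: a soft-tissue body ellipse
(attenuation 40) over air (-1000), two lung ellipses (-800) with a small
seeded jitter, vessel-like line segments inside the lungs (width about
1.3 px, attenuation 30), and `n_nodules` discs of radius 4-9 px at
`lung + 600` attenuation, placed fully inside a lung with bounded retries
(an explicit error reports overcrowding). The slice is smoothed with a
1 px Gaussian so that edges carry realistic gradient ridges, and Gaussian
noise (sd 20) is added last. These attenuation levels are an abstract
scale chosen for testability, not a clinical HU calibration.

The PET activity map is rendered natively on the PET grid: background
uptake of SUV 0.8 in soft tissue, 0.3 in lung, 1.6 in a mediastinal
(cardiac blood pool) ellipse, and 0.02 outside the body, blurred at
1.2 px to mimic PET's low resolution. The map is then warped by the
slice's rigid misalignment, and each nodule's hot spot is planted *after*
the warp as a Gaussian blob whose peak pixel carries exactly the planted
SUVmax (converted to activity through `SUV = activity / (dose/weight)`
with dose 185 MBq and weight 74 000 g). Planting after the warp, at the
misaligned position, keeps the peak value exact under any misalignment,
so the planted-SUV fidelity invariant (recovered SUVmax equals the
planted value to 1e-6 in the noiseless phantom) holds by construction
rather than only approximately. PET noise (default 2.5e-4 activity units,
about 0.1 SUV) is added last.

Default study conditions: one nodule per scan, malignant with probability
120/219 (the case mix of the clinical cohort the pipeline is modelled
on), malignant SUVmax uniform in [2.5, 8], benign (inflammation) in
[0.5, 2.4], and per-scan misalignments up to 8 px and 5 degrees. What the
phantom does *not* emulate: scanner physics (point-spread functions,
attenuation artifacts, reconstruction noise textures), anatomical
variability beyond ellipse jitter, juxtapleural or ground-glass nodules,
and 3-D structure. Passing phantom benchmarks therefore demonstrates
algorithmic correctness under controlled conditions, not clinical
performance.

## Lung segmentation

`iterate_threshold()` is a fixed-point scheme: starting from `p0` the
threshold is repeatedly replaced by the mean of the two class means,
`p <- (mean(x <= p) + mean(x > p)) / 2`, until successive values differ
by at most `sigma`. Design choices: `p0` defaults to the image mean,
which always splits a non-constant image into two non-empty classes;
`sigma` defaults to 0.5 intensity units; a `max_iter = 100` guard turns
non-convergence into an error rather than a silent loop. On an image with
exactly two values `a < b`, any start strictly between them converges to
`(a + b) / 2` -- the property the test suite asserts over random triples.
Binarisation sends strictly-larger pixels to background (255) and ties to
parenchyma (0).

Raw thresholding labels the exterior air as parenchyma and punches
vessel/nodule holes in the lungs, so `refine_lung_mask()` clears
border-touching components, drops components smaller than 64 px or with
bounding-box fill fraction below 0.4 (lung fields are compact; thresholded
pure noise percolates into large dendritic clusters, and the solidity
criterion is what lets an all-air slice come back as an explicit
empty-lungs warning), keeps the two largest survivors, and fills interior
holes up to 500 px. The refinement is idempotent.

## Registration

Mutual information `MI = H(A) + H(B) - H(A,B)` is computed from a joint
histogram of the CT (reference) and the warped, upsampled PET (floating)
over their overlap region only; out-of-overlap pixels are excluded
because zero-padding would bias MI toward large shifts. Entropies use log
base 2 (the MI argmax is base-invariant). Defaults: 64 bins per image,
bilinear interpolation of the floating image, PET upsampled to the CT
grid before optimisation. All three entropies come from the same
histogram, so the identity `mi = h_a + h_b - h_ab` holds to machine
precision and is asserted on random image pairs together with
`0 <= mi <= min(h_a, h_b)`.

The optimiser is Powell's direction-set method over `(tx, ty, theta)`
from the identity: each cycle line-minimises along the current
directions, then replaces the *first* direction with the cycle
displacement and line-minimises once along it. Two numerical safeguards:
the 1-D line search first brackets the minimum with a coarse 13-point
scan of `[-line_range, line_range]` before golden-section/parabolic
refinement (the section of the objective along a direction need not be
unimodal), and when a cycle stalls the direction set is restarted once
from the coordinate axes before stopping (always replacing the first
direction can make the set linearly dependent; the classical variant
replaces the direction of largest decrease instead, which we deliberately
do not use so that the replacement rule matches the method as specified).
Stopping tolerance is 1e-3 MI units with a 50-cycle guard; the per-cycle
best objective is non-increasing by construction.

## Candidate generation and watershed delineation

`detect_pet_candidates()` thresholds the SUV map at 2.5, labels connected
hot spots on the PET grid, maps each component into CT coordinates
through the registration transform, intersects it with the lung mask and
seeds one marker at the component's SUV-max pixel. `segment_nodule()`
crops a window of 1.5x the hot-spot bounding box (at least 16 px),
smooths it (sigma 1) and takes the Sobel gradient magnitude, quantized to
integer levels 0-255 over the window's min-max range.

Flooding is marker-controlled immersion: a bucket priority queue raises
the water level from the minimum gray level upward; a pixel joins the
basin of an adjacent labeled region when the level reaches its own
gradient value, and a pixel adjacent to two or more distinct basins at
its joining level becomes a 1-px dam. Ties on plateaus resolve in FIFO
order of discovery, making the result deterministic given marker order.
Connectivity is 8 for both flooding and dams. Interior seeds are the
hot-spot marker plus the 3 lowest-gradient pixels inside the hot-spot
support ("a plurality of seed points"); background seeds sit at the
lowest-gradient pixel of each window edge. `outer_boundary()` merges the
interior basins, dissolves dams completely surrounded by the merged
candidate, and returns the outermost dam as the closed segmentation
boundary; the ROI includes that dam ring, since the dams at the gradient
ridge *are* the lesion boundary. A brute-force priority-queue oracle
(naive flat-queue selection) reproduces the production flooding exactly
on hundreds of random small landscapes.

The level-nesting property (the basin at level `n` equals the final basin
intersected with the sublevel set) is asserted on radial cone landscapes,
where every sublevel component is connected to its marker. On landscapes
with marker-free pockets, a pocket floods only once the water reaches the
saddle connecting it to a marked basin, so its pixels join later than
their own gradient level and strict equality cannot hold for any
marker-controlled flooding; the snapshots still nest.

## Features

The GLCM is computed on the candidate's bounding rectangle filled from
the original image (not mean/median filled), quantized to 16 gray levels
over the patch range, distance 1, angles 0/45/90/135 averaged, symmetric
accumulation -- standard Haralick practice where the method leaves the
choice open. Features: contrast, correlation (marginal means/sds; if a
marginal is degenerate the correlation is undefined and reported as 0
with a flag), energy, homogeneity `sum G/(1+|i-j|)` (the standard form;
adopted because homogeneity is reported alongside the other four but no
formula accompanies it), and entropy in bits. A naive double-loop oracle
matches all five to 1e-10 on random patches.

SUVmax is taken over the watershed mask mapped through the registration
transform into native PET coordinates with nearest-neighbour sampling,
which preserves planted peak values exactly. SUVmean over the same region
is included as an optional extra column; SUVmax is the feature used by
the classifier and the baseline, the usual clinical convention.

## Classification and evaluation

The RBF-SVM is trained on z-scored features (scaler fitted on training
folds only). The outer loop is stratified 10-fold cross-validation
grouped by scan -- grouping prevents leakage when a scan contributes
several candidates, and with 219 candidates one per scan it reproduces
197/22 train/test splits (+/-1). An inner 5-fold grid search over
`C in {0.1, 1, 10, 100}` and `gamma in {0.01, 0.1, 1, 10}` picks
hyperparameters by accuracy. The SUVmax >= 2.5 rule is the baseline
classifier; on cleanly separated SUV ranges the cross-validated SVM must
not fall below it.

Detection evaluation: a candidate predicted malignant is a true positive
when its mask centroid lies inside a true malignant nodule on the same
scan (each nodule credited once); sensitivity is TP over true malignant
nodules, and false positives per scan is the count of unmatched positive
calls divided by the number of scans. The matching rule is a package
choice -- centroid-in-truth is strict enough for solitary nodules and
cheap to audit.

In `run_pipeline()`, candidates are labelled by the same matching rule
against the phantom truth. When both classes appear among the candidates
the SVM is evaluated by cross-validation; when the detection threshold
leaves only one class (the usual situation when benign uptake stays below
2.5, so benign nodules never become candidates), the pipeline falls back
to the SUV rule and records which classifier ran. Per-scan failures are
isolated: a failed scan is logged and skipped rather than aborting the
cohort.

## Problem sizes and runtime choices

The test suite exercises reduced 128-px phantoms for module tests and the
full 256-px phantom for acceptance-level checks: 20 random misalignment
recoveries (median error must stay within 1 px and 1 degree), 500 random
watershed-oracle comparisons, 100 MI-identity pairs, 50 GLCM-oracle
patches, and a 30-scan end-to-end benchmark that must reach sensitivity
>= 0.90 at <= 3 false positives per scan. `scripts/acceptance.R`
regenerates a 30-scan cohort from a command-line seed and recomputes the
headline quantities from scratch. These sizes are the package's chosen
trade-off between statistical stability of the stochastic checks and a
test suite that runs in minutes on one CPU.

## Known limitations

* Strictly 2-D: no volumetric flooding, 3-D GLCM, or 3-D registration.
* Rigid registration only; deformable motion is out of scope.
* The phantom's intensity statistics are parameter-driven, not matched to
  any scanner; clinical performance claims cannot be derived from it.
* The watershed's directional-penetration description is realised as
  immersion flooding bounded by gradient maxima; per-direction semantics
  beyond that are not formalised.
* Airway removal and juxtapleural boundary repair are not implemented.
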