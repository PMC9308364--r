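---
title: "Landmark-guided organ-at-risk autosegmentation on synthetic phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-guided organ-at-risk autosegmentation on synthetic phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oarseg` re-creates, at desk scale, the data flow of a landmark-guided deep
image-to-image autosegmentation system for radiotherapy organs at risk (OARs),
together with the full geometric formulary used to compare an automatic
contour (AUTO) against a manual reference (MAN). Because clinical planning CTs
and their expert contours are not available to a package of this kind, every
experiment runs on synthetic planning-CT-like phantoms with analytically known
ground truth. This vignette explains the models, the conventions, the tunable
parameters, and what the phantom experiments can and cannot show.

## The coordinate and grid model

All images live on regular axis-aligned grids in the LPS frame (+x left,
+y posterior, +z superior), the convention in which anatomical directions
("the inferior heart boundary") are unambiguous. A `volume_grid` stores voxel
intensities plus `spacing` (mm) and `origin`, the world position of the center
of voxel `(0,0,0)`; voxel indices are 0-based. Region-of-interest boxes are
half-open in world mm: a voxel belongs to a box iff its center does. These
choices make crop/resample round trips exact and testable.

Resampling to isotropic spacing `t` produces `ceiling(extent / t)` voxels per
axis with output voxel `(0,0,0)` centered at the input origin, conserving the
physical extent within one output voxel per axis. Images are interpolated
trilinearly; masks and label maps are resampled with nearest neighbor only —
never trilinear-then-threshold — so mask resampling is deterministic and
binary by construction. Out-of-bounds trilinear queries raise an error rather
than clamp silently, because silent clamping hides registration bugs.

NIfTI-1 files are read and written through their RAS affines, restricted to
axis-aligned positive-scale forms; oblique grids are rejected with a clear
error rather than silently resampled.

## The synthetic phantom

`phantom_spec()` describes a case: a thorax (left/right lung, heart) or pelvis
(bladder, rectum) phantom on a default 96 x 96 x 64 grid at 1.5 x 1.5 x 3 mm —
the anisotropy of a planning CT with 3 mm slice thickness. Organs are smooth
parametric solids (ellipsoids, plus a bent tube for the rectum) inside an
elliptical body cylinder, with per-tissue mean intensities on an HU-like scale
(air -1000, soft tissue +20, lung -750, heart +90, bladder +60, gas-filled
rectum -350) plus Gaussian texture and global noise. Parametric solids were
chosen over learned shapes deliberately: analytic volumes, centroids and
extreme points give closed-form oracles for every downstream test.

Organ sizes are the adult-scale volume targets (bladder 331, rectum 89, heart
569, left lung 1897, right lung 2220 ml) scaled by `size_factor^3`; the
default `size_factor = 0.4` keeps two lungs, a heart and a safety margin
inside the 144 mm field of view while preserving the relative organ scale.
Cohorts (`make_cohort()`) jitter the organ semi-axes by ±10% by default —
enough to make every case's shapes distinct while guaranteeing (by
construction, and asserted at generation time) that organs never overlap.

What the phantom does *not* emulate: CT physics (beam hardening, scatter,
metal artifacts), soft-tissue texture, anatomical pathology, or inter-patient
pose variation. Passing tests on phantoms therefore demonstrate that the
pipeline's *mechanics* — geometry bookkeeping, training loops, metric
formulas — are correct, not that the tiny networks would segment real CTs.

The contour-perturbation model (`perturb_mask()`) manufactures "AUTO-like"
masks with controlled error: a world-mm translation rounded to whole voxels,
then 6-connected dilation/erosion steps, then a smooth boundary displacement
field (white noise on a coarse lattice, trilinearly upsampled, rescaled to the
requested SD, applied through the signed distance function so the perturbed
surface stays smooth). It exists so that metric-recovery tests can dial in a
known error and check that the evaluation formulary reports it.

## The landmark agent

The automatic pipeline first finds a named anatomical landmark by *walking*
through the volume: the current state is a fixed-size image patch centered at
the current voxel, and a per-scale action scorer picks one of the six
axis-aligned unit steps. Training is supervised action classification: at
sampled positions the label is the step that maximally reduces the world-mm
(spacing-weighted) distance to the ground-truth landmark, with ties broken in
the fixed order -x, +x, -y, +y, -z, +z. This realizes the "walk so the
distance to the landmark is minimized" objective directly; no reward machinery
is needed because the optimizing target fully determines the labels, which
keeps desk-scale training deterministic and fast.

The search is multi-stage: the volume is resampled by factors 4, 2 and 1
(coarse to fine), and each stage walks greedily — one voxel of its grid per
step, so effectively 6/3/1.5 mm steps in-plane — until a position repeats.
A deterministic greedy walk that revisits a position is in a cycle, so the
first revisit is the natural stopping rule; of the two cycle positions the one
whose action distribution has higher entropy is kept, since at the landmark
the six actions become indistinguishable ("the action estimation converges").
One refinement proved necessary: the action that would immediately undo the
previous step is masked (unless it is the only feasible move). A purely greedy
walk freezes in a two-step cycle the moment it crosses a decision boundary of
the scorer — typically with error remaining on the other axes — whereas with
the backtrack masked it slides along the boundary and keeps correcting;
termination is still guaranteed because any longer cycle revisits a position.
The stopping position seeds the next finer stage; out-of-bounds actions are
masked so the walk can never leave the volume. Three stages rather than two:
with a 15^3 patch the factor-4 stage resolves position only to about one
coarse voxel (~6 mm), and the factor-2 stage bridges that gap to the fine
stage, whose field of view is only ~22 mm across.

The action scorer is a seeded one-hidden-layer perceptron (64 hidden units by
default) on the window-normalized patch, trained with Adam. Training positions
mix uniform coverage (coarsest stage) with a concentration near the landmark
(all stages), mirroring where each stage actually operates at detection time.

The anchor landmark each organ's ROI hangs on is configurable; the default is
the organ's *superior pole* rather than its centroid. The reason is visibility:
at the fine scale the patch around a centroid deep inside a homogeneous organ
is featureless, so no scorer — however trained — can localize it laterally,
whereas a boundary point always has local appearance (the surface dome) that
pins it down. Boundary points are part of the standard landmark vocabulary for
this task (organ center *and boundary* points); held-out action accuracy at
the fine scale roughly doubles when the anchor moves from the centroid to the
superior pole.

ROI statistics are fitted on a training cohort: per structure (an organ or an
organ group whose union bounding box is used), the offset of the bounding-box
center from the anchor landmark is averaged over cases, and the box size is
the per-axis maximum extent over cases plus twice a safety margin (default
10 mm — sized to absorb both shape variation beyond the training cohort and
the few-mm landmark detection error). `derive_roi()` then centers a box of
that size at `detected landmark + offset`.

## The segmentation network

The segmentation model is a 3D convolutional encoder-decoder operating on a
fixed-size crop: the encoder halves the spatial size per level with stride-2
3^3 convolutions (no max pooling — strided convolutions enlarge the receptive
field while shrinking the maps), the decoder upsamples with trilinear
interpolation, and at each level the encoder features are concatenated into
the decoder stream before a 3^3 convolution. Every convolution is followed by
batch normalization and a rectified-linear unit; a final 1^3 convolution emits
`N` channels — 1 for single-organ segmentation, `1 + number of organs` for
multi-organ. Intensities are clipped to a configured HU-like window (default
[-1000, 300]) and scaled to [0, 1] before entering the network.

Training minimizes per-voxel cross-entropy over softmax-normalized channel
scores with Adam. The default learning rate is 0.001, the production-scale
recipe; the desk-scale experiments bundled with the package train for only a
few hundred optimizer steps and therefore use 0.01, a step size matched to
that schedule. Prediction takes the per-voxel argmax with ties broken toward
the lower (background-first) channel; single-channel models threshold the
sigmoid score at 0.5. No training-time augmentation is applied by default, so
seeded runs are exactly reproducible.

Desk-scale defaults — 3 levels, channels (8, 16, 32), 48^3 input — are sized
so that a full training run stays in minutes on one CPU core. The network is
implemented in the package itself (im2col + BLAS convolutions, hand-derived
backward passes, compiled kernels), and its gradients are verified against
finite differences in the test suite.

The per-case flow (`segment_case()`) mirrors the production data flow: detect
the anchor landmark, derive the ROI, resample the ROI to a working grid (by
default the ROI extent divided by the model input size, i.e. the crop is
fitted to the network), predict, resample each organ mask back to the native
grid with nearest neighbor, and aggregate the per-organ masks into a single
multi-organ label map in which the earliest structure in the priority order
wins overlapping voxels. A landmark that fails to converge marks that route
failed while other routes proceed; an empty predicted organ is kept, with a
warning recorded.

## The evaluation formulary

All comparisons treat MAN as ground truth. Set sizes are voxel counts on the
shared grid. With `A` = AUTO, `M` = MAN:

- Sensitivity `|A∩M|/|M|`; Specificity `|Ā∩M̄|/|M̄|` over the full image grid
  (the only stated universe; the choice matters and is documented, not
  claimed); Jaccard `|A∩M|/|A∪M|`; Dice `2|A∩M|/(|A|+|M|)`;
  Discordance `1 − |M∩A|/|A|` (fraction of AUTO outside MAN); Geographical
  Miss Index `|M∖A|/|M|` (fraction of MAN missed).
- Volumes in ml (voxel count x voxel volume), their difference MAN−AUTO and
  ratio MAN/AUTO.
- Surface distances: the surface of a mask is the set of its voxels with at
  least one 6-connected face neighbor outside the mask or beyond the grid
  boundary (a mask touching the field-of-view edge still has a physical
  boundary there); distances are Euclidean mm between voxel centers,
  anisotropy-aware. MSD pools both directed distance lists,
  `(Σd(p,S′)+Σd(p′,S))/(n_s+n_s′)`; RMSD is the root of the pooled mean of
  squares; HD is the larger directed maximum; HD95 is the larger of the two
  directions' 95th percentiles, percentile by linear interpolation between
  closest ranks (rank `1 + q(n−1)`).
- Center-of-volume distance between occupied-voxel means.
- Six signed boundary differences: per anatomical direction, the extreme world
  coordinate of AUTO minus that of MAN at the same side, reported along the
  axis so that a positive value always means the AUTO boundary sits farther
  toward +axis (left/posterior/superior). The sign convention is the
  package's own documented choice; published tables often leave it ambiguous.

The production path computes directed surface distances with an exact
anisotropic Euclidean distance transform (separable lower-envelope algorithm
over squared distances); the test suite re-derives every metric with a
brute-force all-pairs/voxel-count oracle and requires agreement to 1e-6 mm.
Undefined metrics — any distance when a mask is empty, discordance when AUTO
is empty, sensitivity when MAN is empty — are carried as missing values
through reporting, never silently imputed as zero; cohort summaries
(`aggregate_cohort()`) report the mean and sample SD (n−1) over defined
values only, together with `n_usable` per structure and metric, mirroring
how usable-contour counts are bookkept in clinical evaluations.

## Numerical choices and degenerate inputs

- Resampling to the native spacing is a bitwise identity (the index ratio is
  computed so grid points map to exact integers).
- Trilinear interpolation of a constant volume is constant to ~1e-15 (the
  eight corner weights sum to 1 only in exact arithmetic).
- Nearest-neighbor index rounding uses `floor(i + 0.5)`, i.e. half-way points
  round up, deterministically.
- Mask translation in `perturb_mask()` rounds mm to whole voxels per axis;
  erosion that empties a mask is an error, not an empty result.
- The agent's oscillation tie-break (higher action-score entropy) is
  deterministic; a scorer that never oscillates within the step budget returns
  its last position flagged non-converged.
- Label-map aggregation with an empty input list is supported only through
  `empty_label_map()`, because a label map needs grid metadata.

## Problem sizes used by the bundled experiments

The experiments the package ships (test suite and `scripts/acceptance.R`) use:
10 training and 20 evaluation phantoms; agents with 15^3 patches, scales
(4, 2, 1), 300 sampled positions per case and scale; a 48^3-input network with
the default channels (8, 16, 32) for the 200-epoch single-case overfit check,
and a narrower (4, 8, 16) variant trained for 30 epochs over the cohort for
the end-to-end run; metric-oracle suites on 50 random mask pairs up to 20^3
voxels. These sizes keep a complete run comfortable on a single CPU core while
still exercising every component end to end. One capacity note informed them:
with only 4 first-level channels, the smallest foreground class (the heart,
~2% of crop voxels) can starve for some initialization seeds, while the
default width segments it reliably — hence the default width for the
capacity-sanity overfit, and the longer cohort schedule for the narrow net,
whose end-to-end role is dominated by the high-contrast lungs.

## Known limitations

- The networks are orders of magnitude smaller than production models; their
  phantom Dice scores say nothing quantitative about clinical performance.
- Landmark detection accuracy is reported against phantom ground truth; real
  anatomical landmarks (vessel bifurcations, bony structures) have appearance
  variation the phantom does not model.
- Only axis-aligned grids are supported; oblique acquisitions would need
  resampling upstream.
- Surface distances are voxel-center based; sub-voxel (mesh) surface
  distances are out of scope.
- The cohort generator draws organ shapes from one parametric family;
  distribution shift between "training" and "evaluation" cohorts is limited
  to seeded jitter.
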