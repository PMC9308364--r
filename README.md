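# oarseg

Desk-scale, fully seeded implementation of a landmark-guided deep
image-to-image autosegmentation pipeline for radiotherapy organs at risk
(OARs), together with the complete geometric formulary used to compare an
automatic contour (AUTO) against a manual reference (MAN). Everything runs on
synthetic planning-CT-like phantoms with analytically known ground truth, so
every number the package produces can be checked against a closed form or a
brute-force oracle.

It is written for people who work on contour evaluation and autosegmentation
plumbing — medical-physics and image-analysis developers who need a
transparent, dependency-light reference for:

- **Volume/mask geometry**: LPS world coordinates, voxel-center conventions,
  isotropic resampling, half-open world-space ROI crops, nearest-neighbor mask
  resampling, multi-organ label-map aggregation, NIfTI-1 I/O (axis-aligned
  affines only).
- **A synthetic phantom generator**: thorax (left/right lung, heart) and
  pelvis (bladder, rectum) phantoms with parametric organs at clinically
  scaled volumes, plus a contour-perturbation model (translation, 6-connected
  dilation/erosion, smooth boundary noise) for metric-recovery experiments.
- **A multi-scale landmark agent**: a per-scale action scorer walks one voxel
  at a time toward a named landmark (supervised against the
  distance-minimizing step), coarse to fine, and organ ROIs are derived from
  the detected anchor with statistics fitted on a training cohort.
- **A 3D encoder–decoder segmentation network**: stride-2 convolutions
  (no max pooling) in the encoder, trilinear upsampling and multi-level
  feature concatenation in the decoder, Conv+BN+ReLU blocks, softmax
  cross-entropy + Adam training, `N = 1 + number of organs` output channels
  for multi-organ heads. Implemented in the package (im2col + BLAS kernels,
  hand-derived backward passes) with gradients verified against finite
  differences.
- **The contour-comparison formulary**: volumes (absolute, difference, ratio),
  Sensitivity, Specificity, Jaccard, Dice, Discordance Index, Geographical
  Miss Index, center-of-volume distance, mean and residual-mean surface
  distance, Hausdorff distance and HD95, and six signed directional boundary
  differences — each with an exact distance-transform fast path and a
  brute-force oracle twin in the tests.

The core comparison quantities, for masks A (AUTO) and M (MAN) on a shared
grid:

    DSC  = 2|A∩M| / (|A|+|M|)         JCI = |A∩M| / |A∪M|
    Sens = |A∩M| / |M|                DisI = 1 − |A∩M| / |A|
    GMI  = |M∖A| / |M|                Spec = |Ā∩M̄| / |M̄|
    MSD  = (Σ d(p,S′) + Σ d(p′,S)) / (n_s + n_s′)
    RMSD = sqrt((Σ d(p,S′)² + Σ d(p′,S)²) / (n_s + n_s′))
    HD   = max(max d(p,S′), max d(p′,S));  HD95 analogous with 95th percentiles

with S, S′ the surface voxel centers (6-connectivity) and d(·,·) Euclidean
mm distances.

## Worked example

Generate a thorax phantom, manufacture a degraded "AUTO" heart contour with a
known error (translate 3 mm left + 4.5 mm posterior, dilate one voxel), and
evaluate it against the ground truth:

```r
library(oarseg)
ph <- generate_phantom(phantom_spec(seed = 1))
auto <- perturb_mask(ph$masks$heart,
                     perturbation_spec(translation = c(3, 4.5, 0),
                                       dilation_voxels = 1, seed = 2))
m <- evaluate_pair(auto, ph$masks$heart)
round(m[c("volume_man_ml", "volume_auto_ml", "volume_ratio", "dice",
          "sensitivity", "gmi", "msd_mm", "hd95_mm",
          "centroid_distance_mm", "boundary_superior_mm")], 3)
#>        volume_man_ml       volume_auto_ml         volume_ratio
#>               36.477               47.338                0.771
#>                 dice          sensitivity                  gmi
#>                0.785                0.901                0.099
#>               msd_mm              hd95_mm centroid_distance_mm
#>                2.788                6.185                5.421
#> boundary_superior_mm
#>                3.000
```

Reading the output: the phantom heart is 36.5 ml; dilation inflated AUTO to
47.3 ml (ratio MAN/AUTO 0.77). The translation of (3, 4.5) mm moves the
centroid by ~5.4 mm (the exact 5.41 mm = √(3²+4.5²) up to voxel rounding);
dilation costs discordance but not sensitivity loss beyond the translation
(GMI 0.10); the superior boundary moved +3 mm (one dilation step on the 3 mm
slice axis). A full cohort run — simulate, train the landmark agent and the
segmentation network, segment held-out cases, aggregate Table-style
per-structure summaries — is one call:

```r
res <- run_pipeline(run_config(region = "thorax", n_train = 10, n_eval = 20,
                               seed = 1), out_dir = "run_out")
subset(res$summary, metric == "dice")
```

which writes `per_case_metrics.csv`, `cohort_summary.csv` (mean ± SD with
per-metric usable counts) and a replayable `run_log.txt`.

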