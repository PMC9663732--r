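---
title: "Lesion-level detection of brain metastases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-level detection of brain metastases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmdetect)
```

## The problem

Brain metastases (BM) are the most common intracranial tumors. On
contrast-enhanced MRI they appear as compact enhancing foci; detecting all of
them is clinically decisive but tedious, because patients often carry many
small lesions. Black-blood (BB) imaging suppresses the signal of flowing
blood, so enhancing metastases stand out against dark vessels — but
suppression is imperfect, and residual bright vessel segments are the
dominant source of false positives for any automatic detector on this
contrast.

Slice-wise object detectors emit 2D bounding boxes, yet the clinical unit of
interest is the 3D lesion. `bmdetect` implements the scaffolding that turns
per-slice boxes into lesion-level results:

1. **Linking.** Boxes on slices whose indices differ by exactly 1 and whose
   2D intersection-over-union (IoU) exceeds 0.3 are recognized as the same
   lesion; lesions are connected components of this adjacency graph
   (union-find). Components confined to a single slice are excluded from
   training and evaluation — a metastasis of diameter >= 5 mm must be
   observed on two or more 3 mm slices, so single-slice findings are not
   credible lesions.
2. **Matching.** A predicted lesion certifies a ground-truth lesion when on
   *any one slice* a predicted box overlaps a ground-truth box with IoU >
   0.5 (the one-slice true-positive rule: detecting part of a lesion is
   enough to direct the reader's attention). Matching is greedy one-to-one
   by descending best-slice IoU, so one prediction cannot certify two
   lesions.
3. **Metrics.** With lesion-level counts TP, FN, FP over N scans:
   sensitivity = TP/(TP+FN), precision = TP/(TP+FP),
   F1 = 2TP/(2TP+FN+FP), FP~avg~ = FP/N. Rates are kept as exact ratios
   internally and rounded (2 dp) only in report rendering. Reports also
   carry `f1_half` = TPR*PPV/(TPR+PPV), exactly half the harmonic-mean F1,
   because published detection tables sometimes print this variant;
   the package's F1 is always the standard harmonic mean.

## Why a phantom cohort

The framework is exercised end-to-end on synthetic volumes: clinical BB
cohorts are private, and a trained detection network is not part of this
package (see below). The phantom generator is therefore a first-class,
tested module, not a test fixture. Each scan contains:

- a smooth ellipsoidal **brain** of unit tissue intensity, surrounded by a
  dark CSF gap (>= 5 mm everywhere, built from ellipsoids offset in metric
  units) and a bright skull rim;
- **lesions**: hyperintense balls (default 3x tissue) with diameters drawn
  uniformly from [5, 25] mm. The 5 mm floor mirrors the clinical inclusion
  rule; the uniform shape is a modeling choice, not a claim about the
  clinical size distribution, for which no usable statistics are published.
  Default 5 lesions per scan, matching the mean burden of a metastasis
  work-up cohort (~585 lesions across 113 scans). Centers are rejected and
  resampled until the lesion shows a cross-section of radius
  `max(1 mm, half the pixel diagonal)` on at least two slices — the
  phantom counterpart of "observable over two or more slices", and the
  precondition that makes noise-free recovery well-posed at any resolution;
- **vessels**: random-walk tubes (radius 1–1.5 mm) stamped at lesion-like
  intensity along one contiguous *unsuppressed* run covering
  `1 - vessel_suppression` of their length. The `"bb"` preset (suppression
  0.85) leaves short bright residues, emulating insufficiently suppressed
  vessels; the `"gre"` preset (suppression 0) leaves vessels fully bright,
  qualitatively emulating gradient-echo contrast. Vessel and lesion masks
  are disjoint by construction;
- additive Gaussian noise (default sigma 0.05 of tissue mean), applied
  after the analytic truth boxes are computed. Gaussian (rather than
  Rician) noise is a deliberate simplification: the purpose is to exercise
  detection logic, not to simulate MR physics. Bias fields, k-space
  artifacts and anatomy are likewise out of scope, so a pass on phantoms
  shows the *framework* is correct, not that any detector generalizes to
  clinical data.

The default grid is 40 slices of 256 x 256 at 0.9 x 0.9 mm — half the
clinical 512 x 512 / 0.45 mm axial matrix with the same physical field of
view and the same 3 mm slices, chosen to keep a full cross-validation run
on a laptop-class single core in minutes; `clinical_geometry = TRUE` restores
the full matrix. Every scan derives its own RNG seed from the master seed
and scan index, so cohorts are reproducible and order-independent;
identical seeds give bit-identical volumes.

## Preprocessing

Clinical pipelines skull-strip with a dedicated brain-extraction tool and
then normalize each slice's intensities to [0, 1]. Here:

- **Brain extraction** is a threshold-and-morphology extractor designed for
  the phantom contract (bright rim, dark gap): global Otsu threshold,
  largest 3D connected component (per-slice 4-connective labeling merged
  across adjacent slices by voxel overlap), per-slice closing (disc radius
  2 px) and hole filling. Because the rim is separated from tissue by the
  dark gap, it forms its own component and is discarded without any
  erosion step; avoiding erosion also makes the extractor an exact fixed
  point on already-stripped noise-free volumes. On phantoms the extracted
  mask agrees with the analytic ellipsoid at Dice > 0.99.
- **Normalization** min-max maps each slice's *brain* voxels to [0, 1];
  background stays 0, and degenerate slices with constant brain intensity
  map to 0 rather than NaN. Restricting the range to brain voxels keeps
  the map informative (background zeros would pin the minimum). The
  normalization is invariant to per-slice affine intensity changes, and —
  as on clinical data — it inflates false positives on lesion-free scans,
  because the brightest structure of a normal slice is stretched to 1
  regardless of its absolute enhancement. The package reports this
  (`fp_avg_normal`); it does not correct it.

## The detector is an interface

The contribution this package implements is everything *around* the
detector: the trained network of a clinical deployment (a YOLO-style
single-shot detector with transfer-learned backbone, seven anchor boxes,
rotation/flip augmentation) is GPU-scale and bound to private data, so it
is deliberately not reimplemented. The package ships:

- a **deterministic reference detector**: per-slice threshold on normalized
  intensity within the brain mask, connected components, area gates derived
  from the 5 mm lesion floor (minimum: the area of a 1 mm-radius disc;
  maximum: 1.2x the equatorial area of a 25 mm lesion), and a circularity
  gate `4*pi*area/perimeter^2 >= 0.4` that rejects elongated vessel
  residues — the geometric stand-in for what a trained network learns about
  vessel shape. The perimeter estimate (EBImage boundary-pixel count)
  undercounts smooth contours, so circularity is clamped to [0, 1]; the
  gate is a lower bound, so the clamp is conservative.
- the **detector-support utilities** a trainable detector needs:
  `augment()` (the 0/90/180/270-degree rotation and left-right flip group,
  applied to image and boxes by the same isometry), and
  `estimate_anchors()` (k = 7 anchor shapes by Lloyd k-means under the
  `1 - IoU` distance of co-centered boxes, farthest-point initialization,
  anchors sorted by area). The augmentation sampling policy and the anchor
  estimation method are design choices of this package; rotation is
  defined clockwise and flips follow rotation.
- **calibration**: `calibrate_detector()` grid-searches detector
  configurations and returns the one maximizing pooled lesion-level F1 on
  the training scans (ties: lower FP per scan, then lower threshold). This
  plays the role of training inside the cross-validation harness and
  preserves its train/test discipline. The default grid crosses intensity
  thresholds {0.55, 0.7} with circularity gates {0.35, 0.5, 0.65}: the
  threshold governs how far into the stretched noise tail the detector
  reaches (the dominant failure mode on normalized lesion-free slices),
  the circularity gate how aggressively elongated residues are rejected.

Any detector — including a learned one — can replace the reference
implementation as long as it maps (normalized volume, mask) to a box table;
every downstream module is unchanged.

## Cross-validation harness

`kfold_split()` shuffles scan ids under a seed and deals them round-robin,
so fold sizes differ by at most one (113 scans in 5 folds: 23/23/23/22/22).
`run_crossval()` calibrates on each fold's complement and scores the
held-out fold; lesion-free scans are scored by *all* k calibrated models
and their FP per scan averaged, mirroring the protocol of evaluating a
normal cohort under every cross-validation model. Detections for each
(scan, configuration) pair are computed once and reused across folds —
calibration only aggregates counts from its own training scans, so the
information flow is identical to per-fold recomputation. Reports are
byte-identical across reruns with the same cohort, seed and grid.

Degenerate folds are surfaced, not masked: a fold with no predicted lesions
has undefined precision, carries `NA` with `valid = FALSE` in the report,
and pooled counts still conserve TP + FN = number of ground-truth lesions.

## Numerical and tie-breaking choices

- Boxes are half-open real rectangles `[x, x+w) x [y, y+h)` in 0-based
  pixel coordinates (`x` columns, `y` rows), so area is exactly `w*h` and
  IoU is exact rational arithmetic in doubles.
- Both decision thresholds are strict inequalities as printed: linking
  requires IoU > 0.3, matching IoU > 0.5.
- "Adjacent" means a slice-index difference of exactly 1 — no gap
  tolerance. Predicted lesions pass the same `min_slices = 2` filter as
  labels (configurable), so single-slice detections never reach FP
  counting.
- Lesion numbering orders components by their lexicographically smallest
  `(slice_index, y, x)`; greedy matching breaks IoU ties by ground-truth
  then predicted lesion number. Both rules exist only to make outputs
  deterministic under permutation.
- Undefined rates (0/0) raise errors in the metric functions and become
  `NA` + `valid = FALSE` in pooled reports; they are never reported as 0.

## Problem sizes used by the test-suite and acceptance script

Module tests run on 24-slice 128 x 128 phantoms (1.8 mm pixels, same field
of view). The end-to-end checks run the default 256 x 256 x 40 geometry: a
10-scan noise-free mini-cohort (2 lesions per scan, k = 2) must recover
every planted lesion (pooled sensitivity 100%), and a 30-scan cohort at
noise sigma 0.05 under the default grid must stay within the regression
band sensitivity >= 85% and FP per scan <= 20 — a synthetic analogue of a
clinically plausible operating point, not a reproduction of any clinical
result. The acceptance script runs a 20 + 8-scan cohort at the same
geometry; these sizes were chosen so a complete run stays in the minutes
range on one core.

## Known limitations

- Phantom realism: no anatomy, no bias fields, Gaussian noise, piecewise
  constant intensities. Detection difficulty is dominated by the
  normalization-stretched noise tail and vessel residues, which is the
  right failure mode qualitatively but not quantitatively comparable to
  clinical data.
- The reference detector has no learned component; its absolute
  performance is meaningful only on phantoms.
- Greedy matching is not guaranteed optimal for adversarial overlap
  patterns; on non-overlapping lesions (the phantom contract and the
  typical clinical case) it equals brute-force optimal matching, which the
  test-suite verifies by enumeration on small scans.
- Fold assignment is unstratified (seeded random); lesion-count
  stratification is not implemented.
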