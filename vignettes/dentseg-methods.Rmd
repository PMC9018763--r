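---
title: "Morphology-guided tooth and alveolar bone segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-guided tooth and alveolar bone segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cone-beam CT (CBCT) is the standard 3D imaging modality in digital
dentistry. Treatment planning needs two kinds of masks from a scan: one mask
per individual tooth, numbered in the FDI two-digit scheme (quadrant 1–4 ×
position 1–8), and masks of the two alveolar bones (midface/maxilla and
mandible). Manual delineation takes hours per scan; `dentseg` implements a
fully automatic two-branch pipeline that produces both, together with a
synthetic phantom generator that makes every stage testable on a desk-scale
CPU budget.

The tooth branch is *hierarchical and morphology-guided*: teeth are first
detected as objects via centroid voting, then each detected tooth is
segmented individually in a small crop, guided by its predicted centroid and
skeleton. The bone branch enhances thin bone boundaries with a 3D Haar
detail filter before a cascaded three-class segmentation. Overlapping claims
between branches are fused by comparing predicted probabilities.

## Pipeline stages and their models

**Preprocessing.** Scans are resampled to an isotropic working resolution of
0.4 mm (trilinear for intensities, nearest-neighbor for labels; output shape
is `round(shape * spacing / target)`), clipped to the intensity window
[0, 2500] to suppress metal-artifact extremes, and rescaled to [0, 1]. The
clipping bounds are treated as raw input units, not calibrated Hounsfield
units.

**ROI localization.** A small encoder–decoder predicts a binary
tooth-foreground probability; components above 0.5 with at least 20 voxels
define a bounding box, dilated by a 4-voxel margin, inside which the tooth
branch operates.

**Offset voting and clustering.** Two networks regress, for every foreground
voxel, a 3D offset vector pointing to (a) the tooth's centroid and (b) the
nearest voxel of the tooth's skeleton. Each foreground voxel casts a vote at
`p + offset(p)`. Centroid votes are clustered by density peaks: the local
density `rho_i` counts votes within a cutoff radius `dc`, `delta_i` is the
distance to the nearest denser vote, and cluster centers are votes with
`rho >= peak_min_density` and `delta >= peak_min_sep` (the globally densest
vote is always an eligible center — the densest point must seed a cluster,
so a single tight vote blob yields one tooth); remaining votes inherit the
label of their nearest denser neighbor. Defaults (`dc = 2`
voxels at the 0.4 mm scale, `peak_min_density = 20`, `peak_min_sep = 5`)
were chosen once from the phantom geometry: `dc` is about half a tooth
radius, the density floor is well below the vote count of the smallest
tooth, and the separation floor is below the smallest inter-centroid
distance. Ties in density are broken by point index, which makes the
procedure deterministic and permutation-invariant as a partition.

**Single-tooth segmentation.** Each instance yields a three-channel crop —
a unit-peak Gaussian centroid heatmap, the instance's skeleton channel, and
the image — segmented by a multi-task network with mask, boundary and root-apex
heads plus a 32-class FDI classifier (global average pooling over the
bottleneck, three fully-connected layers). The sigmoid mask is thresholded
at 0.5 and restricted to its largest connected component. The skeleton
channel is a *vote-density* map: skeleton votes (grouped per instance by the
centroid clustering) are accumulated with multiplicity, smoothed, and
normalized to peak 1, so positions many voxels agree on dominate while
stray votes fade. A provisional
arch-position heuristic (upper/lower split at the detection z-midline,
positions ranked by distance from the x midline) provides FDI codes when the
classifier is disabled; by default the classifier overrides it.

**Paste-back.** Crops are pasted at their origins; voxels claimed by two
instances go to the higher per-voxel probability, exact ties to the lower
FDI code. Duplicate FDI codes are kept as distinct instances (disambiguated
in a parallel instance-id volume) and reported.

**Bone branch.** A one-level 3D Haar decomposition on 2×2×2 blocks yields
seven detail subbands; the enhancement map is the sum of their absolute
values, upsampled to the input grid and normalized to [0, 1] by its maximum.
This is a coefficient-magnitude map, not a filtered reconstruction — the
choice concentrates response tightly (within two voxels) around intensity
discontinuities, which is the property the bone network needs. The cascade
is two networks: the first consumes (image, enhanced) and produces coarse
3-class probabilities; the second consumes (image, enhanced, coarse
probabilities) and outputs the refined softmax, argmaxed into
{background, midface, mandible}.

**Fusion.** Where tooth and bone claims overlap, the voxel keeps the label
of the branch with the higher probability; exact ties go to the tooth
branch (teeth are the rarer, more safety-critical structure).

## The network engine

No deep-learning framework is part of the package's dependency set; the
volumetric encoder–decoder is implemented directly (R orchestration over
compiled convolution kernels). The backbone has `levels` resolution scales
with channel doubling, 3×3×3 convolutions with leaky-ReLU activations (slope 0.1; plain rectifiers in very narrow nets risk irrecoverably dead units), 2× average-pool
downsampling, nearest-neighbor upsampling with skip concatenation, and
1×1×1 per-head output convolutions. Losses: binary cross-entropy for
sigmoid mask heads; mean squared error for offset, boundary and apex heads
(offsets averaged over foreground voxels only — an empty foreground
contributes zero, not NaN); softmax cross-entropy (optionally
class-weighted) for the bone heads and the FDI classifier. Optimization is
Adam at learning rate 0.001 with mini-batch size 1 by default. Training
stops when the best validation loss has not improved by more than a
tolerance (default 1e-4; "unchanged" is otherwise ill-defined in floating
point) for 5 consecutive epochs. Boundary and apex maps use sigmoid outputs
under an L2 loss so that all dense outputs live in [0, 1].

Gradient steps can be clipped to a global L2 norm (the desk study uses 5):
with mini-batches of one sample, an occasional extreme gradient can
otherwise derail a tiny network irrecoverably.

Initialization, data order and all stochastic choices are driven by
explicit seeds; repeated runs are bit-identical.

## The phantom generator

The generator emulates the structure of a dental CBCT at adjustable grid
sizes: two parabolic arch curves in fixed z-slabs carry 4–16 teeth per arch
(ellipsoidal crown fused with a tapered root cone; molars scaled larger
than incisors), surrounded by arch-shaped bone bands, over a soft-tissue
background. Raw intensities (soft tissue 500, bone 1100, teeth 1900, on the
0–2500 clipping scale) reproduce the clinical ordering teeth > bone > soft
tissue. Ground truth is complete: FDI-coded instances, centroids, thinned
skeletons, boundary and apex target maps, and 3-class bone labels; tooth
and bone ground truths are disjoint by construction.

The three abnormality classes seen in clinical material are modeled as:
slots dropped with probability `missing_prob` (missing teeth); per-tooth
position jitter and axis tilt (misalignment); and saturated inserts at
`metal_intensity >= 2500` with radial intensity streaks (metal artifacts).

What the phantoms deliberately do not model: CT physics (beam hardening,
scatter, reconstruction artifacts beyond the stylized streaks), anatomical
tooth shape variation (multi-rooted molars, curved roots), contact between
adjacent teeth, and intensity inhomogeneity. Passing tests on phantoms
therefore demonstrates the correctness and trainability of the pipeline
machinery, not clinical-grade accuracy; the reported full-scale numbers on
patient data are out of this package's scope.

Skeleton ground truth uses sequential 3D thinning (simple-point deletion
with six directional subiterations, endpoints preserved) rather than a
distance-transform ridge: thinning guarantees a connected, ≤2-voxel-wide
curve, both of which are directly testable. Boundary/apex regression
targets are unit-peak Gaussian maps (σ = 1.5 voxels by default) — L2
regression needs smooth support, and the encoding is an artifact decision
since only the supervision tasks themselves are prescribed.

## Desk-scale study conditions

All experiments in the test suite and the acceptance script run on one CPU.
The study conditions, fixed once:

* Phantoms: 48³ voxels at 0.4 mm, 6 teeth per arch, `missing_prob = 0.15`,
  misalignment jitter (1 voxel, 4°), a metal insert in every fifth phantom,
  noise σ = 0.02 of the intensity window. Oracle-identity checks use 64³ /
  8 teeth per arch.
* Networks: levels 2, base 4 channels, one convolution per stage, 24³
  training crops (the bone networks use levels 3 — their receptive field
  must span the occlusal gap to tell midface from mandible; tooth-level
  tasks are local and don't need it). Inference tiles volume networks at
  the full 48³ (the networks are fully convolutional), eliminating window
  seams.
* Training: 30 phantoms (25 train / 5 validation), 10 held-out test
  phantoms; Adam with learning rate 4e-3 (the tiny desk networks tolerate
  and need a larger step than the full-scale default of 1e-3), gradient
  norm clipped at 5; 12 epochs cap (16 for the cheap single-tooth
  network), patience 5. Offset targets are scaled by 0.2 during training
  so the regression lives near unit magnitude, and predictions are
  rescaled transparently at inference. Bone cross-entropy uses class
  weights (1, 3, 3) against background dominance. The FDI classifier head
  is down-weighted (0.3) so it cannot swamp the mask task early in
  training.
* The single-tooth network is trained *stage-wise on predicted inputs*:
  after the first-stage networks are fitted, training crops are built from
  their actual detections (predicted centroids and skeleton votes), with
  targets from the ground-truth tooth matched to each detection. Training
  on ground-truth-derived channels instead leaves the network calibrated to
  inputs it never sees at inference — in early experiments that
  train/inference gap made the skeleton channel actively harmful.
* The "paper" preset (256³ ROI patches, 96³ tooth crops) is retained as
  configuration only; it is intended for full-scale hardware.

**Evaluation conventions.** Dice = 2|R∩G|/(|R|+|G|); two empty masks have
Dice 1 (needed for missing-tooth cases). Sensitivity = |R∩G|/|G|, undefined
(NA) for empty G. ASD extracts surfaces as mask minus its 6-connectivity
erosion and averages the two directed mean surface distances — the
symmetric form; distances are physical and anisotropy-aware (exact
separable Euclidean distance transform). For the learned desk-scale
pipeline, per-tooth quality is summarized as *instance-matched* mean Dice
(greedy maximum-overlap matching of predicted instances to ground-truth
teeth): at this scale the 32-class FDI classifier sees nearly
indistinguishable synthetic crops, so pairing masks by FDI code would
measure numbering rather than segmentation. Oracle-identity checks do
compare FDI codes exactly.

## Numerical choices and degenerate inputs

* All sigmoid masks threshold at 0.5; per-tooth masks keep the largest
  26-connected component.
* Density ties in clustering break by point index; instances are sorted by
  centroid so downstream processing is order-independent.
* Offset L2 is computed only over ground-truth foreground; empty
  foreground contributes 0.
* `clip_normalize` requires `hi > lo`; resampling requires a positive
  target spacing; empty masks are errors for skeletonization, ASD and
  boundary/apex derivation, but *absent labels* in evaluation produce NA
  rows rather than errors.
* The Haar map of a constant volume is exactly zero (the axis-sequential
  transform cancels exactly); normalization divides by the maximum only
  when it is positive.
* Windows are half-open, z-major ordered; the last window per axis abuts
  the volume boundary, and overlapping probabilities are averaged.

## Known limitations

* The phantom's geometric simplicity means desk-scale accuracy figures do
  not transfer to clinical data; they demonstrate trainability and
  correctness of the machinery only.
* The FDI classifier is near-chance at desk scale (see above); on real
  data it would require the full 96³ crops and far more training.
* Density-peaks clustering is O(n²) in the number of foreground voxels;
  acceptable inside a desk-scale ROI, quadratic at full scale (the
  full-scale setting would subsample votes).
* One-level Haar enhancement localizes to 2-voxel blocks; deeper
  decompositions would respond to coarser structures but blur
  localization.
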