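---
title: "Classifying epithelial spheroid polarity: models, features and design choices"
author: "spheropol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying epithelial spheroid polarity: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheropol)
```

## The classification problem

Monolayered epithelial cell spheroids (cysts) grown in 3D culture are the
simplest lumen-containing epithelial structure and a standard readout for
epithelial morphogenesis. A spheroid imaged as a four-channel fluorescence
z-stack — basolateral membrane marker (gp58), apical membrane marker
(gp135/podocalyxin), F-actin and nuclei — falls into one of three polarity
phenotypes:

* **group 1, regular apicobasal polarity**: a single central lumen, apical
  marker and a pronounced actin belt lining the lumen, basolateral marker
  facing outward, nuclei arranged in a ring between lumen and surface;
* **group 2, inverse polarity**: apical marker and actin ring at the
  periphery, basolateral (matrix-filled) interior;
* **group 3, aggregates**: either no lumen (nuclei occupy the core) or
  several small lumina. For the convolutional branch the two sub-phenotypes
  are kept as separate labels (`3a_aggregate`, `3b_multilumen`) and
  collapsed to group 3 for reporting, which in our hands (as in the
  original rating practice) makes the four-class problem easier to learn
  than a heterogeneous three-class one.

Manual rating of such stacks is slow (~80–100 spheroids per hour per
trained rater) and bias-prone; this package implements the two supervised
routes that replace it — an engineered-feature decision-tree pipeline and a
small transfer-learning-style convolutional branch — plus the
interrater-agreement statistics used to validate either against human
raters, and a synthetic stack generator so the entire system is testable
without microscope data.

## The equatorial-plane reduction

Spheroid polarity is radially symmetric at the equatorial plane, so all
feature extraction happens on a 2D projection of the central z-slices:

1. the central plane `z*` maximises the spheroid cross-section (voxels
   above a per-channel global Otsu threshold, any channel, after
   per-channel background subtraction);
2. the projection is a per-channel **maximum-intensity projection** over
   `n_slices = 5` planes centred on `z*` (≈1.2 µm at the 0.24 µm z-step
   the defaults assume). The projection type and slice count are free
   choices; a maximum over a thin central window is robust to the exact
   `z*` pick and keeps thin rings bright.

**Spheroid support.** Each channel is background-subtracted (its
5th-percentile *order statistic*, floored at 0) and thresholded with Otsu's
method on its own; the support is the union of the per-channel masks,
hole-filled, largest connected component. Two deliberate choices here:

* *Per-channel thresholds, then union* — a mask built from the summed
  channels moves when one detector's gain changes; per-channel thresholds
  make the support (and every feature downstream) invariant to positive
  per-channel rescaling, which is also a property the test suite asserts
  bit-exactly.
* *Hole filling before component selection* — an outer marker ring around a
  darker interior (inverse spheroids; empty lumina) must fill to its full
  disc rather than survive as an annulus, otherwise the interior markers
  fall outside the support.

The centre of mass is the **area centroid of the binary support** (not an
intensity-weighted centroid, for the same gain-invariance reason), and the
maximum radius `r_max` is the largest rounded pixel distance from it over
support pixels.

## The polar transformation and the 15 features

Every pixel is assigned an integer radius bin

    radius(x, y) = round( sqrt((x − X_com)² + (y − Y_com)²) )

with **half-away-from-zero** rounding — written out because banker's
rounding changes bin membership along the half-integer shells. Per bin the
channel intensity is summed and divided by the number of pixels at that
radius, so a thin bright ring and a broad annulus with equal per-pixel
brightness contribute equally; the per-radius means are normalised by the
channel total and accumulated into the cumulative radial intensity curve
(non-decreasing, ending at 1). Profiles are computed on
background-subtracted projections; without that, the constant camera
background drags every positional feature toward the uniform-disc value.

Positional summaries read off the curves:

* the relative **radius at 60% of total intensity** per channel, refined by
  linear interpolation between the bracketing bins (a step readout
  misstates the centre of the curve's linear rise; note the interpolated
  readout sits up to one bin width below a pure delta ring's position);
* the **nuclear initial slope**: cumulative nuclear intensity at 30% of the
  spheroid radius divided by 0.3 — ~0 for an empty lumen, ~1 for nuclei
  spread uniformly, >1 when nuclei pack the core (no lumen);
* the marker differences `Δgp58−gp135` (positive ⇒ regular polarity,
  negative ⇒ inverse) and `Δactin−gp135` (≈0 for distinct polarity, large
  for undefined polarity).

The full 15-feature vector is: the two marker deltas (f1, f2); the four
per-channel 60% positions (f3–f6); spheroid, nuclei and actin-belt
circularity (f7, f8, f12); the nuclear slope (f9); relative actin area and
particle count (f10, f11); nuclei count (f13); the distance between nuclear
and spheroid centres of mass relative to `r_max` (f14); and `r_max` in µm
(f15). Identities `f1 = f3 − f4` and `f2 = f5 − f4` hold exactly. Only
seven of the fifteen slots have canonical published definitions (f1, f2,
f8, f9, f10, f11, f14); the remaining slots are this package's
reconstruction from the named per-channel positions and shape descriptors
and should not be quoted as the original tool's exact list.

Shape-descriptor conventions, stated because the values depend on them:

* circularity is `4πA/P²` clipped to [0, 1] with the perimeter estimated
  from the Freeman chain code of the object contour (axial steps count 1,
  diagonal steps √2) — a rasterised disc of radius 30 px scores ≈0.92;
* the **actin belt** comprises pixels above the 90th-percentile order
  statistic of the masked actin channel; particles are 8-connected
  components of ≥10 px; belt circularity is that of the largest particle,
  so a single continuous ring reports (low) annulus circularity;
* **nuclei** are segmented by Otsu threshold inside the support and split
  with a distance-map watershed; objects ≥9 px count. Nuclei circularity
  is that of the segmented union's convex hull — it measures how circularly
  the nuclei are *arranged* (ring vs clump), which is the lumen signal the
  classifier needs.

### Numerical determinism

The pipeline is engineered so that a 90° rotation of the input stack (a
pure pixel permutation) and any power-of-two per-channel rescaling
reproduce all 15 features *bit-identically*: quantiles are order
statistics, Otsu works on a fixed 256-bin histogram over [0, max],
perimeters are computed from integer chain-code step counts, the hull
perimeter sums its segment lengths in sorted order, and synthetic
intensities are integer-valued so all image sums are exact. Degenerate
inputs are defined, not improvised: an all-zero channel yields a flat
cumulative curve flagged `zero_signal` (positional readouts refuse it with
an error), an empty actin belt reports zero area/count/circularity with a
warning, and an empty nuclei segmentation is an error.

## The decision-tree branch

A deliberately *complex* (unpruned) CART tree — Gini impurity, minimum leaf
size 3, no depth cap — is trained on the subset of features 1, 2 and 6–15
with stratified 20-fold cross validation guarding against overfitting; the
reported `cv_accuracy` is the pooled held-out accuracy. The tree is grown
by `rpart` and exported into a plain nested-node structure (split feature,
threshold, children, leaf class distributions) that the package descends
deterministically and serialises to a self-describing JSON document.

Because the hardest confusions are group 1 vs group 3, a **second
classification step** re-evaluates records predicted 1 or 3 with a tree
trained only on group-1/3 samples using the lumen descriptors (f8, f9, f13,
f14); group-2 records pass through untouched and every changed label is
flagged. Whether the original workflow used a rule or a second tree is not
documented; a second trained tree was chosen as the more general mechanism.

The **bagged ensemble** trains `n_trees = 30` trees on seeded bootstrap
resamples, votes by majority with ties broken toward the lower group number
(documented, configurable at the record level by reordering `classes`), and
reports out-of-bag accuracy. Impurity-decrease **feature importance**,
summed over a bagged ensemble and normalised to 1, supports choosing the
predictor subset. Hyperparameter search is reduced to the `min_leaf`
argument; the default (3) was fixed a priori with the rest of the control
grid and is not tuned by the package.

## The convolutional branch

Equatorial projections are reduced to 8-bit RGB — basolateral marker to
green, nuclei to blue, apical marker *or* actin to red — with per-image,
per-channel min–max rescaling to 0–255 (floor rounding). Whether the
original conversion scaled globally or per image is unstated; per-image
scaling was chosen because it is deterministic and normalises staining
batches away.

At desk scale the backbone is a small **fixed random-feature convolutional
network**: two conv/ReLU/max-pool stages (12 then 24 filters, He-initialised
from a fixed seed, ~5k weights) whose flattened activations are standardised
and fed to the replaced head — one trainable dense ReLU layer (96 units)
plus a softmax output. The backbone is frozen and only the head is trained,
mirroring the transfer-learning recipe of retraining the final
classification layers; with images this structured, fixed random
convolutional features are an adequate representation, and nothing in the
API precludes swapping in a pretrained backbone where one is available.
Training follows the package defaults: **SGDM (momentum 0.9), 15 epochs,
batch size 80, learning rate 3×10⁻³**, with a seeded stratified 20%
internal-validation holdout (the split fraction is a package choice). The
batch size auto-reduces when the training set is smaller than one batch.
Images are resized bilinearly to the 32×32 backbone input.

**Augmentation** balances every label to exactly 600 images by random
rotation (45–315°) and isotropic scaling (0.4–1.2) of the originals
(originals retained, transforms sampled uniformly, results cropped or
padded back to frame size). Class balance, ranges and the 600-per-label
target are the conditions the training schedule assumes.

## Agreement statistics

Validation against human raters uses the cross-correlation table of two
raters' labels. Percent agreement is the diagonal share, reported to one
decimal (half away from zero). Cohen's κ is `(po − pe)/(1 − pe)`; its
standard error is the large-sample delta-method estimate of Fleiss, Cohen
and Everitt (1969) — the script the original workflow calls does not print
its formula, so the choice is stated here and checked in the test suite
against a multinomial Monte Carlo oracle rather than against any single
worked example. The confidence interval is `κ ± z₁₋α/₂·SE` clipped to
[−1, 1]. Interpretation bands follow the conventional scale (≤0 none,
0.01–0.20 slight, 0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80
substantial, 0.81–1.00 almost perfect). Recall and precision are reported
for group 1 (truth on the rows). The three-rater workflow is implemented as
pairwise tables plus a strict-majority consensus resolver; items without a
majority are flagged unresolved, since resolving them is the human
discussion step. Multi-rater coefficients (Fleiss' κ, Krippendorff's α) are
out of scope.

## The synthetic generator

The generator draws labelled four-channel stacks with the geometry that
*defines* the phenotypes: group 1 with apical + actin rings at the lumen
boundary (lumen radius 0.3–0.5 of the spheroid radius), basolateral outer
ring plus faint lateral signal, nuclei on the mid-ring; group 2 with
apical/actin at the surface and basolateral interior; group 3a with
centre-weighted scattered nuclei and incoherent low-contrast markers (so
the marker deltas concentrate near 0); group 3b with 2–4 small
apical/actin-ringed lumina placed on an inner ring at evenly spaced jittered
angles (which guarantees the drawn number of distinct, well-separated
rings). Defaults mirror the imaging conditions the package targets: 256×256
px frames, 50 z-planes at 0.24 µm, spheroid radii 40–80 px, 12–24 nuclei
(one per cell).

Imaging is emulated by an isotropic in-plane Gaussian PSF (σ = 2 px) —
z-resolution enters only through a spherical-cap intensity modulation of
the plane templates, since all downstream analysis is equatorial — plus the
standard fluorescence camera noise model: constant background (20 counts),
Poisson shot noise (gain 1) and additive Gaussian read noise (σ = 4
counts), all seeded, with intensities rounded to integer counts in the
16-bit range. Peak marker amplitude is 1000 counts, a mid-range SNR for
wide-field stacks.

What the generator does *not* emulate — cell-to-cell texture, membrane
curvature, staining heterogeneity, optical aberrations, batch effects —
bounds what passing tests mean: they demonstrate that the pipeline recovers
the phenotype geometry it was designed around, not that any particular
accuracy transfers to microscope data. The original study's observation
that engineered-feature classifiers degrade across experimental batches
while CNNs degrade less cannot be reproduced here, because the generator
has no batch-to-batch variation model.

## Problem sizes used by the tests

The synthetic defaults above are the full-scale study conditions. The test
and acceptance runs generate frames at 96–128 px with 9 z-planes and radii
20–45 px — the same geometry proportions and unchanged noise model — which
keeps the whole suite within minutes while exercising every code path at
realistic SNR. The tree experiment uses 120 training spheroids (40 per
coarse group) and 150 unseen test spheroids; the sign-separation check uses
100 noise-free spheroids per polarity group; the convolutional run
augments 60 originals to 600 images per label (2400 total) and repeats
training over 10 seeds in the test suite (5 in the acceptance script).

## Known limitations

* Nuclei counting by threshold + watershed undercounts once blurred nuclei
  overlap heavily (small frames, crowded rings); the count still separates
  ring-arranged from core-filling configurations, which is its job here.
* The interpolated 60% readout is biased low by up to one radius bin for
  degenerate (single-ring) profiles.
* The convolutional branch is a desk-scale stand-in by design: it
  demonstrates the training/augmentation/validation mechanics and recovers
  the synthetic geometry, but no claim is made about parity with large
  pretrained backbones on real images.
* Proprietary microscope formats are out of scope; stacks enter as
  multi-page TIFF with an explicit channel-role map and page order
  (`CZYX`, channel fastest, by default) — never guessed from file names.
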