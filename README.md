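# spheropol

Semi-automated polarity classification of epithelial cell spheroids in 3D
culture.

Epithelial cells grown in 3D form monolayered spheroids (cysts) — the
simplest lumen-containing epithelial structure, and a standard assay for
epithelial morphogenesis, ciliopathy disease models and treatment screens.
Each spheroid, imaged as a four-channel fluorescence z-stack (basolateral
marker gp58, apical marker gp135/podocalyxin, F-actin, nuclei), belongs to
one of three polarity phenotypes: **group 1** regular apicobasal polarity
(single central lumen, apical marker + actin belt lining it), **group 2**
inverse polarity (apical surface and actin ring at the periphery,
basolateral interior), **group 3** aggregates (no lumen, or multiple
lumina). Rating hundreds of stacks by eye is slow and bias-prone; this
package automates it along two supervised routes and provides the
statistics used to validate either against human raters.

## What the package computes

**Engineered-feature branch.** The analysis exploits the radial symmetry of
polarity at the equatorial plane. From a projection of the central
z-slices, every pixel is assigned an integer polar radius

```
radius(x, y) = round( sqrt((x − X_CoM)² + (y − Y_CoM)²) )
```

and per-channel cumulative radial intensity curves are built from
per-radius mean intensities (normalised by the channel total). Positional
features read off the curves — the relative radius at 60% of total
intensity per channel, the nuclear initial slope at 30% of the spheroid
radius — and the marker differences

```
f1 = Δ(gp58 − gp135)    > 0 ⇒ regular polarity, < 0 ⇒ inverse
f2 = Δ(actin − gp135)   ≈ 0 ⇒ distinct polarity
```

combine with shape descriptors (circularities, actin-belt area and particle
count, nuclei count, centre-of-mass offset, physical radius) into a
15-feature vector per spheroid. A complex CART decision tree (Gini, minimum
leaf size 3, stratified 20-fold cross validation, feature subset 1, 2,
6–15) classifies the coarse groups; a second-stage tree on lumen
descriptors (f8, f9, f13, f14) re-examines the hard group-1-vs-3 calls; a
bagged ensemble with out-of-bag accuracy and impurity-based feature
importance round out the branch.

**Convolutional branch.** Equatorial projections are reduced to 8-bit RGB
(basolateral → green, nuclei → blue, apical marker or actin → red), class
balance is restored by seeded augmentation (random rotation 45–315°,
scaling 0.4–1.2, to 600 images per label), and a small frozen convolutional
backbone with a retrained dense softmax head is trained with SGDM
(momentum 0.9) for 15 epochs at batch size 80 and learning rate 3×10⁻³,
with a stratified internal-validation holdout. Predictions come with class
probabilities; the four fine labels collapse to the three coarse groups.

**Validation machinery.** Cross-correlation tables between any two raters
(human or algorithm), percent agreement, Cohen's κ with the
Fleiss–Cohen–Everitt large-sample standard error and confidence interval,
the conventional κ interpretation bands, recall/precision for group 1, and
a majority-consensus resolver for three-rater workflows.

**Synthetic generator.** Labelled four-channel stacks of all four fine
phenotypes with controllable geometry, PSF blur, background and
Poisson–Gaussian noise — every other module is testable without microscope
data.

## Worked example

Simulate a labelled cohort, extract features, train and apply the
two-stage tree classifier, and validate against the known labels:

```r
library(spheropol)

p <- synthetic_params(image_size = 96, z_planes = 9, radius_range_px = c(20, 34))
train <- generate_dataset(c("1_regular" = 15, "2_inverse" = 15,
                            "3a_aggregate" = 10, "3b_multilumen" = 5),
                          p, seed = 7)
feats <- extract_features(train)
round(feats[1, c("f1_delta_gp58_gp135", "f4_relpos60_gp135",
                 "f9_nuclear_initial_slope", "f13_nuclei_count")], 3)
#>   f1_delta_gp58_gp135 f4_relpos60_gp135 f9_nuclear_initial_slope f13_nuclei_count
#> 1               0.436             0.421                    0.073                8

tree <- train_tree(feats, feats$coarse_label, folds = 15, seed = 7)
tree
#> <polarity_tree> 12 features, 15-fold CV accuracy 0.956

test <- generate_dataset(c("1_regular" = 10, "2_inverse" = 10,
                           "3a_aggregate" = 7, "3b_multilumen" = 3),
                         p, seed = 8)
fte <- extract_features(test)
records <- classify_spheroids(tree, fte)
records <- reclassify(records, fte,
                      train_secondary_tree(feats, feats$coarse_label, seed = 7))
table(truth = fte$coarse_label, predicted = records$final)
#>      predicted
#> truth  1  2  3
#>     1 10  0  0
#>     2  0 10  0
#>     3  0  0 10

cat(agreement_report(cross_table(fte$coarse_label, records$final,
                                 c("1", "2", "3"))), sep = "\n")
#> n = 30 spheroids; agreement = 100.0%
#> Cohen's kappa = 1.00 [SE = 0.000; CI(alpha = 0.05) = 1.000 to 1.000]
#> interpretation: almost perfect agreement
#> group 1: recall = 1.000, precision = 1.000
```

The first spheroid is a regular-polarity cyst: its basolateral marker sits
0.436 units of relative radius outside the apical marker (`f1 > 0`), the
apical marker lines a lumen at 42% of the radius, and the near-zero nuclear
initial slope says the lumen is empty of nuclei. On this small simulated
cohort the tree separates the three groups perfectly; the report block is
the same summary a lab would print under a manual-vs-automated
cross-correlation table.

A command-line interface wrapping the same functions is installed at
`inst/cli/spheropol` (subcommands `simulate`, `features`, `convert`,
`train-tree`, `predict`, `agree`); run it with `Rscript` or directly after
`chmod +x`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/io_stacks.R` | TIFF stack I/O, ROI splitting, RGB conversion, CSV tables |
| `R/equatorial.R` | equatorial projection, spheroid mask, shape parameters |
| `R/radial.R` | polar transformation, cumulative profiles, 15-feature vector |
| `R/classify.R` | complex/secondary/bagged trees, reclassification, JSON models |
| `R/cnn.R` | augmentation, frozen conv backbone, head retraining, prediction |
| `R/agreement.R` | cross tables, percent agreement, Cohen's κ, consensus |
| `R/synthetic.R` | labelled synthetic spheroid stack generator |
| `vignettes/` | methods vignette: models, assumptions, design choices |
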