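---
title: "Chirality classification with one-hot encoded Cartesian coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chirality classification with one-hot encoded Cartesian coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohecc)
```

## The problem

Chirality is a property of a molecule's three-dimensional arrangement: a
chiral molecule cannot be superimposed on its mirror image, and the two
mirror forms (enantiomers) rotate plane-polarized light in opposite
directions. Most descriptor families used in molecular machine learning
are deliberately invariant under all rigid motions of the coordinates —
rotations, translations *and reflections* — which makes them blind to
chirality by construction. The Coulomb matrix is the canonical example:
its entries are `0.5 * Z_i^2.4` on the diagonal and `Z_i Z_j / d_ij` off
the diagonal, functions of atomic numbers and interatomic distances only,
so a molecule and its enantiomer share one Coulomb matrix exactly.

This package implements the opposite design: the **one-hot encoded
Cartesian coordinate (OHECC)** representation keeps the absolute
coordinates. A molecule with up to 27 atoms over the vocabulary
H, C, N, O, F becomes a 27 × 8 matrix — per row the three Cartesian
coordinates of an atom followed by the five one-hot element indicators,
zero rows padding out small molecules — flattened row-major to a
216-vector for the classifiers. Because a reflection changes the
coordinates, OHECC features can separate enantiomers; because the
encoding applies no centering or alignment, what the classifier sees is
exactly what the geometry file says.

On top of the two encodings the package provides the full study stack:
a geometric stereocenter labeler, a seeded generator of labeled chiral
toy molecules, builders for six balanced classification tasks, three
classifier families under one train/predict contract, confusion-matrix
metrics in the predicted-rows orientation, and rotation-distribution
statistics.

## Stereocenter detection and R/S labels

For synthetic molecules the package assigns configuration labels itself,
with a simplified, geometry-driven version of the CIP procedure:

* **Priorities.** Each of the four branches at a candidate tetrahedral
  carbon is explored breadth-first (never re-entering the center). At
  each sphere the branches are compared by their sorted atomic-number
  multisets, highest first; the first differing sphere decides, and a
  longer multiset outranks a shared prefix. Two branches identical
  through the search depth (default 6 spheres) tie, and a tied center is
  not stereogenic. This resolves every acyclic substituent pattern over
  H/C/N/O/F that differs in constitution. It is **not** full CIP: no
  isotopes, no duplicated atoms for multiple bonds, none of the
  like/unlike rules — deliberate limits, documented here, that the
  synthetic vocabulary never exercises.
* **Handedness.** With priorities 1–4 fixed, let u1, u2, u3 be unit
  vectors from the center to the top three neighbors. The sign of the
  scalar triple product `s = u1 · (u2 × u3)` decides the label: `s < 0`
  is R, `s > 0` is S. The sign-to-label convention was fixed once by
  checking both placement parities of a constructed
  fluoro(amino)(hydroxy)methane center against an independent CIP
  implementation, and is frozen in the code and in a regression test.
  Centers whose top-three tetrahedral volume falls below 1e-6 Å³ are
  rejected as geometrically degenerate rather than guessed.

Two invariances pin the semantics down and are property-tested: proper
rigid motions never change a label, and any reflection flips every
label; equivalently, swapping the positions of any two substituents
inverts the configuration.

## The synthetic generator

The generator emulates the *structure* of the study's inputs — small
organic molecules with 0–4 tetrahedral stereocenters, known labels, and
a signed rotation value — without any quantum chemistry:

* Stereocenters are carbons in a short chain, each carrying four
  branches at ideal tetrahedral angles (109.47°). The per-center
  substituent plans (drawn from H, F, OH, NH₂, CH₃, with CH₂F/CH₂OH in
  the library) were chosen so that every center's four branches differ
  within two comparison spheres — tie-free by construction — and a
  4-center chain still fits in 27 atoms. Achiral molecules carry two
  identical substituents at their candidate center.
* The intended R/S label of each center is drawn uniformly and realized
  by the *placement parity* of the branches: after a default placement,
  the two lowest-priority movable branches are swapped if the signed
  volume disagrees with the intended label. Atom append order is fixed
  by the template, never by geometry, so the R- and S-forms of a
  template have identical element sequences and differ only in
  coordinates — a classifier cannot read the label off the one-hot
  block.
* Positions receive isotropic Gaussian jitter (default sd 0.02 Å, far
  below the ~1.4 Å bond scale, so labels are never flipped by noise),
  then a random proper rigid motion.
* **Orientation.** By default (`orientation = "standard"`) each
  molecule is finally expressed in a deterministic canonical frame: the
  nuclear-charge-weighted centroid at the origin and the principal axes
  of the charge-weighted covariance as coordinate axes, with axis signs
  fixed by third moments and the third axis completing a right-handed
  frame — always a *proper* rotation, so chirality is preserved. This
  mirrors how optimized geometries are deposited by quantum-chemistry
  programs, which print structures in a standard orientation, and it is
  what makes chirality learnable from raw Cartesian features at
  moderate sample sizes. With `orientation = "random"` (uniform SO(3)
  plus a Gaussian translation, sd 0.5 Å) the same classifier drops
  toward chance at these sample sizes — a useful reminder that OHECC
  features are not rotation-invariant, and that consistent orientation
  of inputs is part of the method's contract.
* The **surrogate rotation** is `α = Σ_k s_k w_k + ε` with `s_k = +1`
  for R and −1 for S, per-center weight `w = 10` by default and
  Gaussian noise (sd 1 by default; 0 for noiseless benchmarks). Its
  sign plays the role of the computed specific rotation at 589.3 nm: a
  learnable, chirality-determined target. Real DFT rotations are *not*
  sign-determined by R/S labels (their published correlation is
  essentially zero); the surrogate deliberately is, because its job is
  to give the sign tasks a recoverable ground truth, not to mimic
  optical physics.

What passing tests on these molecules show — and what they do not: the
generator produces rigid, idealized, acyclic molecules from a small
template family, so results certify the correctness of the encoding,
labeling, task and model plumbing, and the *capacity* of the
classifiers to read handedness from coordinates. They do not certify
accuracy on conformationally diverse real molecules, whose
task difficulty the published OR-QM9 benchmarks (bundled as reference
confusion matrices) reflect.

## Tasks, balancing, splitting

Six classification problems are built from labeled records: existence
(0 vs ≥1 centers), 0 vs 1, R vs S within single-center molecules, the
rotation sign for single-center molecules, the rotation sign for all
molecules, and the 0–4 center count. Each class is downsampled, seeded
and without replacement, to exactly `per_class` records; the pool is
then split 80–20. The split is stratified by label — the study states
only "standard 80–20", and stratification is our assumption, chosen
because it preserves the designed balance in both folds. Sign tasks
strictly exclude zero-valued rotations (excluded counts are reported on
the task object). The (R)-vs-(S) task is balanced by downsampling like
the others; whether the original study balanced that task is unstated.
A molecule-size partition at 17 atoms (≤17 = small) supports
size-stratified experiments.

## Models

One contract — `train_model(x, y, config)`, `predict(model, x)` — over
three families, all single-threaded and seed-deterministic:

* **Random forest** (ranger backend): `min_samples_leaf = 2`,
  `max_features = "sqrt"`; study-scale settings (1200–1800 trees,
  depths 100–420) ship as YAML configs, desk-scale defaults (300 trees)
  run in seconds. The returned label is the majority vote of the trees;
  `predict_votes()` exposes the per-tree votes so that contract is
  verified against the backend rather than assumed, and reported
  probabilities are vote shares.
* **Gradient-boosted trees** (xgboost backend): `max_depth = 20` at
  study scale with otherwise default boosting settings; eta and the
  evaluation metric are configurable per task.
* **Feed-forward network**, implemented in the package: input → 500 →
  200 → softmax, ReLU activations, inverted dropout 0.05 at each hidden
  layer, cross-entropy loss, full-batch training. The optimizer named
  in the study's description does not exist under that name in any
  framework; we default to Adam (lr 1e-3) with Adagrad selectable —
  an interpretation, flagged as such. Weight initialization (He),
  learning-rate schedule (constant) and early stopping
  (training-loss patience) are unstated in the study; our defaults are
  documented, not asserted as the original ones. Study-scale training
  (≥10,000 epochs) is a config away; desk-scale uses a few hundred.

## Evaluation conventions

Confusion matrices are oriented **rows = predicted, columns = true**,
and the positive class of a binary task is the **first-listed** class
({0}, (R), "−"). This is the unique convention under which the bundled
published benchmark matrices reproduce their published
accuracy/precision/recall/F1 rows, and it is the opposite of the common
"positive = second level" habit — hence stated loudly here and printed
on every matrix. With that orientation, `precision = cm[1,1] /
rowsum_1` and `recall = cm[1,1] / colsum_1`; accuracy is trace over
total for any class count; F1 is the harmonic mean. Metrics are kept at
full precision and rounded (half-to-even) to 3 decimals only for table
comparison. One bundled matrix — the XGBoost (R)-vs-(S) table — is
internally inconsistent with its published summary row and sample total;
it is shipped verbatim with a `discrepant` flag and excluded from the
reproduction test.

## Rotation statistics

`describe_rotations()` filters values with |z| > 3 in a **single pass**
(z-scores computed once from the unfiltered mean and sd — not
iteratively, matching the single threshold statement it follows) and
reports mean, sd, skewness `m3 / m2^1.5` and **excess** (Fisher)
kurtosis `m4 / m2² − 3`. The excess convention is an inference from the
near-0/1 kurtosis values published for near-normal rotation classes.
`outlier_census()` reports the heavy-tail fraction beyond a threshold
(default 1000°) and the maximum magnitude. `label_sign_correlation()`
encodes R/S as ±1 against the rotation sign and returns the Pearson
correlation with the standard non-correlation test, excluding exact
zeros. Reproducing the published distribution table requires the
deposited OR-QM9 rotations; the same computations run on any record
list or CSV via `rotation_summary_table()` and the CLI `stats`
subcommand.

## Numerical choices and degenerate inputs

* Coordinates are used exactly as given: no centering, alignment or
  unit detection anywhere in the encoding path; units are Å throughout.
* Coulomb matrices reject atom pairs closer than 1e-6 Å (division
  blow-up) and are compared order-robustly via the sorted eigenvalue
  spectrum when atom order is not shared.
* Rotation matrices must be proper orthogonal within 1e-8; improper
  operations are redirected to `reflect_molecule()`.
* Stereo assignment requires a tetrahedral volume above 1e-6 Å³;
  candidates failing ranking (ties) or geometry are skipped and logged
  on the result, never silently labeled.
* Tie-breaks in prediction (equal votes, equal probabilities) resolve
  to the first-listed class deterministically.
* Metric denominators of zero return NaN with a warning rather than a
  silent 0.

## Problem sizes

Default test and demonstration sizes are chosen so the whole stack —
suite and acceptance script — runs in about a minute on one CPU:
synthetic datasets of a few hundred to 2,000 molecules for learning
checks, 1,000 molecules for round-trip censuses, 100 enantiomer pairs
for the degeneracy check, 100,000 draws for moment checks, and one
46,000-record build verifying the study-scale task arithmetic.
Study-scale model settings remain available through the shipped
configs and the CLI's `--paper-scale` flag.

## Known limitations

* The stereo labeler is intentionally sub-CIP; molecules outside the
  acyclic H/C/N/O/F world (rings, multiple bonds, isotopes,
  non-tetrahedral chirality) are out of its scope.
* The generator's geometry is idealized-plus-jitter; no force field or
  conformer sampling. Its molecules are far easier to classify than
  DFT-optimized structures.
* The surrogate rotation is sign-faithful to configuration by design,
  unlike real optical rotations.
* The archive reader targets this package's manifest-driven CSV layout;
  the originally deposited NumPy archive must be converted once (its
  internal naming is mapped by the same manifest mechanism).
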