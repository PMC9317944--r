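---
title: "Landmark-based facial symmetry features: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based facial symmetry features: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`facesym` treats unilateral facial palsy as a departure from left/right
facial symmetry measurable in landmark coordinates. The working assumptions
are:

* a healthy face at a neutral (or indeed any single) expression is nearly
  mirror-symmetric in the position and shape of eyebrows, eyes, nose and
  mouth;
* unilateral palsy manifests as a one-sided droop that perturbs exactly the
  quantities a left/right comparison measures;
* a threshold separating expected from pathological asymmetry can be learned
  by ordinary classifiers from a modest number of labelled samples.

No temporal information, no texture or intensity information, and no
specific facial gesture is required: one image's landmarks produce one
label. Identifying *which* side is affected is intentionally out of scope,
and the feature set is (almost — see below) blind to it by construction.

The pipeline is: 68-point landmarks → 51-point renumbering → head-tilt
correction → 28 distances + 2 averages → 29 features → optional regional
projection (face 29 / eyes 19 / mouth 15) → repeated stratified 5-fold
cross-validation with one of four classifier presets.

## Conventions that needed a decision

Several conventions are pinned only pictorially in the source material, so
the package ships them as *editable, validated data files* rather than code
constants.

**68→51 mapping** (`inst/extdata/landmark_map_68to51.csv`). The textual
anchors — P10/P19 are the outer eye corners, P23–P27 the nostril row below
the midline tip P22, P28/P34 the mouth corners, P28–P39 the outer lip,
P22–P37 the vertical midline — admit exactly one region-contiguous layout:
eyebrows P0–P9, eyes P10–P21, nose tip and base P22–P27, outer lip P28–P39,
inner lip P40–P47. The three nose-bridge points have no pinned slot and are
placed last (P48–P50). The loader validates any replacement mapping
(bijection, 51 rows, indices in range).

**Distance endpoints** (`inst/extdata/distance_definitions.csv`). Every
left/right pair (`Bl/Br`, `D/E`, `H/I`, `Nl/Nr`, `Ol/Or`, `Pl/Ql`, `Pu/Qu`,
`Vl/Vr`, `F/G`, `J/K`, `R/S`, `T/U`, `L/M`, `Wl/Wr`) is homologous under
mirror relabelling — a property enforced by unit test, so a misread endpoint
cannot silently survive. `A` (outer-eye-corner distance) is the global
normalizer used by `f18`, `f25`–`f28`; `W` is the mouth width. The eye
measures `Nl/Nr` and `Ol/Or` are the upper and lower eye diagonals (outer
corner to upper-inner / lower-inner lid point): `f12` and `f13` compare them
*across* sides, so all four must coincide on a symmetric face, which the
diagonal reading satisfies and most other readings do not.

**Angle convention.** The angle primitive returns the inclination of a
segment from horizontal, folded into (−90°, 90°] so it is independent of
endpoint order; features take the absolute value. A level pair scores 0 and
the facial midline `f23` scores 90° on a healthy face. The literal printed
formula (`arctan2(Δx, Δy)`) would swap these roles; the implemented
convention follows the stated feature semantics (horizontal pairs "close to
0", `f23` "expected to be vertical"). A constant offset is irrelevant to the
classifiers either way.

**Eyebrow heights `L`, `M`** are mean vertical offsets of each brow's five
points from the (post-correction, horizontal) eye-corner line. Reading them
as raw mean y-coordinates would break translation invariance of
`f3 = max(L/M, M/L)`.

**"Max" features.** The paired form `max(x/y, y/x)` (f3, f8–f13, f15–f17,
f24) is ≥ 1, equal to 1 exactly at symmetry. The normalized form
`max(x/A, y/A)` (f18–f21 with `W` as denominator for f19–f21, f25, f26) is
implemented literally; at symmetry it equals the common ratio, *not* 1, and
is not bounded below by 1. The source text's remark that ratios live in
[0, 1] is inconsistent with either form and is not implemented.

**Side-blindness, precisely.** Mirroring a landmark set (with left/right
relabelling) leaves 26 of 29 features bit-identical; the three signed slopes
f4–f6 negate, and f12/f13 exchange values. So the unordered feature multiset
cannot identify the affected side, but a classifier could in principle learn
the slope sign. Keeping the slopes signed follows the literal feature table.

**Vertical slopes** raise an error rather than clamp: eyebrow endpoint pairs
are never vertical on plausible faces, and silent clamping would mask
corrupt landmarks.

## Tilt correction

The correcting transform is the pure rotation (scale 1) about the eye-corner
midpoint that maps P10 and P19 onto the horizontal line through their
midpoint. A rotation preserves all distances, so correcting an already-level
face changes no ratio feature; the operation is idempotent to 1e−9, and
features after correction are invariant to prior in-plane rotations of up to
±45° within 1e−6 (tested property). The estimation is closed-form from the
two point pairs — four unknowns, four equations, no least squares.

Rotation **augmentation** (`rotate_augment`, default ±15°) triples a dataset
with two oppositely rotated copies. Since extraction tilt-corrects first,
augmented copies reproduce their parent's features within 1e−6 — the
augmentation exercises the rotation-invariance path rather than
manufacturing new geometry, mirroring the published protocol.

## The synthetic world

`make_template()` builds an exactly mirror-symmetric 51-point face at a
configurable interocular distance (default 100 px; all magnitudes below are
quoted at that scale). It emulates a neutral, frontal, level face.

`apply_palsy()` models unilateral droop per region as vertical displacement
with a small outward pull (0.1× magnitude) on the mouth points, attenuated
by fixed per-point weights: brow sag strongest at the lateral end; lower-lid
dominant eye sag anchored at the inner canthus; mouth-corner droop with the
lip midline deviating at half weight. Weights were chosen so every feature a
droop knob is designed to drive responds monotonically over 0–20 px (brow →
f0–f6, f3, f10; eye → f8–f13; mouth → f14–f21, f24, f25; verified before
the property test was frozen). Because tilt correction re-levels the face
using a drooping eye corner, features *outside* the drooped region shift
slightly too (for example `f23` by well under a degree) and not necessarily
monotonically; that coupling is real geometry, not noise.

Defaults state the generated world: slight palsy SL1 draws per-region droop
from U(3, 6) px, strong palsy SL2 from U(8, 16) px; landmark jitter is
Gaussian with sd 0.5 px (a typical shape-predictor error at a ~200 px face);
the global pose is uniform over ±15° rotation, ±20 px translation, 0.8–1.2
scale. `class_mix` reproduces unbalanced clinical assemblies (e.g. 740
healthy / 208 slight / 472 strong). The generator stream is a pure function
of the config, including its seed.

What the synthetic world does *not* model: anatomical variation between
subjects (every sample shares one template), synkinesis, bilateral palsy,
non-neutral expressions, 3-D pose, landmark-predictor failure modes on real
palsy faces, and the label noise of human intensity annotations. A green
end-to-end test therefore establishes that the pipeline's geometry, its
invariances, and the evaluation protocol are implemented correctly — it does
not certify clinical accuracy, and the published database accuracies
(~92–96%) are deliberately not reproduced here because those databases are
request-only.

## Classifier backends

No Weka/LibSVM-equivalent backend is available in the target environment, so
the four families are implemented in-package behind the published parameter
surface:

* **MLP** — one hidden layer of `H` sigmoid units, sigmoid one-hot outputs,
  squared-error loss, full-batch gradient descent with learning rate `L` and
  momentum `M` for `N` epochs; weights initialized U(−0.5, 0.5) from seed
  `S`; inputs rescaled to [−1, 1] from train ranges (the Weka default
  behaviour the presets assume).
* **SVM** — C-SVC with RBF kernel `exp(−G·|u−v|²)` solved by a compact SMO
  with deterministic second-choice heuristic; one-vs-one voting for
  multi-class; inputs rescaled to [0, 1] from train ranges (standard LibSVM
  practice).
* **KNN** — `k` neighbors, Euclidean or Manhattan distance, majority vote
  with nearest-neighbor tie-break.
* **MNLR** — multinomial logistic regression with ridge `R` (intercept
  unpenalized), fitted by BFGS on the penalized negative log-likelihood.

The shipped presets (`inst/extdata/classifier_presets.json`) carry the
published per-experiment values verbatim (e.g. `L = 0.2045`, `M = 0.1909`,
`H = 59`; `C = 1000` with `G` ∈ {0.1, 0.001, 0.01} per region; `k = 1`;
`R = 1e−8`), plus this backend mapping note.

## Evaluation protocol

`repeated_kfold()` stratifies by class (per-fold class counts deviate from
proportionality by at most one sample), reshuffles per repeat with seed
`base + repeat`, accumulates the confusion counts of the five folds of one
repeat, and reports mean ± sd across repeats — and, because the source is
ambiguous about which spread is quoted, also across all `k × repeats` folds
(`fold_sd`). Splitting is image-wise by default, faithfully reproducing the
published protocol in which images of one patient may land in both train and
test folds; `group_by_subject = TRUE` provides the leakage-free alternative
and keeps augmented siblings together. Multi-class reports take accuracy
from the trace of the k×k count matrix and macro-average the remaining six
statistics one-vs-rest, labelled as an extension of the binary formulas.
Undefined ratios (zero denominators) surface as `NaN` with a warning, never
as silent zeros.

## Numerical notes

* Angle fold boundary: exactly vertical segments return +90°, so `|·|` maps
  into [0, 90]; coincident points are a degeneracy error.
* Zero denominators in features (`A`, `W`, any paired ratio) raise an error
  naming the offending feature.
* The similarity-transform validator enforces the `[[a, −b], [b, a]]` block
  within 1e−9 and a positive determinant; reflections are rejected.
* Equality tolerances in tests: 1e−12 for oracle equivalence (independent
  transliteration of the feature table, brute-force matrix products,
  edge-sum perimeters, metric formulas), 1e−9 for exact-geometry identities,
  1e−6 for invariances that traverse a tilt-correction round trip.
* All RNG use is locally scoped (`with_seed`): generators and CV never
  disturb the caller's `.Random.seed`.

## Known limitations

* The 51-point numbering beyond the anchored points is a best reconstruction
  of a figure; both convention files are replaceable and validated, but a
  different figure reading would permute unanchored nose/inner-lip indices
  (no shipped feature touches the inner lip or bridge, so features are
  unaffected).
* `f7` (eye-corner angle) is identically zero after tilt correction and
  carries no information in this implementation; it is retained for fidelity
  to the published feature table.
* The SMO solver targets the small-to-moderate n of the shipped experiments
  (hundreds to a few thousand samples); it is not tuned for large kernels.
* Synthetic results transfer to real data only to the extent the droop model
  captures real palsy geometry; see the synthetic-world section above.
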