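---
title: "Whole-body water-fat MRI registration and voxel-wise analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body water-fat MRI registration and voxel-wise analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-body water-fat MRI yields, for every voxel, the absolute fat and
water content (in percent) of the tissue at that position.  To compare
this information across people — or within a person over time — every
subject's volumes must first be brought into a common coordinate system,
so that "the same voxel" means "the same anatomical position" in every
image.  Once that point-to-point correspondence exists, analysis becomes
voxel-wise statistics: atlases of normal fat content, outlier detection
against the atlas, group comparisons, correlation of local image values
with non-imaging biomarkers, and longitudinal difference maps.

The hard part is the registration.  Whole-body anatomy varies enormously
between people, but not uniformly: the skeleton is nearly rigid and
similar across subjects, lean tissue (muscle, organs) varies moderately,
and adipose tissue varies strongly and deforms freely.  This package
implements a three-step registration that exploits exactly that ordering.

## The registration model

All transforms map **fixed** (reference) physical coordinates into
**moving** (subject) physical coordinates — the resampling convention, so
the deformed moving image is `I_M(T(x))` evaluated on the fixed grid.
Coordinates are physical millimetres throughout: voxel `(i, j, k)`
(0-based) sits at `origin + (i, j, k) * spacing`, and spacings are
anisotropic (a typical whole-body protocol reconstructs around
2 x 2 x 8 mm; the phantom uses 4 x 4 x 8 mm), so voxel-index arithmetic
would be wrong.

Three cost ingredients drive every step:

* **SSD**: mean squared intensity difference over the fixed-image domain,
  `S_SSD = (1/|Omega|) sum_x (I_F(x) - I_M(T(x)))^2`.
* **Landmark distance**: `S_LM = (1/P) sum_i ||x_Mi - T(x_Fi)||` — the
  mean of residual *norms*, not squared norms, which makes the term
  robust-ish to a few bad pairs.
* **Weighted combination**: `C = (sum_i w_i S_i) / (sum_i w_i)`.

**Step 1 (bone).**  A global similarity transform is fit in closed form
by Procrustes analysis of the 8 anatomical joint landmarks (left/right
ankle, knee, femoral head, humeral head).  Then, for each of nine
bodyparts (two lower legs, two upper legs, pelvis, torso, head, two
upper arms — lower arms are excluded), an affine transform is optimized
on the SSD of the *distance transforms* of the bone masks plus the
part's 1, 2 or 4 nearest landmarks, restricted to the bodypart's label
region.  Matching distance transforms rather than the binary masks gives
the cost a wide capture basin: the DT is smooth and informative far from
the bone surface.  The torso section allows a slightly elastic B-spline
(64 mm control spacing) instead of an affine, to follow spine
articulation.  Unsigned exterior distances are used.  From the per-part
results, 1000 points per bone segment are sampled uniformly (seeded) and
mapped through the part transform; these `bone` pairs carry the skeletal
alignment into the later steps as soft constraints.

**Step 2 (lean tissue).**  A single whole-body cubic B-spline at 64 mm
control spacing, initialized from the Procrustes similarity, minimizes
water-image SSD plus the bone-pair landmark cost.  From the result, 4000
pairs are sampled from fixed voxels with water signal above 50% and
mapped through the transform (`water` pairs).

**Step 3 (adipose tissue).**  A finer whole-body B-spline at 32 mm
control spacing refines the step-2 mapping, minimizing fat-image SSD,
body-mask SSD (the mask treated as a 0/100 intensity image, which keeps
the outline matched), and both landmark terms.  Its output is the final
fixed-to-moving mapping into the common coordinate system.

**Step chaining.**  Each step refines the previous one by composition:
the optimized inner transform acts on the coordinates produced by the
previous step, so the total mapping is `T(x) = inner(T_prev(x))`,
returned as a composite transform.  Exact cubic
B-spline control-grid subdivision would be an alternative way to carry
the 64 mm solution into the 32 mm grid; composition was chosen because
it preserves the previous solution exactly at initialization and is the
standard multi-grid chaining in parametric registration practice.

## The optimizer

Each step minimizes its cost by stochastic gradient descent over a
Gaussian pyramid (downsampling factors 4, 2, 1; smoothing sigma of half
the factor, in voxels; the factor-1 level is the unsmoothed original).
Per iteration a random subsample of 2048 fixed-domain voxels (and up to
512 pairs per landmark term) is drawn through R's seeded RNG, the
analytic gradient is evaluated in compiled code, and a Robbins-Monro
step `a_k = a / (A + k)^0.602` is taken, with `A = 20` and 150
iterations per level by default.  The initial step `a` is calibrated
from the first gradient so the first update moves points by about one
finest-level voxel — large enough to traverse the capture range, small
enough not to tear the field.  Affine matrix entries are preconditioned
by the inverse squared lever arm of the domain so that rotations and
translations move at comparable physical rates.

After the stochastic search, a deterministic L-BFGS refinement runs on a
fixed, seeded evaluation subsample (8000 voxels, 2000 pairs per landmark
term) at the finest level, in displacement-balanced variables.  The
stochastic phase does the global work; the refinement tightens the last
millimetre, which matters for the sub-voxel self-registration and
2-degree articulation-recovery properties.  A best-seen guard compares
evaluation-set costs at the initial parameters, after each pyramid
level, and after refinement, and returns the best: a step's final cost
never exceeds its initial cost.

Non-positive Jacobian determinants (folding) are flagged with a warning
when a displacement field is converted to a local-volume map; they are
reported, not repaired.

### Cost weights

The weights are package defaults chosen so each step's terms have
comparable magnitude on the phantom suite, and are fully overridable
through `registration_config()` / YAML:

| step  | weights (in cost order)            |
|-------|------------------------------------|
| bone  | DT-SSD 1, landmarks 1              |
| water | SSD 1, bone pairs 0.05             |
| fat   | SSD 1, body SSD 0.3, bone 0.05, water 0.05 |

The landmark weights are small because `S_LM` is in millimetres while
the SSD terms are in squared percent; at these values the landmark terms
act as regularizers rather than as the driving force.

The B-spline steps additionally carry a **bending-energy penalty**: the
mean squared second difference of the control-point displacements
(weight `w_bending`, default 2, 0 disables).  The landmark terms alone
cannot prevent a localized distortion, because their cost averages over
all pairs — a field that drags a small interior structure toward
bright tissue pays a penalty proportional to the few affected pairs
while collecting the full SSD reward.  The concrete failure mode is
longitudinal analysis: when liver fat genuinely drops between
timepoints, an unregularized fat-step B-spline "explains" the intensity
change by warping the liver toward subcutaneous fat, destroying the
very change the analysis is supposed to measure.  Curvature is zero for
every affine field, so the penalty leaves global deformations
essentially free; its weight was fixed by a three-point scan balancing
longitudinal fidelity against known-deformation recovery on the phantom
suite.

## Evaluation metrics

With subject A registered to reference B (`T_ab`, mapping B coordinates
into A) and the reverse registration `T_ba`, the composition
`T_ba(T_ab(x))` should be the identity; its deviation is measured as

* **VME** (vector magnitude error): mean `|x - T_ba(T_ab(x))|` in mm,
* **IME** (intensity magnitude error): mean `|I_B(x) - I_B(composed(x))|`
  on fat content (percent points),
* **composed Dice**: Dice overlap of the 50%-thresholded fat (or water)
  volume before vs after resampling through the composition.

Both composition orders are evaluated, as are all nine bodyparts (label
regions of the outer volume) and the whole body (voxel-weighted over the
body mask — the aggregation is voxel-weighted rather than
part-averaged).  Composed points leaving the volume contribute their
actual displacement to VME and the fill value (0, i.e. air) to IME.
Thresholding is strict (`> 50`), applied identically everywhere.

## The phantom

Real whole-body cohorts are not redistributable, so validation runs on a
synthetic subject generator with analytic ground truth.  A phantom is
nine bodyparts built from capsules and ellipsoids articulated at the 8
joint landmarks, with interior bone tubes (zero fat+water signal — bone,
like air, gives no signal in water-fat MRI), a muscle compartment
(fat 15%, water 75%), a subcutaneous fat shell (fat 88%) whose thickness
grows linearly with the total-fat-mass covariate
(`4 + 0.35 * fat_mass_kg` mm at the torso), an ellipsoidal liver whose
fat content is set by the liver-fat covariate, and two signal-void
lungs.  Limb and torso cross-sections scale with `(weight/80)^(1/3)`;
foot-head distances scale with a height factor.  Additive Gaussian noise
(sigma 2 percent points) is applied inside the body, and fat+water is
capped at 100.  Landmarks sit at the exact joint centers.

The default grid is 64 x 64 x 160 voxels at 4 x 4 x 8 mm — about 650k
voxels, a deliberately scaled-down analog of a clinical acquisition that
keeps a full three-step registration under a minute while preserving
the anisotropic spacing.  Statistical calibration experiments use a
further-halved grid (32 x 32 x 80 at 8 x 8 x 16 mm), since they need
voxel counts, not anatomical detail, and cohort sizes of 43-60 subjects.

Cohorts draw covariates from stated distributions (weight normal around
72/84 kg by sex, fat mass `0.28 * weight` plus noise, liver fat
log-normal around 4%), and can implant known effects: a voxel-covariate
correlation of a stated rho in the liver, a group mean shift, or anomaly
subjects with pathological liver fat.  With `vary_shape = FALSE` all
subjects share the default anatomy so the stack is voxel-aligned without
registration — that construction isolates the statistics from the
registration and is what the calibration experiments use.

What the phantom does *not* emulate: MR physics (bias fields beyond an
optional smooth multiplicative term, chemical shift, partial volume
beyond grid discretization), organ-level anatomy beyond the named
regions, and positioning variability such as unseparated thighs.
Passing phantom tests therefore demonstrates the machinery — coordinate
handling, optimization, statistics — under known ground truth, not
clinical-grade accuracy on real data.

## Voxel-wise statistics

All analyses assume inputs already in the common coordinate system.

* **Atlas**: voxel-wise n, mean, and sample SD (n-1 denominator; SD 0
  when n = 1).
* **Anomaly P-map**: two-sided z-test of a subject against the atlas
  (`z = (v - mean)/sd`, normal reference; SD floored at 1e-6 with
  floored voxels counted in the metadata).  An empirical-percentile
  variant is available when the atlas keeps its per-subject values.
  The z-test was chosen as the default because it needs only the
  atlas's first two moments and matches "deviation from the atlas"
  with minimal assumptions.
* **Group P-map**: two-tailed two-sample t-test per voxel; Welch by
  default (group variances are not equal in general), pooled variance
  by flag.
* **r-map**: Pearson correlation per voxel against a per-subject
  covariate (the biomarkers of interest are continuous); Spearman by
  flag.  Zero-variance voxels get r = 0 and are counted.
* **Local volume**: the Jacobian determinant of the final deformation,
  by central differences in physical units (one-sided at borders);
  values above 1 mean the subject is locally larger than the reference.
* **Longitudinal difference**: voxel-wise fixed minus deformed-moving.

No multiple-testing correction is applied by default — the P-maps are
exploratory images, not confirmatory tests — but Benjamini-Hochberg
adjustment is available as an explicit post-processing step
(`adjust_pmap()`).  Analyses can be masked to the reference body mask;
outside voxels carry `NA` and are excluded from calibration counts.

## Numerical choices and degenerate inputs

* Trilinear interpolation for intensities, nearest-neighbour for masks
  and labels (labels must stay in the dictionary).  The interpolation
  kernel for intensities is trilinear rather than B-spline: it is exact
  for affine intensity fields, cheap, and sufficient at phantom noise
  levels; this is an artifact choice, not a claim about any particular
  clinical implementation.
* Out-of-volume sampling returns 0 (air / no MR signal).
* `threshold_mask` uses strict `>`; a voxel exactly at the cutoff is
  background.  Documented and used consistently everywhere.
* Dice of two empty masks is 1 (nothing disagrees).
* Distance transforms are exact Euclidean (Felzenszwalb's separable
  algorithm) with anisotropic spacing; empty masks are an error rather
  than an infinite field.
* Procrustes needs 3 non-collinear pairs; collinear configurations are
  rejected.  The rotation is proper (det +1) via a reflection guard on
  the SVD.
* Majority-vote ties break toward the lowest label id, so fusion is
  deterministic.
* The body-mask closing radius defaults to half the finest voxel; a
  larger radius would bridge the genuinely narrow gap between the
  thighs.
* The bone-extraction shape rule removes candidate components whose
  maximum inscribed radius exceeds 13 mm (air spaces like lungs) —
  which also removes the ball-like skull: a documented limitation of
  the single-subject extraction, recoverable by the multi-atlas
  refinement (`majority_vote()` over deformed library masks).  The rule
  needs voxels finer than the bone radius.
* All randomness flows from the configured seed through R's RNG; no
  unseeded draws anywhere, so every stochastic command is bit-for-bit
  reproducible.

## Problem sizes

The shipped defaults were sized on the phantom suite: full three-step
registrations run on the 650k-voxel phantom (about a minute each on one
core), the inverse-consistency report on a cohort of 6 phantoms with
forward and reverse registrations per subject, recovery experiments on a
single 10 mm-mean synthetic deformation, and statistical calibration on
aligned cohorts of 43-60 subjects at the halved grid with at least 2000
in-body voxels.  These are the package's own validation conditions, at
desk scale; a clinical deployment would raise iteration counts and
resolution together.

## Known limitations

* The optimizer augments plain decayed SGD with a deterministic L-BFGS
  refinement pass; with the refinement disabled (`polish_iters = 0`),
  convergence to sub-voxel accuracy needs substantially more stochastic
  iterations.
* Affine articulation recovery can express part of a joint rotation as
  shear; the rotation is therefore measured on the limb segment's
  principal axis (`segment_rotation_deg()`), which is the anatomically
  meaningful quantity.
* The multi-atlas label/landmark propagation reuses the registration
  with a rough preset; it is functional but not tuned, and real
  segmentation pipelines would add intensity models.
* No inverse transforms are computed beyond per-point fixed-point
  inversion (used only to map phantom landmarks); inverse consistency
  is evaluated from two independently estimated registrations, which is
  the point of the metric.
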