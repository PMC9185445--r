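---
title: "Registration and classification of left atrial voltage maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration and classification of left atrial voltage maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eamreg)
```

## The problem

During atrial fibrillation (AF) ablation, electroanatomical mapping samples
the left atrial endocardium at a few hundred to a few thousand points,
recording the 3D position and the unipolar and bipolar electrogram
amplitudes at each point. Low bipolar voltage is a widely used surrogate
for fibrotic substrate, which is implicated both in whether AF is
paroxysmal or persistent and in whether it recurs after ablation. Two
obstacles stand between these maps and a conventional classifier: every
patient's atrium has a different shape and arrives in its own coordinate
frame, and the points carry no natural order, so the voltages of two
patients cannot be compared coordinate by coordinate.

`eamreg` addresses both with a three-stage pipeline:

1. **Registration.** Every map is rigidly aligned to a chosen template map
   by Lucas–Kanade (LK) iteration in the feature space of a
   permutation-invariant point-cloud encoder.
2. **Canonical reordering.** After alignment, each map's voltages are
   sorted by their point's L1 distance to the origin of the normalised
   template frame, giving a fixed-length vector whose coordinates carry
   the same spatial meaning across patients.
3. **Classification.** A two-layer MLP maps the ordered voltage vector to
   a class probability; unipolar and bipolar channels are trained
   separately and ensembled by averaging their predicted probabilities.
   Evaluation is leave-one-out cross-validation (LOOCV), pooled over folds.

## Preprocessing

Maps with fewer than 100 points are discarded. Each surviving map is
min–max normalised *per map and per channel*: x, y, z, unipolar and bipolar
are each affinely mapped onto [0, 1]. Per-map (rather than cohort-wide)
normalisation is deliberate: it removes atrial size, catheter gain and
voltage-scale differences so that only geometry and the spatial pattern of
voltage remain. A constant channel would make the min–max denominator zero;
such channels are mapped to all zeros with a warning. Finally every map is
resampled without replacement to a common count of 406 points — the rule
being that the common count is the size of the smallest surviving map,
406 for the clinical cohort the method was developed on. The fixed order
is filter → normalise → resample, so resampling cannot reintroduce values
outside [0, 1], at the accepted cost that the resampled subset attains the
exact bounds 0 and 1 only approximately.

## The encoder

The encoder is a PointNet-style trunk: a shared per-point map
3 → 64 → 128 → 1024 with rectifier nonlinearities, followed by
coordinate-wise max pooling over points. Max (rather than mean) aggregation
makes permutation invariance *exact*, which the tests assert bitwise. No
input/feature transform sub-networks are used: the registration stage
estimates pose explicitly, and a learned canonicalisation inside the
encoder would compete with it. The method fixes only the
1024-dim feature; the interior widths are the smallest standard PointNet
trunk consistent with it, and we read "feature dimension 1024" as both the
final per-point width and the pooled global width, which satisfies either
interpretation.

The encoder is pretrained in two stages, both on synthetic data generated
by the package (no external shape corpus is required):

- **Shape classification warm-up.** Four elementary closed-surface classes
  (sphere, ellipsoid, box shell, two-lobe) with a temporary linear head,
  softmax cross-entropy, Adam, batch 16. This gives the features coarse
  geometric sensitivity.
- **Registration pretraining.** Each training shell is perturbed by a
  random rigid transform (rotation uniform in [0, 45] degrees about a
  random axis, translation magnitude uniform in [0, 0.8]); the LK
  registration is run for a small fixed number of unrolled iterations, and
  the recovery loss ‖G_est⁻¹·G_gt − I₄‖_F is minimised by Adam. The
  gradient is exact reverse-mode differentiation through the whole unrolled
  computation: every per-iteration feature evaluation, the rigid motion of
  the coordinates, the composed exponential maps, the template Jacobian
  and its Moore–Penrose pseudoinverse. (The only numerical shortcut is a
  central finite difference for the six partials of each 4×4 exponential,
  which is cheap and accurate to ~1e-10; the backward pass is verified
  against finite differences of the whole loss in the test suite.) A
  truncated gradient through only the terminal twist solve was tried first
  and abandoned: it does not approximate the true gradient usefully, and
  training stalls.

## Registration

A twist ξ ∈ R⁶ (three rotation, three translation components) generates a
rigid transform via the exponential map, implemented in closed Rodrigues
form with a series fallback below angle 1e-8. Registration of a source
map P_S onto a template P_T iterates:

- ξ = J⁺ [φ(P_S) − φ(P_T)], with J⁺ the SVD pseudoinverse (relative
  singular-value cutoff 1e-10) of the template Jacobian,
- ΔG = exp(ξ), applied to the source coordinates only — each point's
  unipolar/bipolar values stay bound to it,
- φ(P_S) is recomputed, and the estimate is the composition
  G_est = ΔG_n ⋯ ΔG_0.

The Jacobian is the inverse-compositional finite difference: column i is
[φ(exp(−t·e_i)·P_T) − φ(P_T)]/t with step t = 0.01, computed once per
registration call from the template alone. The sign pair (negative
perturbations in J, ΔG = exp(+ξ) applied to the source) is fixed by two
requirements checked in the tests: a source equal to the template yields
ξ = 0 immediately, and small perturbations contract. Iteration stops when
‖ξ‖ < 1e-7 (the twist norm is the natural scale-free stopping quantity;
the method itself fixes only the iteration cap) or after 20
iterations. The returned residual trace includes the initial residual, so
its length is `iterations_run + 1`.

Two registration regimes behave very differently and the package treats
them explicitly. When source and template are the *same* geometry in
different poses (pretraining, benchmark recovery), the feature residual
vanishes at the true alignment and the plain Gauss–Newton step is right:
`lk_register()` defaults to an unbounded step. When source and template
are *different patients*, the residual can never vanish; the unconstrained
step on that permanent residual is ill-scaled and walks the source tens of
degrees away from any meaningful pose (we measured median drifts of ~50°).
The evaluation harness therefore registers cross-patient maps under a
trust region — `max_step = 0.05` on the twist norm per iteration — which
keeps alignment local and, on synthetic cohorts, is the difference between
registration helping and registration destroying the downstream
classification. The bound is exposed everywhere and the plain iteration is
one argument away.

Registration quality is judged two ways in the tests: recovery of known
synthetic perturbations (rotation/translation error of G_est against the
ground-truth transform), and agreement with the closed-form Kabsch
solution, which is available because synthetic perturbations preserve
row correspondence. The Kabsch solver is an *oracle only* — the shipped
registration path never uses correspondences.

**Finetuning.** On a patient cohort there is no ground-truth transform, so
the published recovery loss cannot be evaluated; we adopt the terminal
feature residual ‖φ(G_est·P_S) − φ(P_T)‖² as the finetuning objective,
cycling templates leave-one-out (each cohort map serves as template once
per epoch, the rest as sources) with an encoder update per template round.
This objective choice and the per-round update schedule are our
interpretation; the source description leaves both open.

## Reordering and classification

After registration every map lives in the template's normalised frame, so
d_i = |x_i| + |y_i| + |z_i| — the L1 distance to the origin of that frame,
read literally from the method's definition — induces a canonical order.
Sorting is ascending with stable ties by original row index (ties have
measure zero for continuous data but determinism matters); the identical
permutation is applied to both voltage channels. The result is invariant
to any prior shuffling of a map's rows, which is the stage's entire
purpose and is asserted over random shuffles. The ordering is, as its
authors note, heuristic: nearby indices need not be spatially adjacent
everywhere, and alternatives (space-filling curves, learned orderings)
are deliberately out of scope.

The classifier is a two-layer MLP: 406 → 300 fully connected, rectifier,
dropout 0.4 (training only, inverted scaling), 300 → 2 fully connected,
softmax. The training loss is the printed two-term form

L(y, t) = −Σ_j [ t_j log y_j + (1 − t_j) log(1 − y_j) ],

summed over both softmax outputs — for two classes this double-counts
relative to the standard softmax cross-entropy (the uniform prediction
scores 2·ln 2, not ln 2), but it is implemented as printed for fidelity; a
standard softmax cross-entropy is available behind
`mlp_config(use_standard_ce = TRUE)`.

The classifier training scheme is not specified by the source and is the
package's own design, fixed as follows:

- **Optimizer and schedule:** Adam, learning rate 1e-3, full-batch (the
  training set is seven examples), 200 epochs by default; the validation
  runs use 30 (accuracy is flat between 30 and 200 epochs at these sizes).
- **Class balancing:** examples are weighted inversely to their class
  frequency during training.
- **Balanced sub-bagging in the LOOCV harness:** a leave-one-out fold of a
  balanced cohort is always imbalanced by exactly one example. The held-out
  patient's own class is then estimated from fewer examples; its noisier
  fit makes pure-noise test points look systematically more like the
  *other* class. This is the classic small-sample LOOCV anti-bias: without
  mitigation, null-signal pooled accuracy on 8-patient cohorts measures
  around 0.2, not 0.5 (weight decay does not touch it — the asymmetry is
  statistical, not a capacity problem). The harness therefore averages
  each fold's prediction over all balanced subfits obtained by dropping
  one majority example in turn. Under the null this restores coin-flip
  behaviour; with signal it is a small ensemble and slightly *improves*
  accuracy. The null-cohort acceptance checks verify both.
- **Positive class:** persistent AF and recurrence = yes, for F1.

The unipolar/bipolar ensemble averages the two classifiers' probability
vectors with equal weight 0.5 (exposed as `ensemble_weight`; the source
says only "averaging the probabilities"), and the predicted class is the
argmax with ties broken toward class 0.

## Evaluation

`loocv_splits(n)` yields the n leave-one-out folds. Metrics are computed
on the n held-out predictions *pooled* across folds — with one test case
per fold, per-fold ROC curves are undefined; pooling is our documented
interpretation. Accuracy and positive-class F1 use the 0.5 threshold;
ROC-AUC is the rank (Mann–Whitney) statistic with ties counted one half;
PR-AUC is average precision by step integration. If the pooled truth is
single-class the areas are reported as `NA` rather than 0. The full
report iterates all templates × {unipolar, bipolar, ensemble} ×
{AF type, 1-year recurrence}: six tables, one row per template, columns
Accuracy/F1/ROC-AUC/PR-AUC. The template map itself participates in the
classification LOOCV (all n patients are tested for every template
choice). Template choice visibly moves the metrics on synthetic cohorts,
mirroring the clinical observation that some templates register better
than others.

## The synthetic cohort generator

The generator provides what the clinical data cannot ship: cohorts with
known ground truth. Each patient is

1. a **shell**: points on a randomly scaled ellipsoid (semi-axes ~30 mm,
   left-atrial scale) modulated by a few smooth directional bumps — closed,
   star-convex, varied; point counts are log-normal, clamped to
   [200, 4000] with mean ≈ 1300, emulating clinical mapping density;
2. a **voltage field** in the shell's intrinsic frame: a smooth baseline
   (Gaussian bumps with correlation length 0.3 of the shell diameter)
   times a patch-depression field. Background low-voltage patches appear
   regardless of label (Poisson, mean 0.8); label-linked patches, whose
   count is `round(1.5 * label * effect_size)` (deterministic count,
   random placement), concentrate around a fixed intrinsic direction, so
   class signal lives both in overall low-voltage burden and in *where*
   the burden sits. The label-linked count is deterministic on purpose:
   a Poisson count would tie the burden's variance to its mean, and the
   between-class separation on the per-map normalised scale would stop
   growing (and eventually shrink) with `effect_size` — the parameter
   must *control separation*, so the class signal shifts the burden
   without inflating its spread. The two outcome labels are assigned
   orthogonally (recurrence stratified within AF type), so on an 8-patient
   cohort neither patch family confounds the other's classification. The bipolar channel shares patch
   geometry with the unipolar channel (lower baseline, deeper relative
   depression, mirroring the clinical observation that bipolar carries
   slightly more class information), and each channel gets independent
   Gaussian noise (sd 0.4 mV by default — `effect_size` is naturally read
   in units of this noise, and the default effect of 2.0 sits at the
   "clearly separable" end);
3. a **random rigid pose** (rotation up to 10°, translation up to 10 mm).
   Clinical exports share the electroanatomical mapping system's patient
   frame, so inter-patient orientation offsets are moderate — the
   [0, 45°] range the registration is *pretrained* on describes the
   perturbations the aligner must undo in training, not the spread of a
   clinical cohort. (At a hypothetical 45° cohort spread the true
   inter-patient alignment, up to ~90° relative, lies outside any
   feature-LK convergence basin and registration returns noise.)

At `effect_size = 0` the field construction consumes an identical random
stream for either label, so the two classes are exchangeable *exactly*,
not just in distribution. What the generator does **not** emulate:
electrogram physics, wall thickness, fiber direction, catheter contact
artifacts, or non-rigid deformation between patients. Passing tests
therefore demonstrate that the pipeline recovers the kind of signal it
assumes (spatially coherent low-voltage burden under rigid pose nuisance),
not that it will perform comparably on clinical data.

## Numerical and scale choices

- Problem sizes in the tests and acceptance runs are chosen for a
  single-CPU run: encoder warm-up on 100 clouds of 200 points;
  registration pretraining on 200 shells of 200 points for 20 epochs
  (Adam, learning rate 3e-4) with 5 unrolled iterations per sample
  (evaluation always uses the full cap of 20 iterations on 406-point
  maps); recovery measured over 50 seeded trials. The training epoch count for the full published schedule (200)
  remains the default where the source prints it.
- All randomness flows from explicit integer seeds through a
  multiplicative seed-derivation scheme; every generator and training
  routine restores the caller's RNG state.
- The pseudoinverse cutoff (1e-10 relative), convergence tolerance (1e-7
  on ‖ξ‖), exponential-map series switch (angle < 1e-8) and cross-entropy
  clamp (1e-12) are fixed constants, chosen at the conservative end of
  double precision.
- Degenerate inputs are errors, not silent repairs: fewer than two points
  for normalisation, fewer points than the resample target, mismatched
  point counts in registration, single-class training sets.

## Known limitations

- The L1-distance ordering is heuristic (see above); poorly registered
  maps scramble it. Because the class signal of the synthetic cohorts is
  carried mostly by the burden *distribution*, which any within-map
  ordering preserves, classification without registration is strong on
  these cohorts — and registration, whose cross-patient estimates carry
  irreducible noise (different shapes never match in feature space), can
  measure *worse* than no registration at all. On synthetic burden-type
  signal the registered pipeline's advantage is therefore not
  demonstrable; what the tests do establish is that registration does
  not destroy the signal (pooled accuracy through the registered
  pipeline still exceeds 0.9 on separable cohorts). A signal carried
  purely by patch *location* would make registration indispensable, but
  would also make near-perfect accuracy unattainable at the registration
  quality achievable at this training scale.
- LK with a fixed template Jacobian has a finite convergence basin; with
  the CPU-scale pretraining used here a minority of 20° perturbations
  still land in feature-space stalls where the residual is orthogonal to
  the Jacobian's 6-dimensional column space. More pretraining widens the
  basin; the acceptance run reports the achieved agreement rate with the
  Kabsch oracle rather than asserting perfection.
- Cohorts of eight patients make every metric coarse (steps of 0.125);
  conclusions about channel or template superiority on such cohorts are
  illustrative, not inferential — the package computes no significance
  tests across templates by design.
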