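---
title: "Multidimensional gait feature fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional gait feature fusion: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitfusion)
```

gaitfusion quantifies two complementary aspects of pathological gait in knee
osteoarthritis (KOA) and after total knee arthroplasty (TKA): *dynamic
coordination* between the hip and knee, read off the morphology of hip–knee
cyclograms, and *movement complexity*, read off the sample entropy of the
joint-angle signals. This vignette explains the models and procedures, the
parameters that matter, what the synthetic cohort generator does and does not
emulate, and the numerical choices behind the implementation.

## From angle traces to gait cycles

The package starts from per-trial hip, knee, and ankle flexion angles in
degrees, uniformly sampled (flexion positive; for the ankle, dorsiflexion
positive and plantarflexion negative — the sign convention is load-bearing
for event detection).

**Event detection.** Gait events are located on the ankle trace alone.
Toe-off is the maximum plantarflexion angle: a deep local minimum, found
after light smoothing (moving average, `smooth_window = 5` samples), with a
depth gate (`trough_depth_frac = 0.35` of the trace's range) and a minimum
separation of half the median candidate spacing to suppress double troughs.
Heel strike is described clinically as the "initiation point of ankle joint
angle change", which has no numeric definition; we operationalize it as the
first zero crossing (positive to non-positive) of the smoothed first
difference after each toe-off whose descent is *sustained*: the trace must
drop by at least `onset_prominence_frac = 0.05` of its range within the
lookahead window and must not rebound above the turning point inside it.
The rebound guard matters in practice — without it, noise dips on the
swing-phase dorsiflexion rise trigger detections well before the true
turning point on noisy recordings. All three thresholds are configuration
keys; the onset rule as a whole is an explicit package convention, flagged
here because the clinical phrase underdetermines it. Smoothing is used only
inside detection, never on exported angles.

**Time normalization.** Each heel-strike-to-heel-strike segment is
resampled to `n_cycle_points = 101` points (0–100% of the cycle in 1%
steps, the biomechanics convention; the value is configurable) using a
not-a-knot cubic interpolating spline built in-package: piecewise cubics
$s(x) = a_i + b_i(x-x_i) + c_i(x-x_i)^2 + d_i(x-x_i)^3$ with continuous
first and second derivatives, and third-derivative continuity across the
second and second-to-last knots. Not-a-knot was chosen over natural end
conditions because it reproduces cubic polynomials exactly and avoids
artificial flattening at the cycle boundaries; the tests pin the boundary
condition via the third-derivative property and values frozen from an
independent implementation. The spline never extrapolates — queries outside
the knot span are an error. No smoothing or filtering is applied to the
angles themselves: denoising is an acquisition-side concern.

Per the acquisition convention of keeping 3–5 complete cycles per subject,
`select_cycles()` draws a seeded uniform subset when more cycles are
available.

## Cyclogram morphology

The hip–knee cyclogram plots hip angle (X) against knee angle (Y) over one
cycle; physiological loops are traversed clockwise (the implementation warns
when the signed area is positive). Features per cycle:

- **Range of motion** per joint: max − min angle.
- **Centroid** (`hip_com`, `knee_com`): the mean hip and knee angles.
- **Perimeter**: the sum of consecutive point distances plus the closing
  segment back to the first point.
- **Area**: the absolute shoelace sum with the standard closure term
  $\theta h_n \theta k_1 - \theta k_n \theta h_1$. (A variant closure term
  sometimes seen in print is dimensionally inconsistent and breaks
  translation invariance; the standard cross-product closure is used.)

Stance and swing sub-features are partial sums of the *same* closed-figure
summation, with a segment assigned to the phase of its starting point and
the closing segment to swing; the totals are defined as stance + swing, so
additivity holds bit-exactly. For closed physiological loops the last point
nearly coincides with the first, so the closing-segment convention is
immaterial; for arbitrary labelled polygons the area parts carry the loop's
orientation sign. Per-subject features are the arithmetic mean over the
selected cycles (median available via configuration).

## Sample entropy

For a series of length $N$, embedding dimension $m$ and tolerance $r$,
SampEn$(m, r, N) = -\ln(A/B)$ where $B$ counts ordered template pairs of
length $m$ within Chebyshev distance $r$ (self-matches excluded), and $A$
the same at length $m+1$, both over the same $N-m$ template positions.
Defaults: $m = 2$, $r = 0.1 \times$ SD of the analyzed series. The
SD-relative tolerance is the standard convention that adapts $r$ to the
dynamic range of the signal and makes SampEn scale-invariant; an absolute
mode (`sampen_r_mode = "absolute"`) exists for sensitivity analyses. Each
subject's selected normalized cycles are concatenated per joint and SampEn
computed once per joint (`sampen_input = "concatenated"`); a
per-cycle-mean alternative is configurable.

Edge cases are defined, not accidental: a zero-variance series yields 0 with
a warning; zero matches at length $m+1$ yields `Inf` flagged with a reason;
$N \le m+1$ is an error. One property worth stating explicitly: an exactly
periodic smooth signal does *not* have SampEn near zero under the
SD-relative tolerance — near-matches at neighbouring phases fail at length
$m+1$, leaving values around 0.15–0.22 for gait-like curves. What noise
does is raise SampEn strictly and monotonically, and that contrast (not an
absolute "zero for regular signals") is the property the tests assert.

## Group statistics

The feature matrix (subjects × features, with category tags, group labels,
and covariates) feeds a two-track protocol:

1. **Nonparametric screening**: Shapiro–Wilk per group per feature;
   Kruskal–Wallis omnibus across the three groups; when the omnibus test is
   significant at $\alpha = 0.05$, all three pairwise Mann–Whitney U tests,
   declared significant at the fixed Bonferroni threshold $p < 0.017$
   (0.05/3 as conventionally printed — the threshold is applied as a fixed
   decision rule, not as adjusted p-values). Fisher's exact test serves any
   categorical variable. Groups with fewer than 3 observations skip the
   feature with a warning.
2. **ANCOVA**: per feature, `feature ~ group + covariates` by least squares;
   the group main effect is reported with Type II sums of squares (Type I
   and III configurable), partial
   $\eta^2 = SS_{group}/(SS_{group}+SS_{res})$, and Tukey HSD contrasts on
   covariate-adjusted group means for significant effects. Constant
   covariates are dropped with a warning. The side-adjusted variant
   dummy-codes the unilateral/bilateral involvement category among the
   covariates, merging singleton categories into the most frequent one.

`percent_change()` implements the signed group-mean summary
$100 (\bar x_{comp} - \bar x_{ref})/\bar x_{ref}$, reported to one decimal
by convention.

## Machine-learning harness

Four feature sets — fused (10 cyclogram + 3 entropy), cyclogram, entropy,
spatiotemporal — are each evaluated with four classifiers (RF via ranger,
RBF-kernel SVM via e1071, decision tree via rpart with the Gini criterion,
and an in-package distance-weighted KNN) under nested stratified
cross-validation: outer 5-fold for performance, inner 3-fold for
hyperparameter selection. Per outer fold, median imputation, Z-score
standardization, and top-10 ANOVA-F feature selection are all fitted on the
training fold only (leakage is probed in the tests). Search ranges: RF
trees 50–100 and depth 3–5 by random search with 20 draws (a grid mode
exists); SVM cost 0.1–10; tree depth 3–5; KNN neighbours 3–7 with distance
weighting. Classes are weighted inversely proportional to frequency (the
SVM receives per-class penalty weights). Metrics pool the out-of-fold
predictions: accuracy and support-weighted precision/recall/F1 in percent,
and macro one-vs-rest AUC with a percentile bootstrap interval over
subjects (resamples missing a class are redrawn). A 5-fold
cross-validated LDA serves as the linear baseline contrasting fused against
spatiotemporal inputs. Everything is reproducible from one seed; the RF
backend is ranger because the depth grid needs an explicit `max.depth`
control. KNN is implemented in-package because no installed library offers
distance weighting; it is ~20 lines over Euclidean distances with
inverse-distance votes scaled by the class weights.

## The synthetic cohort generator

Because the clinical recordings behind the reference cohort are not
deposited, the generator is the package's ground-truth instrument, not a
test fixture. Each subject draws template parameters from a group profile
and renders 3–5 cycles at 100 Hz with a quarter-cycle lead-in and tail:

- **hip**: a single flexion–extension cosine scaled to the drawn RoM;
- **knee**: two Gaussian flexion bumps (small stance flexion at 15% of the
  cycle, large swing flexion at 72%) scaled to the drawn RoM and centroid;
- **ankle**: a dorsiflexion plateau, a sharp plantarflexion trough at the
  drawn stance fraction (the toe-off landmark), and a narrow dorsiflexion
  apex at the cycle boundary (the heel-strike landmark).

Smoothed Gaussian noise (moving average width 3) with SD equal to
`complexity_noise_sd` × joint RoM is added — the knob that raises sample
entropy — and each cycle's hip and knee curves are then affinely mapped
onto the drawn RoM and centroid, so the manifest records exact ground truth
for recovery tests. Group defaults are anchored to published cohort values:
group sizes 21/24/25; RoM and centroid means and SDs per group from the
reference table shipped in `extdata/`; stance fraction 0.60 ± 0.012 for all
groups (stance is about 60% of the cycle; group-specific stance values are
not anchored); ages and BMIs per the published anthropometry; side-category
frequencies per the published involvement counts; spatiotemporal parameters
set to plausible clinical values in which patients walk slower with shorter
strides and the stride width does not differ. The complexity-noise defaults
(Healthy 0.008, KOA 0.021, TKA 0.003) were calibrated once so that the
group-mean hip sample entropies land on the published scale (≈0.24, 0.30,
0.23); the TKA anchor of 0.21 lies below the noiseless floor (≈0.22) of the
smooth template, so TKA sits at that floor. These are defaults of record,
set before the acceptance runs and not revisited.

What the generator does *not* emulate: soft-tissue artifact, marker
occlusion, inter-cycle shape drift within a subject (cycles share the
subject's template), asymmetric left/right kinematics, real spatiotemporal
covariance with the kinematics, and any failure mode of the capture
pipeline. Passing tests therefore demonstrate that the algorithms recover
known ground truth under physiologically scaled, well-behaved signals — not
that they are robust to every artifact of real motion capture.

## Numerical choices and degenerate inputs

- Splines: at least 4 points, strictly increasing abscissae, no
  extrapolation; endpoints of a resampled cycle are returned exactly.
- Geometry: single points have perimeter 0; fewer than 3 points have area 0
  with a degenerate flag; collinear points give area 0.
- Entropy: both template counts use the same $N-m$ start positions, so the
  value is always non-negative; ties at the tolerance boundary use
  $\le r$.
- Event detection: constant or too-short traces raise a no-events error;
  cycles without exactly one toe-off are skipped with a warning; detected
  events alternate strictly.
- CV: stratified fold assignment deals each class round-robin after a
  seeded shuffle, keeping per-fold class counts within one subject of
  proportionality; hyperparameter ties resolve to the first candidate;
  zero-variance training columns are dropped with a warning.
- Reports embed the effective configuration and seed; bundle outputs are
  hashed so reproducibility is checkable at the byte level.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the full default cohort (70
subjects), a 1000-point circle for the geometry oracles, 20–50 series of
length ≤ 300 against the $O(N^2)$ brute-force entropy oracle, 500–1000
replicates for the null-calibration checks, and nested CV on all 16
model × feature-set combinations (10 seeds for the fused-versus-single
comparison, bootstrap B reduced to a few hundred). These sizes were chosen
to exercise every claim at the default study scale while keeping a full run
in minutes on one core.

## Known limitations

- The heel-strike onset rule is a package convention; other
  operationalizations (force plates, foot switches) will move events by a
  few samples.
- Phase sub-areas follow the partial-sum convention; separately closing
  each sub-path would give different (non-additive) values.
- The statistics layer mirrors a fixed-threshold decision protocol rather
  than reporting adjusted p-values; both views are recoverable from the
  emitted tables.
- Absolute classification accuracies on synthetic cohorts are not
  comparable to accuracies on clinical data; only directions and orderings
  are designed to transfer.
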