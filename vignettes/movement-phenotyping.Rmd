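---
title: "Movement phenotyping from pose-landmark time series: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement phenotyping from pose-landmark time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(povmotion)
```

This vignette is the package's own account of its science: what is
modeled, which parameters matter and why they default to what they do,
what the synthetic cohort generator does and does not emulate, and where
design decisions were genuinely open.

## The measurement pipeline

The object of measurement is gross body movement of a seated child over
a fixed 300-second interaction, observed indirectly through a 33-keypoint
pose estimator running at 30 fps on a head-mounted examiner camera. Three
nuisance processes separate the estimator output from the quantity of
interest: per-frame landmark jitter, intermittent detection failures, and
camera motion shared by all landmarks. The pipeline addresses each one
explicitly, in a fixed order: trim → confidence mask → exclusion check →
linear gap interpolation → One Euro smoothing → composite aggregation →
pelvic-root transform → windowed displacement.

### Quality control

A cell (frame × landmark) is invalid when its confidence is *strictly*
below `confidence_threshold` (0.50). The session-level missing fraction
is the mean over the 33 landmarks of each landmark's invalid-frame
fraction (*cell mean*). "Overall missing data" could equally have been
read as the fraction of frames with *any* invalid landmark; the cell
mean was chosen because a single jittery landmark (commonly an occluded
distal foot) would otherwise dominate the session decision. Sessions are
excluded when the fraction *exceeds* 0.20 — a session at exactly 20% is
retained.

Gaps are reconstructed per landmark and axis by linear interpolation
between nearest valid neighbours; leading/trailing gaps hold the nearest
valid value. Filled cells receive confidence equal to the threshold, so
they count as valid downstream while remaining distinguishable from
genuine detections; x, y *and* z are all interpolated (QC is lossless in
depth, which is only discarded at the root-frame projection).

### One Euro smoothing

The One Euro filter is a first-order recursive low-pass whose cutoff
rises with the (itself low-pass-filtered) signal speed:
`f_c = min_cutoff + beta * |v̂|`, smoothing weight
`alpha = 1 / (1 + 1/(2·pi·f_c·T_e))` at sampling period `T_e = 1/fps`.
Defaults are `min_cutoff = 1` Hz, `beta = 0.05`, `d_cutoff = 1` Hz — the
filter's recommended starting point for ~30 Hz interactive signals. All
three are exposed in `one_euro_params()`. The filter is applied per
landmark and axis on raw coordinates, *before* the pelvic-root
transform, matching the order in which the processing stages are
defined. A consequence worth knowing: common-mode camera motion is
rejected *exactly* only by the root transform itself; once the adaptive
filter has run, per-landmark cutoffs differ slightly and a small
fraction of shared motion leaks into root-relative coordinates. With the
default generator settings this leakage is about 4% of the global
activity index. The exact-invariance property is therefore tested at the
kinematics level (unsmoothed), and the leakage is part of what the
synthetic cohorts treat as realistic measurement background.

### Composites, root frame, displacement

The 15 composite points are unweighted member centroids (head = 11
facial landmarks, distal hand = thumb/index/pinky, distal foot =
heel/foot-index, the rest singletons). The hips define the per-frame
root (midpoint of landmarks 23/24) and are never analyzed as a region —
their root-relative displacement is zero by construction.

Displacement uses non-overlapping block means: positions averaged over
consecutive `w`-frame windows (primary `w = 5`; 10 and 15 as sensitivity
settings), Euclidean distance between successive block means, trailing
partial block dropped. Sliding windows would have yielded 8,996 rather
than 1,799 values per session and double-counted motion; block means are
also what makes frame-level jitter average out. The **activity index**
is the sum of the displacement series; the **variability SD** its
sample standard deviation (n − 1); the **global activity index** is the
*sum* (not mean) of the 15 regional indices — the sum convention is the
one consistent with the magnitude relation between published regional
medians (~1–4 × 10⁻³) and global means (~0.03–0.04). Height
normalization divides an index by standing height in cm.

## Statistical conventions

* Test gating: Mann–Whitney U if Shapiro–Wilk rejects normality
  (p < 0.05) in *either* group; otherwise Student's t, upgraded to
  Welch when an F variance-ratio test rejects at 0.05. (A pooled-residual
  gate would be an alternative; the either-group rule is the recorded
  choice.)
* Mann–Whitney: `U = min(U_a, U_b)`; Z from the tie-corrected normal
  approximation with 0.5 continuity correction — verified identical to
  `wilcox.test(exact = FALSE, correct = TRUE)`; two-tailed p; effect
  size `r = |Z|/√N` with N the **total** sample size, never a
  per-comparison n.
* Domain-wise Bonferroni: four upper-limb measures per side share
  α = 0.05/4 = 0.0125; three lower-limb measures share 0.05/3 = 0.0167;
  the head composite and the global index are single primary outcomes at
  0.05. Variability comparisons are exploratory and reported
  uncorrected.
* Power: noncentral t with `ncp = d·√(n1·n2/(n1+n2))`; required-n mode
  iterates equal per-group n until the target power is reached.
* Wilson intervals: the default effective n is the **whole sample** for
  every classification metric — including sensitivity and specificity,
  whose natural denominators are the class sizes — because that is the
  reporting convention the package reproduces; `n_eff_mode = "metric"`
  gives the per-metric denominators.
* Hanley–McNeil: closed-form AUC standard error with
  `Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`, class sizes as the n's, interval
  clipped to [0, 1].
* 2×2 chi-square: Pearson statistic *without* continuity correction.

## Classification design

Features are the 15 regional activity indices only: the global index is
excluded as an exact linear combination of them, and the variability SDs
are kept out of the feature set by design. Six families run under one
protocol: Random Forest, Extremely Randomized Trees, gradient-boosted
trees, AdaBoost over shallow decision trees (discrete SAMME, written
in-package), an RBF SVM, and a class-weighted KNN in which each
neighbour's vote is multiplied by its class weight `w_c = n/(2 n_c)` —
the only deterministic reading of "greater penalty for minority
misclassification" that KNN admits. Class weights apply to SVM and KNN;
those two also get within-fold feature standardization.

Unstated protocol details were fixed as: 5 outer / 3 inner folds for the
nested importance stage, 5 evaluation folds, every split stratified and
shuffled under seed 42; small fixed hyperparameter grids (tree count
{50, 100, 200}, AdaBoost depth {1, 2}, SVM C {0.1, 1, 10}, KNN k
{3, 5, 7}). Permutation importance permutes one validation column at a
time (the fold model is fitted once and never refit), averages the
accuracy drop over `pfi_repeats` permutations, then over outer folds,
then over model families (plain mean). Elimination drops the
least-important feature repeatedly and stops when mean pooled CV
accuracy falls more than ε = 0.02 below the best seen, returning the
best-scoring set (ties favour the smaller set). Evaluation pools
out-of-fold predictions into a single confusion matrix per model — a
per-fold-averaged alternative would not yield one 66-subject matrix.
`distal8_features()` ships the eight-region reduced set (left elbow,
right wrist, both distal hands, both distal feet, right knee, right
ankle) so the reduced-model evaluation can be reproduced without
rerunning elimination.

The pooled AUC is computed by the rank (Mann–Whitney) identity and is
tested to equal pair counting and an independent ROC implementation to
1e−12.

## The synthetic cohort generator

The generator exists because the kind of data this pipeline consumes —
videos of children in clinical settings — cannot be published. It
emulates the *statistical structure* the analysis assumes, not the
kinematics of real children:

* **Motion model.** Each composite region performs a discrete
  Ornstein–Uhlenbeck walk around a fixed seated rest pose
  (mean-reversion 0.08/frame), applied coherently to its member
  landmarks plus small independent estimator jitter (25% of the mean
  regional amplitude). Whole-body fidget bursts arrive as a Poisson
  process (4/min, 1 s, ×3 step SD), producing the heavy-tailed
  displacement variability the case group shows. Hips stay anchored.
  Camera jitter is a slow mean-reverting drift added to all landmarks,
  drawn from a separate RNG stream so jitter-only changes leave body
  motion bit-identical.
* **Amplitude calibration.** Control regional amplitudes are
  proportional to the observed control-group regional profile, with one
  overall scale fixed once so a default control session yields a global
  activity index of ~0.033 over 9,000 frames *after the full QC chain*.
* **Group effect.** Case amplitudes are scaled per region: head,
  shoulders, elbows, ankles and feet carry weight 1.2; wrists, hands and
  knees 0.35. The overall scaling is root-found on a large deterministic
  latent draw so the *population* Cohen's d of the global index equals
  the target (default 0.76). Between-subject variation is a shared
  lognormal multiplier (CV 0.22) times independent per-region lognormals
  (CV 0.32); this split gives regions partially independent information,
  which is what lets a multivariate classifier exceed the global index's
  univariate separability — the regime the classification stage is
  designed for. The cost of that choice is that the weak regions'
  univariate effect sizes (~0.1) sit below the small-effect values a
  real cohort showed; the strong regions land at r ≈ 0.33–0.35.
* **Symptom scores.** Hyperactivity scores follow group-specific
  marginals of a 9-item 0–3 parent-report scale and link to each
  subject's movement latent through a Gaussian copula whose within-group
  strength is root-found so the *pooled* Spearman correlation with
  realized activity approximates the target (default 0.28) — the planted
  group effect alone already induces rank concordance, and the
  calibration accounts for it.
* **What passing tests do not show.** The generator says nothing about
  real children's movement spectra, posture changes, occlusion
  structure, or engine-specific confidence behaviour; missingness is
  independent across cells, whereas real dropouts are bursty and
  landmark-correlated. Recovery of the planted effects demonstrates that
  the *pipeline* is correct and calibrated, not that the effects exist
  in nature.

## Numerical choices and degenerate inputs

Sessions are bit-deterministic in their seed; every stochastic stage
(fold shuffling, permutations, forests) derives from the protocol seed,
and `run_pipeline()` bundles are byte-reproducible. The One Euro filter
initializes at the first observation with zero derivative. Windowed
displacement requires at least two full windows and errors otherwise; a
landmark with no valid frame at all is an unrecoverable error rather
than a silent fill. Ties in KNN distances resolve by index order; ties
in elimination accuracy favour the smaller feature set; the AdaBoost
loop stops early on a zero- or ≥0.5-error weak learner (falling back to
the class prior if the first learner is already degenerate).

The test suite runs the Monte-Carlo properties at reduced problem sizes
chosen to keep the statistical content intact: effect-recovery cohorts
use 1,200-frame sessions (40 s) at the full 37/29 design, null
calibration uses 200 cohorts of 12/12 at 300 frames, and end-to-end
classification uses 20 cohorts of 66 at 600 frames. Displacement indices
scale linearly with session length, so shorter sessions change only the
measurement noise around each subject's index, slightly attenuating
recovered effects relative to full-length sessions; the analysis scripts
under `analysis/` run the full 9,000-frame design.

## Known limitations

The pose-engine adapter is declared but untested against a real engine.
The generator's OU-plus-bursts model is a stand-in, not a claim about
kinematics. The Wilson whole-sample convention reproduces a particular
reporting choice and is not the textbook interval for class-conditional
metrics (use `n_eff_mode = "metric"` for those). Elimination operates on
an importance ranking computed once; a fully re-nested
selection-within-evaluation scheme would be slower and is out of scope,
mirroring the evaluated workflow's own acknowledged limitation.
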