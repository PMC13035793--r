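# povmotion

Quantifying children's body movement from pose-landmark time series
recorded during brief seated clinical interactions, and testing whether
movement-derived features separate hyperactive from typically developing
groups.

The package is written for researchers in digital behavioral phenotyping
who have (or plan to collect) per-frame 33-keypoint pose-estimator output
(BlazePose/MediaPipe topology) of a seated child, plus basic cohort
metadata (group, age, sex, height, parent-reported symptom scores). No
video is processed here: the input is the landmark time series; an
adapter interface (`session_from_engine()`) is declared for plugging in a
pose engine. Because no public dataset of this kind exists, the package
ships a first-class synthetic cohort generator with the statistical
structure the analysis assumes, so the whole pipeline is testable and
reproducible end to end.

## The measurement model

For each session (300 s at 30 fps, i.e. 9,000 frames):

1. **QC** — landmark detections with confidence `< 0.50` are masked;
   sessions with an overall missing fraction `> 20%` are excluded; gaps
   are reconstructed by per-landmark linear interpolation; coordinates
   are smoothed with the **One Euro filter** (adaptive first-order
   low-pass, cutoff `f_c = f_min + β|v̂|`).
2. **Composite points** — the 33 landmarks are aggregated to 15
   anatomical regions: head (centroid of the 11 facial landmarks),
   bilateral shoulder/elbow/wrist/knee/ankle (singletons), distal hand
   (thumb/index/pinky centroid) and distal foot (heel/foot-index
   centroid). Hips define the **pelvic root** and are not a region.
3. **Root frame** — every composite is expressed relative to the
   per-frame hip midpoint (cancels camera drift); depth is dropped
   (x–y plane only).
4. **Windowed displacement** — positions are averaged over consecutive
   non-overlapping 5-frame blocks and Euclidean displacement taken
   between successive block means (1,799 values per session; 10- and
   15-frame windows as sensitivity analyses).
5. **Indices** — per region, the **activity index** is the summed
   displacement and the **variability SD** its sample standard
   deviation; the **global activity index** is the sum of the 15
   regional activity indices, optionally normalized by height (index /
   height in cm).

Group inference follows a Shapiro–Wilk-gated battery (Student/Welch t or
Mann–Whitney U with tie-corrected normal approximation; effect sizes
Cohen's *d* or `r = |Z|/√N`), with domain-wise Bonferroni thresholds
(upper limb α = 0.0125, lower limb α = 0.0167, head and global index
uncorrected). Classification uses the 15 regional activity indices with
six class-weighted model families (`w_c = n/(2 n_c)`), nested
cross-validated permutation feature importance, iterative feature
elimination, and a stratified 5-fold evaluation whose pooled predictions
yield one confusion matrix per model, Wilson 95% intervals (whole-sample
n convention) and a Hanley–McNeil interval for the AUC.

## Worked example

The numbered scripts under `analysis/` run the full study on a synthetic
cohort (37 cases / 29 controls, 9,000-frame sessions, seed 42):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_features.R
Rscript analysis/03_group_stats.R
Rscript analysis/04_classify.R
```

Output of stages 2–4 for this cohort (tables under `results/`):

```
QC: 66 of 66 sessions retained (mean missing fraction 0.0200)
global activity: case 0.0449 +- 0.0119, control 0.0368 +- 0.0082
significant at domain alpha (w=5): left_shoulder, right_shoulder,
  left_elbow, left_ankle, right_ankle, left_foot, global
variability: 7 of 15 regions higher-variance in cases at p<0.05
hyperactivity ~ global activity: rho = 0.29 (p = 0.017)
height-adjusted model: beta_group = 0.38 (p = 0.003)
planning: power 0.816 at d = 0.72 (37/29); required total n = 64

selected features: right_foot, left_shoulder, right_ankle, left_ankle,
  right_shoulder, left_elbow, left_knee
best model: extra_trees | accuracy 72.73% (61.0-82.0) | AUC 0.78 (0.66-0.89)
```

Reading: the planted case-group effect (global-activity Cohen's d 0.76)
is recovered (0.0449 vs 0.0368 ⇒ d ≈ 0.78 here), proximal-plus-distal
regions pass their domain thresholds while wrists/hands/knees stay
sub-threshold, parent-reported hyperactivity tracks measured activity
(ρ ≈ 0.29), the group difference survives height adjustment, and a
reduced distal-dominant feature set classifies the groups well above
chance with honest (pooled cross-validated) intervals.

The same stages are available as one call: `run_pipeline(pipeline_config())`,
configurable from YAML (`read_pipeline_config()`), writing a stamped,
byte-reproducible report bundle.

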