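# Demonstration pipeline configuration: a small synthetic cohort run end
# to end. All study constants are surfaced here; omitted keys fall back
# to the package defaults (confidence threshold 0.50, exclusion cap 0.20,
# One Euro 1.0/0.05/1.0, domain alphas 0.0125/0.0167).
out_dir: results/demo
cohort:
  n_group1: 10
  n_group2: 10
  target_d_global: 0.76
  target_rho_symptom: 0.28
  seed: 42
qc:
  confidence_threshold: 0.50
  session_missing_cap: 0.20
  target_frames: 900
  fps: 30
windows: [5, 10, 15]
protocol:
  outer_folds: 5
  inner_folds: 3
  eval_folds: 5
  pfi_repeats: 10
  seed: 42
feature_preset: distal8
n_frames: 900
seed: 42
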