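# Small programmatic fixtures shared across the suite.

# A session built from explicit matrices, defaulting to benign values.
make_session <- function(n = 10L, x = NULL, y = NULL, z = NULL, conf = NULL,
                         fps = 30, subject_id = "t01") {
  fill <- function(m, v) if (is.null(m)) matrix(v, n, 33L) else m
  landmark_session(subject_id, fps, fill(x, 0.5), fill(y, 0.5),
                   fill(z, 0), fill(conf, 1))
}

# A static session at the rest pose (all confidences 1).
rest_session <- function(n = 10L, fps = 30) {
  p <- rest_pose()
  make_session(n, x = matrix(p[, 1], n, 33L, byrow = TRUE),
               y = matrix(p[, 2], n, 33L, byrow = TRUE), fps = fps)
}

# A small moving session with full confidence (deterministic).
wiggle_session <- function(n = 60L, amp = 1e-3, seed = 1, fps = 30) {
  set.seed(seed)
  p <- rest_pose()
  x <- matrix(p[, 1], n, 33L, byrow = TRUE) + matrix(rnorm(n * 33, 0, amp), n)
  y <- matrix(p[, 2], n, 33L, byrow = TRUE) + matrix(rnorm(n * 33, 0, amp), n)
  make_session(n, x = x, y = y, fps = fps)
}

# Feature matrix with planted group separation on selected columns.
synth_feature_matrix <- function(n1 = 37L, n2 = 29L, p = 15L, delta = 0.35,
                                 informative = seq_len(p), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  colnames(X) <- if (p == 15L) region_names() else paste0("f", seq_len(p))
  y <- factor(rep(c("case", "control"), c(n1, n2)),
              levels = c("case", "control"))
  X[y == "case", informative] <- X[y == "case", informative] + delta
  list(X = X, y = y)
}

# QC config for short simulated sessions.
short_qc <- function(n) qc_config(target_frames = n)
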