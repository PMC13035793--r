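#' One Euro filter parameters
#'
#' Defaults follow the filter's recommended starting point for ~30 Hz
#' interactive signals: `min_cutoff = 1` Hz, `beta = 0.05` (cutoff increase
#' per unit speed), `d_cutoff = 1` Hz for the derivative filter.
#'
#' @param min_cutoff Minimum cutoff frequency in Hz (> 0).
#' @param beta Speed coefficient (>= 0); larger values let fast movements
#'   through with less lag.
#' @param d_cutoff Fixed cutoff in Hz for the derivative estimate (> 0).
#' @return A list of class `one_euro_params`.
#' @export
one_euro_params <- function(min_cutoff = 1.0, beta = 0.05, d_cutoff = 1.0) {
  if (min_cutoff <= 0 || d_cutoff <= 0 || beta < 0)
    stop("min_cutoff and d_cutoff must be > 0 and beta >= 0", call. = FALSE)
  structure(list(min_cutoff = min_cutoff, beta = beta, d_cutoff = d_cutoff),
            class = "one_euro_params")
}

#' Quality-control configuration
#'
#' @param confidence_threshold Landmark confidence below which a (frame,
#'   landmark) cell is invalid (strictly below; default 0.50).
#' @param session_missing_cap Session-level missing fraction above which
#'   (strictly) the whole recording is excluded (default 0.20).
#' @param target_frames Trimmed session length in frames (default 9,000,
#'   i.e. 300 s at 30 fps).
#' @param fps Expected frame rate.
#' @param one_euro [one_euro_params()] for the smoothing stage.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(confidence_threshold = 0.50, session_missing_cap = 0.20,
                      target_frames = 9000L, fps = 30,
                      one_euro = one_euro_params()) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            session_missing_cap >= 0, session_missing_cap <= 1,
            target_frames >= 2, fps > 0)
  structure(list(confidence_threshold = confidence_threshold,
                 session_missing_cap = session_missing_cap,
                 target_frames = as.integer(target_frames), fps = fps,
                 one_euro = one_euro),
            class = "qc_config")
}

#' Trim a session to the fixed analysis duration
#'
#' Keeps `cfg$target_frames` frames starting at `onset_frame` (the frame
#' aligned to the onset of the examiner's first spoken word) and re-indexes
#' from 0.
#'
#' @param session A [landmark_session()].
#' @param onset_frame 0-based first frame to keep.
#' @param cfg A [qc_config()].
#' @return The trimmed [landmark_session()].
#' @export
trim_session <- function(session, onset_frame = 0L, cfg = qc_config()) {
  nf <- n_frames(session)
  need <- onset_frame + cfg$target_frames
  if (onset_frame < 0) stop("onset_frame must be >= 0", call. = FALSE)
  if (need > nf)
    stop(sprintf("session too short: %d frames, need %d after onset %d",
                 nf, cfg$target_frames, onset_frame), call. = FALSE)
  idx <- seq.int(onset_frame + 1L, length.out = cfg$target_frames)
  landmark_session(session$subject_id, session$fps,
                   session$x[idx, , drop = FALSE], session$y[idx, , drop = FALSE],
                   session$z[idx, , drop = FALSE], session$conf[idx, , drop = FALSE])
}

#' Mask low-confidence landmark detections
#'
#' A cell is valid iff its confidence is at least the threshold (a
#' confidence that falls strictly below 0.50 marks the landmark invalid for
#' that frame). The session-wide missing fraction is the mean over the 33
#' landmarks of each landmark's invalid-frame fraction (cell mean), so a
#' single jittery landmark cannot dominate the exclusion decision.
#'
#' @param session A [landmark_session()].
#' @param cfg A [qc_config()].
#' @return A `masked_session`: the session plus `valid` (logical matrix),
#'   `landmark_missing` (length-33 fractions) and `missing_fraction`.
#' @export
mask_low_confidence <- function(session, cfg = qc_config()) {
  valid <- session$conf >= cfg$confidence_threshold
  landmark_missing <- colMeans(!valid)
  structure(list(session = session, valid = valid,
                 landmark_missing = landmark_missing,
                 missing_fraction = mean(landmark_missing),
                 threshold = cfg$confidence_threshold),
            class = "masked_session")
}

#' Session exclusion decision
#'
#' A recording is excluded when its overall missing fraction exceeds the
#' cap (strictly greater than 20% by default); sessions at exactly the cap
#' are retained.
#'
#' @param masked A `masked_session` from [mask_low_confidence()].
#' @param cfg A [qc_config()].
#' @return List with logical `exclude` and a human-readable `reason`.
#' @export
should_exclude <- function(masked, cfg = qc_config()) {
  ex <- masked$missing_fraction > cfg$session_missing_cap
  list(exclude = ex,
       reason = if (ex)
         sprintf("missing fraction %.4f exceeds cap %.2f",
                 masked$missing_fraction, cfg$session_missing_cap)
       else
         sprintf("missing fraction %.4f within cap %.2f",
                 masked$missing_fraction, cfg$session_missing_cap))
}

# Linear interpolation of invalid cells for one column, with end-holding.
interp_column <- function(v, ok) {
  if (all(ok)) return(v)
  if (!any(ok)) stop("landmark has no valid frames; cannot reconstruct",
                     call. = FALSE)
  idx <- seq_along(v)
  stats::approx(idx[ok], v[ok], xout = idx, method = "linear", rule = 2)$y
}

#' Reconstruct masked gaps by linear interpolation
#'
#' Invalid cells are replaced per landmark and per axis (x, y and z) by
#' linear interpolation between the nearest valid neighbours; leading and
#' trailing gaps hold the nearest valid value. Confidences of filled cells
#' are set to the threshold so they count as valid downstream yet remain
#' distinguishable from genuine detections.
#'
#' @param masked A `masked_session`.
#' @return A gap-free [landmark_session()].
#' @export
interpolate_gaps <- function(masked) {
  s <- masked$session
  x <- s$x; y <- s$y; z <- s$z; conf <- s$conf
  for (j in which(masked$landmark_missing > 0)) {
    ok <- masked$valid[, j]
    x[, j] <- interp_column(x[, j], ok)
    y[, j] <- interp_column(y[, j], ok)
    z[, j] <- interp_column(z[, j], ok)
    conf[!ok, j] <- masked$threshold
  }
  landmark_session(s$subject_id, s$fps, x, y, z, conf)
}

#' One Euro filter
#'
#' Adaptive first-order low-pass filter: a recursive exponential smoother
#' whose cutoff frequency rises with the (itself smoothed) signal speed,
#' attenuating high-frequency jitter at rest while preserving rapid,
#' behaviourally meaningful movements. With sampling period `Te = 1/fps`
#' and `tau(fc) = 1/(2*pi*fc)`, the smoothing weight is
#' `alpha = 1/(1 + tau/Te)`; the cutoff is
#' `fc_i = min_cutoff + beta * |vhat_i|`, where `vhat` is the derivative
#' estimate `(x_i - xhat_{i-1}) * fps` smoothed at the fixed `d_cutoff`.
#' The first output equals the first input.
#'
#' @param x Numeric vector, or a matrix whose columns are filtered
#'   independently (shared clock).
#' @param fps Sampling rate in Hz.
#' @param p [one_euro_params()].
#' @return Filtered vector or matrix, same shape as `x`.
#' @export
one_euro_filter <- function(x, fps, p = one_euro_params()) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n == 0L) stop("empty series", call. = FALSE)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  te <- 1 / fps
  alpha_of <- function(fc) 1 / (1 + 1 / (2 * pi * fc * te))
  a_d <- alpha_of(p$d_cutoff)
  out <- x
  xhat <- x[1L, ]
  vhat <- rep(0, ncol(x))
  if (n > 1L) for (i in 2L:n) {
    dx <- (x[i, ] - xhat) * fps
    vhat <- a_d * dx + (1 - a_d) * vhat
    a <- alpha_of(p$min_cutoff + p$beta * abs(vhat))
    xhat <- a * x[i, ] + (1 - a) * xhat
    out[i, ] <- xhat
  }
  if (vec) out[, 1L] else out
}

#' Run the full QC chain on one session
#'
#' Fixed order: trim to the analysis duration, mask low-confidence cells,
#' decide exclusion, reconstruct gaps by linear interpolation, then smooth
#' x and y per landmark with the One Euro filter (depth is carried through
#' untouched and only dropped later, at the root-frame projection). When
#' the session is excluded, no interpolation or smoothing is attempted.
#'
#' @param session A raw [landmark_session()].
#' @param cfg A [qc_config()]. If the session is already exactly
#'   `target_frames` long, trimming is the identity; pass `onset_frame` for
#'   longer recordings.
#' @param onset_frame 0-based onset frame for trimming.
#' @return List: `session` (QC-complete, or `NULL` if excluded), logical
#'   `excluded`, `reason`, `missing_fraction`, `landmark_missing`.
#' @export
qc_session <- function(session, cfg = qc_config(), onset_frame = 0L) {
  trimmed <- trim_session(session, onset_frame, cfg)
  masked <- mask_low_confidence(trimmed, cfg)
  dec <- should_exclude(masked, cfg)
  if (dec$exclude)
    return(list(session = NULL, excluded = TRUE, reason = dec$reason,
                missing_fraction = masked$missing_fraction,
                landmark_missing = masked$landmark_missing))
  filled <- interpolate_gaps(masked)
  sm <- landmark_session(
    filled$subject_id, filled$fps,
    one_euro_filter(filled$x, filled$fps, cfg$one_euro),
    one_euro_filter(filled$y, filled$fps, cfg$one_euro),
    filled$z, filled$conf)
  list(session = sm, excluded = FALSE, reason = dec$reason,
       missing_fraction = masked$missing_fraction,
       landmark_missing = masked$landmark_missing)
}
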