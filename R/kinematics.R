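#' The 15 composite anatomical points
#'
#' Maps each composite-point name to the raw BlazePose landmark ids it
#' aggregates. The head is the centroid of the 11 facial landmarks (nose,
#' inner/center/outer eyes, ears, mouth corners; ids 0--10), each distal
#' hand the centroid of thumb/index/pinky, each distal foot the centroid of
#' heel and foot-index; shoulders, elbows, wrists, knees and ankles are
#' singletons. The hips (ids 23, 24) define the pelvic root and are never a
#' region of their own.
#'
#' @return Named list of integer landmark-id vectors (15 entries).
#' @export
composite_map <- function() {
  list(
    head           = 0:10,
    left_shoulder  = 11L, right_shoulder = 12L,
    left_elbow     = 13L, right_elbow    = 14L,
    left_wrist     = 15L, right_wrist    = 16L,
    left_hand      = c(17L, 19L, 21L), right_hand = c(18L, 20L, 22L),
    left_knee      = 25L, right_knee     = 26L,
    left_ankle     = 27L, right_ankle    = 28L,
    left_foot      = c(29L, 31L), right_foot = c(30L, 32L))
}

#' Names of the 15 composite points
#' @return Character vector of region names in canonical order.
#' @export
region_names <- function() names(composite_map())

# 33 x k averaging matrix realizing the centroid of each region's members.
composite_weights <- function(map = composite_map()) {
  W <- matrix(0, 33L, length(map), dimnames = list(NULL, names(map)))
  for (i in seq_along(map)) {
    ids <- map[[i]]
    if (any(ids < 0 | ids > 32))
      stop("composite map references unknown landmark id", call. = FALSE)
    W[ids + 1L, i] <- 1 / length(ids)
  }
  W
}

#' Aggregate raw landmarks into composite-point trajectories
#'
#' Each composite frame value is the unweighted centroid of its member
#' landmarks, computed per axis (x, y and z; depth is only discarded later,
#' at the root-frame projection).
#'
#' @param session A QC-complete [landmark_session()].
#' @param map A composite map, by default [composite_map()].
#' @return List with per-axis `n_frames x 15` matrices `x`, `y`, `z`.
#' @export
to_composites <- function(session, map = composite_map()) {
  W <- composite_weights(map)
  list(x = session$x %*% W, y = session$y %*% W, z = session$z %*% W)
}

#' Express composite trajectories in the pelvic-root frame
#'
#' The root is the per-frame midpoint of the two hip landmarks (ids 23,
#' 24); every composite point is re-expressed relative to it, which cancels
#' any common-mode translation (camera drift and jitter). Depth is dropped
#' here: downstream displacement uses the image plane only, where monocular
#' estimates are stable.
#'
#' @param comps Output of [to_composites()].
#' @param session The session the composites came from (provides the hips).
#' @return List of `n_frames x 15` matrices `x`, `y` of root-relative
#'   coordinates.
#' @export
to_root_frame <- function(comps, session) {
  root_x <- (session$x[, 24L] + session$x[, 25L]) / 2
  root_y <- (session$y[, 24L] + session$y[, 25L]) / 2
  list(x = comps$x - root_x, y = comps$y - root_y)
}

#' Windowed Euclidean displacement of a trajectory
#'
#' Positions are averaged over consecutive non-overlapping blocks of `w`
#' frames (a trailing partial block is dropped) and the series of Euclidean
#' distances between successive block means is returned. Block averaging
#' suppresses frame-level estimator jitter while retaining behaviourally
#' meaningful movement; for a 9,000-frame session and `w = 5` this yields
#' 1,800 blocks and 1,799 displacement values.
#'
#' @param xy Two-column matrix (or a list with `x`, `y` vectors) of one
#'   root-relative trajectory.
#' @param w Window length in frames (5 primary; 10 and 15 for sensitivity).
#' @return Numeric vector of `floor(n/w) - 1` displacements.
#' @export
windowed_displacement <- function(xy, w = 5L) {
  if (is.list(xy) && !is.matrix(xy)) xy <- cbind(xy$x, xy$y)
  n <- nrow(xy)
  w <- as.integer(w)
  if (w < 1L) stop("window length must be >= 1", call. = FALSE)
  if (n < 2L * w)
    stop("trajectory too short: need at least 2 windows of ", w, " frames",
         call. = FALSE)
  nb <- n %/% w
  g <- rep(seq_len(nb), each = w)
  mx <- rowsum(xy[seq_len(nb * w), 1L], g) / w
  my <- rowsum(xy[seq_len(nb * w), 2L], g) / w
  as.numeric(sqrt(diff(mx)^2 + diff(my)^2))
}

#' Regional activity index: total displacement over the session
#'
#' @param disp Displacement series from [windowed_displacement()].
#' @return Sum of displacements (normalized image units), `>= 0`.
#' @export
activity_index <- function(disp) {
  if (length(disp) == 0L) stop("empty displacement series", call. = FALSE)
  sum(disp)
}

#' Movement variability: SD of the windowed-displacement series
#'
#' Sample standard deviation (n - 1 denominator) of the same displacement
#' series the activity index sums.
#'
#' @param disp Displacement series.
#' @return Non-negative scalar; 0 iff the series is constant.
#' @export
variability_index <- function(disp) {
  if (length(disp) < 2L)
    stop("need at least 2 displacement values for an SD", call. = FALSE)
  stats::sd(disp)
}

#' Global activity index
#'
#' The session-level summary is the sum of the 15 regional activity
#' indices. (The printed group means of the global index match the sum of
#' regional values, not their mean.)
#'
#' @param activity Named vector of the 15 regional activity indices.
#' @return Scalar sum.
#' @export
global_activity <- function(activity) {
  missing <- setdiff(region_names(), names(activity))
  if (length(missing))
    stop("missing regional activity for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(activity[region_names()])
}

#' Height-normalize an activity index
#' @param index Activity index (normalized image units).
#' @param height_cm Subject standing height in cm.
#' @return `index / height_cm`.
#' @export
normalize_by_height <- function(index, height_cm) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("height_cm must be positive", call. = FALSE)
  index / height_cm
}

#' Extract the movement feature set of one session
#'
#' Runs composites -> pelvic-root frame -> windowed displacement and
#' returns, per composite point, the activity index (summed displacement)
#' and variability SD, plus the global activity index.
#'
#' @param session A QC-complete [landmark_session()].
#' @param w Window length in frames.
#' @param map Composite map.
#' @return List with named vectors `activity`, `variability`, scalar
#'   `global`, and `window` (the `w` used).
#' @export
extract_features <- function(session, w = 5L, map = composite_map()) {
  rel <- to_root_frame(to_composites(session, map), session)
  regions <- colnames(rel$x)
  act <- vab <- stats::setNames(numeric(length(regions)), regions)
  for (r in regions) {
    d <- windowed_displacement(cbind(rel$x[, r], rel$y[, r]), w)
    act[r] <- activity_index(d)
    vab[r] <- variability_index(d)
  }
  list(activity = act, variability = vab,
       global = global_activity(act), window = as.integer(w))
}

#' Build the per-subject feature matrix for a set of sessions
#'
#' Applies QC ([qc_session()]) and [extract_features()] to every session
#' and joins the result to cohort metadata. Sessions failing QC (missing
#' data above the exclusion cap) are dropped and reported.
#'
#' @param sessions List of [landmark_session()] objects.
#' @param cohort Cohort `data.frame` ([read_cohort()]).
#' @param w Window length in frames.
#' @param cfg QC configuration ([qc_config()]).
#' @return List with `features` (data.frame: subject_id, metadata, 15
#'   activity columns, 15 `sd_` variability columns, `global`,
#'   `global_per_height`) and `qc` (per-subject QC report).
#' @export
feature_table <- function(sessions, cohort, w = 5L, cfg = qc_config()) {
  qc_rows <- list(); feat_rows <- list()
  for (s in sessions) {
    q <- qc_session(s, cfg)
    qc_rows[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id,
      missing_fraction = q$missing_fraction,
      excluded = q$excluded, stringsAsFactors = FALSE)
    if (q$excluded) next
    f <- extract_features(q$session, w = w)
    feat_rows[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id,
      t(f$activity), t(stats::setNames(f$variability,
                                       paste0("sd_", names(f$variability)))),
      global = f$global, stringsAsFactors = FALSE)
  }
  qc <- do.call(rbind, c(qc_rows, list(make.row.names = FALSE)))
  feats <- do.call(rbind, c(feat_rows, list(make.row.names = FALSE)))
  out <- merge(cohort, feats, by = "subject_id", sort = TRUE)
  out$global_per_height <- normalize_by_height(out$global, out$height_cm)
  list(features = out, qc = qc, window = as.integer(w))
}
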