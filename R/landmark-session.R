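#' Landmark session objects
#'
#' A landmark session holds the per-frame output of a 33-keypoint pose
#' estimator (BlazePose topology) for one recording: normalized image
#' coordinates `x`, `y`, relative depth `z`, and a per-landmark detection
#' confidence in `[0, 1]`. Frames are stored as rows of four
#' `n_frames x 33` matrices; column `j` is landmark id `j - 1` (ids 0--32).
#'
#' @param subject_id Character scalar identifying the recorded subject.
#' @param fps Frame rate in frames per second (30 for the study protocol).
#' @param x,y,z,conf Numeric `n_frames x 33` matrices.
#' @return An object of class `landmark_session`.
#' @export
landmark_session <- function(subject_id, fps, x, y, z, conf) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    stop("subject_id must be a single string", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar", call. = FALSE)
  mats <- list(x = x, y = y, z = z, conf = conf)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || ncol(m) != 33L)
      stop(sprintf("%s must be a matrix with 33 columns (one per landmark)", nm),
           call. = FALSE)
    if (nrow(m) != nrow(x))
      stop("coordinate and confidence matrices must have equal frame counts",
           call. = FALSE)
  }
  if (anyNA(conf) || any(conf < 0) || any(conf > 1))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  structure(
    list(subject_id = subject_id, fps = as.numeric(fps),
         x = unname(x), y = unname(y), z = unname(z), conf = unname(conf)),
    class = "landmark_session")
}

#' @export
print.landmark_session <- function(x, ...) {
  cat(sprintf("<landmark_session> subject %s: %d frames x 33 landmarks @ %g fps (%.1f s)\n",
              x$subject_id, n_frames(x), x$fps, n_frames(x) / x$fps))
  invisible(x)
}

#' Number of frames in a session
#' @param session A `landmark_session`.
#' @return Integer frame count.
#' @export
n_frames <- function(session) nrow(session$x)

#' Read a landmark session from its long-CSV dialect
#'
#' The on-disk dialect is a long CSV with header
#' `frame,landmark,x,y,z,confidence`: one row per (frame, landmark), UTF-8,
#' `.` decimal separator. Frames must be contiguous from 0 and each frame
#' must carry exactly the 33 landmark ids 0--32. Row order in the file is
#' not significant; it is normalized to (frame, landmark) on read.
#'
#' @param path Path to a session CSV.
#' @param subject_id Subject id to attach (defaults to the file stem).
#' @param fps Frame rate of the recording.
#' @return A validated [landmark_session()].
#' @export
read_session <- function(path, subject_id = NULL,  fps = 30) {
  if (!file.exists(path)) stop("no such session file: ", path, call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  req <- c("frame", "landmark", "x", "y", "z", "confidence")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("session file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(dt) == 0L)
    return(landmark_session(subject_id, fps,
                            matrix(0, 0, 33), matrix(0, 0, 33),
                            matrix(0, 0, 33), matrix(0, 0, 33)))
  data.table::setorderv(dt, c("frame", "landmark"))
  frames <- sort(unique(dt$frame))
  if (!identical(as.integer(frames), seq_along(frames) - 1L))
    stop("frame indices must be contiguous from 0; first gap near frame ",
         frames[which(as.integer(frames) != seq_along(frames) - 1L)[1]],
         call. = FALSE)
  cnt <- table(dt$frame)
  bad <- which(cnt != 33L)
  if (length(bad))
    stop(sprintf("frame %s has %d landmarks (expected 33)",
                 names(cnt)[bad[1]], cnt[[bad[1]]]), call. = FALSE)
  if (any(dt$landmark < 0 | dt$landmark > 32))
    stop("landmark ids must lie in 0..32", call. = FALSE)
  nf <- length(frames)
  shape <- function(v) matrix(v, nrow = nf, ncol = 33L, byrow = TRUE)
  landmark_session(subject_id, fps,
                   shape(dt$x), shape(dt$y), shape(dt$z), shape(dt$confidence))
}

#' Write a landmark session to the long-CSV dialect
#'
#' @param session A [landmark_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_session()] for the dialect.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "landmark_session"))
  nf <- n_frames(session)
  dt <- data.table::data.table(
    frame = rep(seq_len(nf) - 1L, each = 33L),
    landmark = rep(0:32, times = nf),
    x = as.vector(t(session$x)),
    y = as.vector(t(session$y)),
    z = as.vector(t(session$z)),
    confidence = as.vector(t(session$conf)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a cohort metadata table
#'
#' Expects a CSV with header
#' `subject_id,group,age,sex,height_cm,inattention,hyperactivity`. `group`
#' is parsed case-insensitively to `case`/`control`; symptom scores are the
#' 0--27 parent-report domain sums (9 items rated 0--3).
#'
#' @param path Path to the cohort CSV.
#' @return A `data.frame` of typed subject records.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  req <- c("subject_id", "group", "age", "sex", "height_cm",
           "inattention", "hyperactivity")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(dt)[, req]
  if (nrow(df) == 0L) return(df)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop("duplicate subject_id: ", dup[1], call. = FALSE)
  grp <- tolower(trimws(df$group))
  if (!all(grp %in% c("case", "control")))
    stop("group must be 'case' or 'control' (case-insensitive)", call. = FALSE)
  df$group <- factor(grp, levels = c("case", "control"))
  df$sex <- factor(toupper(trimws(df$sex)), levels = c("F", "M"))
  if (any(!is.finite(df$height_cm)) || any(df$height_cm <= 0))
    stop("height_cm must be positive", call. = FALSE)
  df
}

#' Write a cohort metadata table
#' @param cohort A cohort `data.frame` as returned by [read_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(data.table::as.data.table(cohort), path)
  invisible(path)
}

#' Adapter interface for external pose-estimation engines
#'
#' The package never decodes video. To use it on real recordings, supply an
#' `extract_fn` wrapping your pose engine (e.g. a MediaPipe/BlazePose
#' runner): it must take a video path and return a data.frame in the long
#' session dialect (`frame,landmark,x,y,z,confidence`). This adapter only
#' validates and repackages that output; it ships untested because no
#' engine is bundled.
#'
#' @param video_path Path handed to `extract_fn`.
#' @param extract_fn Function `(video_path, ...) -> data.frame`.
#' @param subject_id Subject id for the resulting session.
#' @param fps Frame rate of the video.
#' @param ... Passed on to `extract_fn`.
#' @return A [landmark_session()].
#' @export
session_from_engine <- function(video_path, extract_fn, subject_id,
                                fps = 30, ...) {
  df <- extract_fn(video_path, ...)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  data.table::fwrite(data.table::as.data.table(df), tmp)
  read_session(tmp, subject_id = subject_id, fps = fps)
}
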