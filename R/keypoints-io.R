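#' @keywords internal
"_PACKAGE"

#' The 17 PoseNet/COCO part names
#'
#' Closed set of keypoint names, in canonical order, as emitted by 2-D pose
#' estimators (nose, eyes, ears, shoulders, elbows, wrists, hips, knees,
#' ankles; left before right).
#'
#' @return Character vector of length 17.
#' @export
pose_parts <- function() {
  c("nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

#' Construct a pose sequence
#'
#' A `pose_sequence` holds a time-ordered series of frames, each with exactly
#' one keypoint per part. Internally coordinates are stored as
#' `n_frames x 17` matrices (columns named by part), which keeps frame
#' indices aligned with timestamps even when parts are missing: an absent
#' keypoint is represented as confidence 0 with `NA` coordinates, never
#' dropped.
#'
#' Image coordinates follow the screen convention of pose estimators:
#' x increases rightward, y increases DOWNWARD. All "height" semantics are
#' handled downstream in the kinematics layer. Timestamps are authoritative;
#' `nominal_fps` is advisory metadata used only as the resampling rate.
#'
#' @param t Numeric vector of per-frame timestamps (seconds, strictly
#'   increasing, at least one frame; kinematic derivation needs >= 2).
#' @param x,y Numeric matrices, one row per frame, 17 columns named by
#'   [pose_parts()]. Pixels.
#' @param conf Confidence matrix, same shape, values in `[0, 1]`.
#' @param nominal_fps Positive nominal frame rate (frames/second).
#' @param source_id Opaque string label for provenance.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(t, x, y, conf, nominal_fps = 30,
                          source_id = "unknown") {
  parts <- pose_parts()
  t <- as.numeric(t)
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  if (length(t) < 1L)
    stop("pose_sequence needs at least 1 frame", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(t < 0))
    stop("timestamps must be non-negative", call. = FALSE)
  for (m in list(x, y, conf)) {
    if (nrow(m) != length(t) || ncol(m) != 17L)
      stop("coordinate matrices must be n_frames x 17", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- parts
  if (is.null(colnames(y))) colnames(y) <- parts
  if (is.null(colnames(conf))) colnames(conf) <- parts
  if (!identical(colnames(x), parts) || !identical(colnames(y), parts) ||
      !identical(colnames(conf), parts))
    stop("columns must be named by the 17 canonical parts, in order",
         call. = FALSE)
  cf <- conf[is.finite(conf)]
  if (any(cf < 0 | cf > 1))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(nominal_fps) || length(nominal_fps) != 1L ||
      !is.finite(nominal_fps) || nominal_fps <= 0)
    stop("nominal_fps must be a positive number", call. = FALSE)
  structure(
    list(t = t, x = x, y = y, conf = conf,
         nominal_fps = as.numeric(nominal_fps),
         source_id = as.character(source_id)),
    class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf(
    "<pose_sequence> %d frames, %.3f-%.3f s, nominal %g fps, source '%s'\n",
    length(x$t), x$t[1], x$t[length(x$t)], x$nominal_fps, x$source_id))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$t)

#' Extract one frame from a pose sequence
#'
#' @param seq A `pose_sequence`.
#' @param i Frame index.
#' @return A `pose_frame`: list with `timestamp` and a 17-row data frame
#'   `keypoints` (`part`, `x`, `y`, `confidence`).
#' @export
pose_frame <- function(seq, i) {
  stopifnot(inherits(seq, "pose_sequence"),
            i >= 1L, i <= length(seq$t))
  structure(
    list(timestamp = seq$t[i],
         keypoints = data.frame(
           part = pose_parts(),
           x = as.numeric(seq$x[i, ]),
           y = as.numeric(seq$y[i, ]),
           confidence = as.numeric(seq$conf[i, ]),
           stringsAsFactors = FALSE)),
    class = "pose_frame")
}

# Assemble matrices from long-format records, filling absent parts with
# confidence 0 / NA coordinates so every frame carries all 17 parts.
.assemble_sequence <- function(t_vec, part_vec, x_vec, y_vec, score_vec,
                               nominal_fps, source_id) {
  parts <- pose_parts()
  bad <- setdiff(unique(part_vec), parts)
  if (length(bad))
    stop(sprintf("unknown part name(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  ts <- unique(t_vec)
  if (is.unsorted(ts, strictly = TRUE))
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  key <- paste(match(t_vec, ts), part_vec)
  if (anyDuplicated(key))
    stop("duplicate (t, part) record", call. = FALSE)
  n <- length(ts)
  X <- matrix(NA_real_, n, 17, dimnames = list(NULL, parts))
  Y <- X
  C <- matrix(0, n, 17, dimnames = list(NULL, parts))
  ri <- match(t_vec, ts)
  ci <- match(part_vec, parts)
  idx <- cbind(ri, ci)
  X[idx] <- x_vec
  Y[idx] <- y_vec
  C[idx] <- score_vec
  pose_sequence(ts, X, Y, C, nominal_fps = nominal_fps,
                source_id = source_id)
}

#' Read a pose sequence from JSON
#'
#' Expects the schema shipped in `inst/extdata/schemas/pose.schema.json`:
#' a top-level object with `fps`, optional `source_id`, and `frames`, each
#' frame `{t, keypoints: [{part, x, y, score}, ...]}`. Parts missing from a
#' frame are filled with confidence 0 and `NA` coordinates.
#'
#' @param con File path, connection, or a JSON string.
#' @return A [pose_sequence()].
#' @export
read_pose_json <- function(con) {
  obj <- tryCatch(
    jsonlite::fromJSON(con, simplifyVector = FALSE),
    error = function(e)
      stop(sprintf("malformed pose JSON: %s", conditionMessage(e)),
           call. = FALSE))
  if (!is.list(obj) || is.null(obj$frames) || is.null(obj$fps))
    stop("pose JSON must have top-level 'fps' and 'frames'", call. = FALSE)
  frames <- obj$frames
  if (!length(frames))
    stop("pose JSON has no frames", call. = FALSE)
  nk <- vapply(frames, function(f) length(f$keypoints), integer(1))
  t_vec <- rep(vapply(frames, function(f) {
    if (is.null(f$t)) stop("frame missing 't'", call. = FALSE)
    as.numeric(f$t)
  }, numeric(1)), nk)
  kps <- unlist(lapply(frames, function(f) f$keypoints), recursive = FALSE)
  getf <- function(field, default = NULL) {
    vapply(kps, function(k) {
      v <- k[[field]]
      if (is.null(v)) {
        if (is.null(default))
          stop(sprintf("keypoint missing '%s'", field), call. = FALSE)
        v <- default
      }
      if (field == "part") as.character(v) else as.numeric(v)
    }, if (field == "part") character(1) else numeric(1))
  }
  .assemble_sequence(
    t_vec, getf("part"), getf("x", NA_real_), getf("y", NA_real_),
    getf("score", 0),
    nominal_fps = as.numeric(obj$fps),
    source_id = if (is.null(obj$source_id)) "json" else
      as.character(obj$source_id))
}

#' Read a pose sequence from long-format CSV
#'
#' Long format with header `t,part,x,y,score`, one row per (frame, part).
#' Optional `# fps=<value>` / `# source_id=<label>` comment lines (as
#' written by [write_pose_csv()]) carry the metadata; otherwise `fps`
#' must be supplied.
#'
#' @param con File path or connection.
#' @param fps Nominal frame rate override; required when the file carries
#'   no `# fps=` header.
#' @return A [pose_sequence()].
#' @export
read_pose_csv <- function(con, fps = NULL) {
  lines <- readLines(con, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  fps_line <- grep("^#\\s*fps=", meta, value = TRUE)
  src_line <- grep("^#\\s*source_id=", meta, value = TRUE)
  if (length(fps_line))
    fps <- as.numeric(sub("^#\\s*fps=", "", fps_line[1]))
  if (is.null(fps) || !is.finite(fps))
    stop("fps not given and no '# fps=' header in CSV", call. = FALSE)
  source_id <- if (length(src_line))
    sub("^#\\s*source_id=", "", src_line[1]) else "csv"
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("t", "part", "x", "y", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("pose CSV missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!nrow(df)) stop("pose CSV has no data rows", call. = FALSE)
  .assemble_sequence(as.numeric(df$t), as.character(df$part),
                     as.numeric(df$x), as.numeric(df$y),
                     as.numeric(df$score),
                     nominal_fps = fps, source_id = source_id)
}

#' Write a pose sequence as long-format CSV
#'
#' One row per (frame, part); header `t,part,x,y,score`; timestamps and
#' coordinates rendered with enough digits (up to 15 significant) that
#' [read_pose_csv()] reproduces them to well under 1e-6 px. Metadata is
#' kept in `# fps=` / `# source_id=` comment lines.
#'
#' @param seq A [pose_sequence()].
#' @param path Output file path or writable connection.
#' @return Invisibly, the path/connection.
#' @export
write_pose_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  parts <- pose_parts()
  n <- length(seq$t)
  num <- function(v) {
    out <- vapply(v, function(z)
      if (is.na(z)) "NA" else sprintf("%.15g", z), character(1))
    out
  }
  rows <- character(n * 17L)
  k <- 1L
  for (i in seq_len(n)) {
    rows[k:(k + 16L)] <- paste(
      sprintf("%.15g", seq$t[i]), parts,
      num(seq$x[i, ]), num(seq$y[i, ]), num(seq$conf[i, ]),
      sep = ",")
    k <- k + 17L
  }
  out <- c(sprintf("# fps=%.15g", seq$nominal_fps),
           sprintf("# source_id=%s", seq$source_id),
           "t,part,x,y,score",
           rows)
  writeLines(out, path)
  invisible(path)
}

#' Write a pose sequence as JSON
#'
#' Inverse of [read_pose_json()]; emits the shipped pose schema.
#'
#' @param seq A [pose_sequence()].
#' @param path Output file path or connection.
#' @return Invisibly, the path/connection.
#' @export
write_pose_json <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  parts <- pose_parts()
  frames <- lapply(seq_along(seq$t), function(i) {
    list(t = seq$t[i],
         keypoints = lapply(seq_len(17L), function(j) {
           kp <- list(part = parts[j], x = seq$x[i, j], y = seq$y[i, j],
                      score = seq$conf[i, j])
           kp
         }))
  })
  obj <- list(fps = seq$nominal_fps, source_id = seq$source_id,
              frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Compare two pose sequences for near-equality
#'
#' Coordinates compared to `tol` pixels (NA matching NA), confidences and
#' timestamps exactly up to `tol`.
#'
#' @param a,b `pose_sequence` objects.
#' @param tol Numeric tolerance in px/seconds.
#' @return Logical scalar.
#' @export
pose_all_equal <- function(a, b, tol = 1e-6) {
  eqm <- function(p, q) {
    if (!all(dim(p) == dim(q))) return(FALSE)
    na_ok <- all(is.na(p) == is.na(q))
    ok <- all(abs(p[!is.na(p)] - q[!is.na(q)]) <= tol)
    na_ok && ok
  }
  length(a$t) == length(b$t) &&
    all(abs(a$t - b$t) <= tol) &&
    eqm(a$x, b$x) && eqm(a$y, b$y) && eqm(a$conf, b$conf)
}
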