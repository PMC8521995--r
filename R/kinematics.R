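#' Signal-cleaning configuration
#'
#' Controls how raw keypoint signals are turned into scoring-ready series:
#' keypoints below `min_confidence` are masked out, masked gaps up to
#' `max_gap` seconds are linearly interpolated, and the result is smoothed
#' with a centered moving average of `smoothing_window` seconds.
#'
#' @param min_confidence Confidence threshold in `[0, 1)`; samples whose
#'   contributing keypoints all fall below it are treated as undefined.
#'   Default 0.2.
#' @param smoothing_window Moving-average window in seconds (0 disables
#'   smoothing). Default 0.2.
#' @param max_gap Longest undefined gap, in seconds, that linear
#'   interpolation may bridge; a longer gap raises an unusable-segment
#'   error. Default 0.5.
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(min_confidence = 0.2, smoothing_window = 0.2,
                            max_gap = 0.5) {
  stopifnot(min_confidence >= 0, min_confidence < 1,
            smoothing_window >= 0, max_gap >= 0)
  structure(list(min_confidence = min_confidence,
                 smoothing_window = smoothing_window,
                 max_gap = max_gap),
            class = "cleaning_config")
}

.kp_xy <- function(frame, part) {
  k <- frame$keypoints
  row <- k[k$part == part, ]
  row
}

.pair_sep_x <- function(frame, left, right, min_confidence) {
  l <- .kp_xy(frame, left); r <- .kp_xy(frame, right)
  if (l$confidence < min_confidence || r$confidence < min_confidence ||
      is.na(l$x) || is.na(r$x))
    return(NA_real_)
  abs(l$x - r$x)
}

#' Shoulder width of a single frame
#'
#' Horizontal (x-axis) separation of the two shoulder keypoints, in pixels.
#' Horizontal rather than Euclidean separation is used because the exerciser
#' faces the camera, making x-separation robust to slight crouching.
#' Returns `NA` (undefined-sample sentinel) when either shoulder falls below
#' the confidence threshold.
#'
#' @param frame A `pose_frame` (see [pose_frame()]).
#' @param min_confidence Confidence threshold; default 0.2.
#' @return Width in px, or `NA`.
#' @export
shoulder_width <- function(frame, min_confidence = 0.2) {
  .pair_sep_x(frame, "left_shoulder", "right_shoulder", min_confidence)
}

#' Knee width of a single frame
#'
#' As [shoulder_width()], using the knee keypoints.
#'
#' @inheritParams shoulder_width
#' @return Width in px, or `NA`.
#' @export
knee_width <- function(frame, min_confidence = 0.2) {
  .pair_sep_x(frame, "left_knee", "right_knee", min_confidence)
}

#' Hip elevation above the knees for a single frame
#'
#' Signed vertical distance of the hip midpoint ABOVE the knee midpoint:
#' `(mean y of knees) - (mean y of hips)` in the y-down image convention.
#' Positive while the hip is above the knees, 0 at parallel depth, negative
#' below parallel. Left/right y-coordinates are averaged before the
#' difference is taken. `NA` when any of the four keypoints is below the
#' confidence threshold.
#'
#' @inheritParams shoulder_width
#' @return Elevation in px, or `NA`.
#' @export
hip_elevation <- function(frame, min_confidence = 0.2) {
  k <- frame$keypoints
  get <- function(p) k[k$part == p, ]
  lh <- get("left_hip"); rh <- get("right_hip")
  lk <- get("left_knee"); rk <- get("right_knee")
  confs <- c(lh$confidence, rh$confidence, lk$confidence, rk$confidence)
  ys <- c(lh$y, rh$y, lk$y, rk$y)
  if (any(confs < min_confidence) || any(is.na(ys))) return(NA_real_)
  mean(c(lk$y, rk$y)) - mean(c(lh$y, rh$y))
}

# Vectorized raw signals over all frames of a sequence (px; NA where the
# contributing keypoints miss the confidence threshold).
.raw_signals <- function(seq, min_confidence) {
  ok <- function(parts) {
    m <- seq$conf[, parts, drop = FALSE] >= min_confidence &
      !is.na(seq$x[, parts, drop = FALSE])
    rowSums(m) == length(parts)
  }
  sw <- abs(seq$x[, "left_shoulder"] - seq$x[, "right_shoulder"])
  sw[!ok(c("left_shoulder", "right_shoulder"))] <- NA_real_
  kw <- abs(seq$x[, "left_knee"] - seq$x[, "right_knee"])
  kw[!ok(c("left_knee", "right_knee"))] <- NA_real_
  hip_parts <- c("left_hip", "right_hip", "left_knee", "right_knee")
  okh <- rowSums(seq$conf[, hip_parts] >= min_confidence &
                   !is.na(seq$y[, hip_parts])) == 4L
  he <- (seq$y[, "left_knee"] + seq$y[, "right_knee"]) / 2 -
    (seq$y[, "left_hip"] + seq$y[, "right_hip"]) / 2
  he[!okh] <- NA_real_
  list(width_shoulder = sw, width_knee = kw, hip_elev = he)
}

# Interpolate a masked signal from its native timestamps onto a uniform
# grid, refusing to bridge undefined gaps longer than max_gap seconds.
.interp_grid <- function(t, v, grid, max_gap) {
  def <- which(!is.na(v))
  if (length(def) < 2L)
    stop("unusable sequence: fewer than 2 confident samples", call. = FALSE)
  gaps <- diff(t[def])
  if (any(gaps > max_gap + 1e-9))
    stop(sprintf(
      "unusable segment: undefined gap of %.3f s exceeds max_gap = %.3f s",
      max(gaps), max_gap), call. = FALSE)
  stats::approx(t[def], v[def], xout = grid, rule = 2)$y
}

# Centered moving average with edge windows shrunk symmetrically, so the
# output has no NA padding and constants pass through unchanged.
.moving_average <- function(v, half) {
  if (half < 1L) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

#' Derive the kinematic series a squat set is scored on
#'
#' Converts a [pose_sequence()] into per-sample scalar signals on a uniform
#' time grid at `seq$nominal_fps`: shoulder width, knee width, the
#' knee/shoulder ratio in percent, hip elevation above the knees, and hip
#' elevation normalized by its standing baseline in percent.
#'
#' The pipeline is: confidence masking, linear interpolation of masked gaps
#' (refusing gaps longer than `cfg$max_gap`), resampling onto the uniform
#' grid, then moving-average smoothing. The baseline is the median hip
#' elevation over the first 0.5 s of the set, which is robust to first-frame
#' jitter; `hip_norm` is 100% while standing at the baseline and reaches 0
#' at parallel depth, negative below parallel.
#'
#' @param seq A [pose_sequence()].
#' @param cfg A [cleaning_config()].
#' @return A `kinematic_series`: list with vectors `t`, `width_shoulder`,
#'   `width_knee`, `knee_ratio` (%), `hip_elev` (px), `hip_norm` (%), and
#'   scalars `baseline_hip` (px) and `fps`.
#' @export
derive_series <- function(seq, cfg = cleaning_config()) {
  stopifnot(inherits(seq, "pose_sequence"))
  raw <- .raw_signals(seq, cfg$min_confidence)
  if (all(is.na(raw$hip_elev)) || all(is.na(raw$width_shoulder)))
    stop("unusable sequence: no frame passes the confidence threshold",
         call. = FALSE)
  fps <- seq$nominal_fps
  t0 <- seq$t[1]
  t1 <- seq$t[length(seq$t)]
  grid <- t0 + seq.int(0L, floor((t1 - t0) * fps + 1e-9)) / fps
  sw <- .interp_grid(seq$t, raw$width_shoulder, grid, cfg$max_gap)
  kw <- .interp_grid(seq$t, raw$width_knee, grid, cfg$max_gap)
  he <- .interp_grid(seq$t, raw$hip_elev, grid, cfg$max_gap)
  half <- floor(cfg$smoothing_window * fps / 2)
  sw <- .moving_average(sw, half)
  kw <- .moving_average(kw, half)
  he <- .moving_average(he, half)
  if (any(sw <= 0))
    stop("degenerate posture: non-positive shoulder width", call. = FALSE)
  base_idx <- which(grid - t0 <= 0.5 + 1e-9)
  baseline <- stats::median(he[base_idx])
  if (!is.finite(baseline) || baseline <= 0)
    stop("degenerate posture: baseline hip elevation must be positive",
         call. = FALSE)
  structure(
    list(t = grid,
         width_shoulder = sw,
         width_knee = kw,
         knee_ratio = kw / sw * 100,
         hip_elev = he,
         hip_norm = he / baseline * 100,
         baseline_hip = baseline,
         fps = fps),
    class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf(
    paste0("<kinematic_series> %d samples @ %g fps, %.2f-%.2f s; ",
           "baseline hip %.1f px, min hip_norm %.1f%%\n"),
    length(x$t), x$fps, x$t[1], x$t[length(x$t)],
    x$baseline_hip, min(x$hip_norm)))
  invisible(x)
}
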