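#' Synthetic squat profile
#'
#' Parameter bundle for the squat-kinematics simulator. The simulated
#' exerciser faces the camera; the hip midpoint follows a cosine
#' descent/ascent each round,
#' `elev(t) = baseline * ((1+d)/2 + (1-d)/2 * cos(pi t'/3))` with
#' `t' = (t - phase_offset) / tempo_scale`, so the normalized hip height
#' sweeps 100% -> d x 100% -> 100% over one nominal 6-s round. With
#' `tempo_scale = 1` the trajectory sits exactly on the optimal rhythm
#' cosine, making the maximal-score case analytic.
#'
#' @param depth_frac Target minimum of normalized hip height as a fraction
#'   of baseline; default -0.1 (slightly below parallel, a full-depth
#'   squat).
#' @param stance_ratio Knee/shoulder width ratio; default 1.10.
#' @param tempo_scale Ratio of actual to nominal 6-s cadence (0.5 = twice
#'   too fast); default 1.
#' @param phase_offset Seconds of standing still before the first descent;
#'   default 0.
#' @param noise_sd Standard deviation of i.i.d. Gaussian keypoint jitter,
#'   px; default 0.
#' @param fps Frame rate, frames/s; default 30.
#' @param n_rounds Number of 6-s rounds simulated; default 10.
#' @param baseline_hip_px Standing hip-above-knee distance, px; default 100.
#' @param shoulder_px Shoulder width, px; default 80.
#' @param seed Integer RNG seed for the jitter; default 1.
#' @return A `squat_profile` list.
#' @export
squat_profile <- function(depth_frac = -0.1, stance_ratio = 1.10,
                          tempo_scale = 1, phase_offset = 0,
                          noise_sd = 0, fps = 30, n_rounds = 10,
                          baseline_hip_px = 100, shoulder_px = 80,
                          seed = 1L) {
  stopifnot(fps > 0, shoulder_px > 0, n_rounds >= 1, noise_sd >= 0,
            tempo_scale > 0, phase_offset >= 0, baseline_hip_px > 0)
  structure(list(depth_frac = depth_frac, stance_ratio = stance_ratio,
                 tempo_scale = tempo_scale, phase_offset = phase_offset,
                 noise_sd = noise_sd, fps = fps,
                 n_rounds = as.integer(n_rounds),
                 baseline_hip_px = baseline_hip_px,
                 shoulder_px = shoulder_px, seed = as.integer(seed)),
            class = "squat_profile")
}

#' Named simulator presets
#'
#' Each preset degrades exactly one aspect of the ideal squat:
#' * `ideal` — full depth (-10%), stance 110%, on-cadence: the maximal
#'   10-point round.
#' * `shallow` — minimum hip height 60% of baseline: depth score 0.
#' * `narrow` — stance 90% (< 100%): knee-width score 0.
#' * `wide` — stance 180% (>= 175%): knee-width score 0.
#' * `rushed` — tempo twice too fast (3-s repetitions against the 6-s
#'   clock): rhythm score below maximum.
#' * `noisy` — 3 px Gaussian keypoint jitter on the ideal motion.
#'
#' @param name One of `"ideal"`, `"shallow"`, `"narrow"`, `"wide"`,
#'   `"rushed"`, `"noisy"`.
#' @param ... Overrides passed on to [squat_profile()].
#' @return A [squat_profile()].
#' @export
squat_preset <- function(name, ...) {
  presets <- list(
    ideal   = list(),
    shallow = list(depth_frac = 0.6),
    narrow  = list(stance_ratio = 0.9),
    wide    = list(stance_ratio = 1.8),
    rushed  = list(tempo_scale = 0.5),
    noisy   = list(noise_sd = 3))
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(squat_profile, args)
}

#' Simulate a camera-facing squat set as a pose sequence
#'
#' Places all 17 keypoints from a simple articulated template: knees and
#' ankles stay planted at the stance width, the hip midpoint follows the
#' cosine descent/ascent of the profile, and the torso (shoulders, arms
#' held parallel to the ground, head) translates rigidly with the hip.
#' Image coordinates are y-down pixels in a nominal 640 x 480 frame.
#' Gaussian jitter of `noise_sd` px is added to every coordinate using the
#' profile's seed; identical profiles produce identical output, and the
#' caller's RNG state is left untouched.
#'
#' @param profile A [squat_profile()].
#' @param round_duration Nominal round length in seconds (the set clock);
#'   default 6.
#' @return A [pose_sequence()] covering
#'   `phase_offset + n_rounds * round_duration` seconds.
#' @export
simulate_squat <- function(profile, round_duration = 6) {
  stopifnot(inherits(profile, "squat_profile"))
  p <- profile
  duration <- p$phase_offset + p$n_rounds * round_duration
  t <- seq.int(0L, floor(duration * p$fps - 1e-9)) / p$fps
  n <- length(t)

  # hip elevation above the knees, px
  tp <- pmax(0, t - p$phase_offset) / p$tempo_scale
  d <- p$depth_frac
  elev <- p$baseline_hip_px * ((1 + d) / 2 + (1 - d) / 2 *
                                 cos(pi * tp / (round_duration / 2)))

  cx <- 320
  knee_y <- 370
  ankle_y <- 440
  hip_y <- knee_y - elev
  torso <- 120
  shoulder_y <- hip_y - torso
  half_sh <- p$shoulder_px / 2
  half_kn <- p$shoulder_px * p$stance_ratio / 2
  half_hip <- p$shoulder_px * 0.4

  parts <- pose_parts()
  X <- matrix(NA_real_, n, 17, dimnames = list(NULL, parts))
  Y <- X
  set_col <- function(part, x, y) {
    X[, part] <<- x
    Y[, part] <<- y
  }
  set_col("nose", cx, shoulder_y - 40)
  set_col("left_eye", cx + 10, shoulder_y - 45)
  set_col("right_eye", cx - 10, shoulder_y - 45)
  set_col("left_ear", cx + 18, shoulder_y - 40)
  set_col("right_ear", cx - 18, shoulder_y - 40)
  set_col("left_shoulder", cx + half_sh, shoulder_y)
  set_col("right_shoulder", cx - half_sh, shoulder_y)
  set_col("left_elbow", cx + half_sh + 30, shoulder_y)
  set_col("right_elbow", cx - half_sh - 30, shoulder_y)
  set_col("left_wrist", cx + half_sh + 60, shoulder_y)
  set_col("right_wrist", cx - half_sh - 60, shoulder_y)
  set_col("left_hip", cx + half_hip, hip_y)
  set_col("right_hip", cx - half_hip, hip_y)
  set_col("left_knee", cx + half_kn, knee_y)
  set_col("right_knee", cx - half_kn, knee_y)
  set_col("left_ankle", cx + half_kn, ankle_y)
  set_col("right_ankle", cx - half_kn, ankle_y)

  if (p$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(p$seed)
    X <- X + matrix(stats::rnorm(n * 17L, sd = p$noise_sd), n, 17)
    Y <- Y + matrix(stats::rnorm(n * 17L, sd = p$noise_sd), n, 17)
  }

  C <- matrix(0.9, n, 17, dimnames = list(NULL, parts))
  pose_sequence(t, X, Y, C, nominal_fps = p$fps, source_id = "simulated")
}
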