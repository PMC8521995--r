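#' Knee-width level for a knee/shoulder ratio
#'
#' Index 1 evaluates stance: the knee width should be slightly greater than
#' the shoulder width to minimize shear force. Per-sample levels on the
#' ratio r = Width_Knee / Width_Shoulder x 100%:
#' 3 points for 100% <= r < 125%, 2 for 125% <= r < 150%,
#' 1 for 150% <= r < 175%, 0 for r < 100% or r >= 175%.
#' Bands are half-open, lower-closed.
#'
#' @param knee_ratio Numeric vector of ratios in percent.
#' @return Integer vector of points in 0..3 (`NA` for non-finite input).
#' @export
level_index1 <- function(knee_ratio) {
  out <- rep(NA_integer_, length(knee_ratio))
  f <- is.finite(knee_ratio)
  r <- knee_ratio[f]
  lv <- integer(length(r))
  lv[r >= 100 & r < 125] <- 3L
  lv[r >= 125 & r < 150] <- 2L
  lv[r >= 150 & r < 175] <- 1L
  out[f] <- lv
  out
}

# Mode with ties broken toward the LOWER score: on ambiguity the rubric
# never inflates performance.
.mode_lowest <- function(levels) {
  tab <- table(levels)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

#' Score Index 1 (knee width) for one round
#'
#' The most frequent per-sample level over the round is the round score;
#' ties break toward the lower score. Undefined (low-confidence) samples
#' are excluded from the mode; a round with no defined samples scores 0
#' and is flagged empty.
#'
#' @param knee_ratio Per-sample knee/shoulder ratios (%) within the round.
#' @return List with `points` (0..3), `modal_level`, and `empty` flag.
#' @export
score_index1 <- function(knee_ratio) {
  lv <- level_index1(knee_ratio)
  lv <- lv[!is.na(lv)]
  if (!length(lv))
    return(list(points = 0L, modal_level = NA_integer_, empty = TRUE))
  m <- .mode_lowest(lv)
  list(points = m, modal_level = m, empty = FALSE)
}

#' Score Index 2 (hip position) for one round
#'
#' Depth is judged by the minimum of the normalized hip height within the
#' round, m = min(Height_Hip(t)/Height_Hip(0) x 100%): 3 points for
#' m <= 0 (full depth, at/below parallel), 2 for 0 < m <= 25, 1 for
#' 25 < m <= 50, 0 for m > 50 (upper-closed bands).
#'
#' @param hip_norm Per-sample normalized hip heights (%) within the round.
#' @return List with `points` (0..3), `min_hip_norm`, and `empty` flag.
#' @export
score_index2 <- function(hip_norm) {
  v <- hip_norm[is.finite(hip_norm)]
  if (!length(v))
    return(list(points = 0L, min_hip_norm = NA_real_, empty = TRUE))
  m <- min(v)
  pts <- if (m <= 0) 3L else if (m <= 25) 2L else if (m <= 50) 1L else 0L
  list(points = pts, min_hip_norm = m, empty = FALSE)
}

#' Rhythm trace of one round
#'
#' The hip trajectory is rescaled to `[-1, 1]` within the round,
#' rhythm(t) = 2 (H(t) - H_min) / (H_max - H_min) - 1 with the extrema
#' taken within the round, and compared with the optimal cadence
#' Optimal(t) = cos(pi t / 3) (down in 3 s, up in 3 s). A sample is
#' in-band when |rhythm - optimal| <= `band_halfwidth` — the band is
#' additive in normalized units, the constant-width corridor around the
#' cosine; a multiplicative band would vanish where the cosine crosses 0.
#'
#' Undefined samples are excluded from both the in-band count and the
#' total. A motionless round (H_max = H_min) is degenerate and scores 0.
#'
#' @param hip_elev Per-sample hip elevations (px) within the round.
#' @param t_rel Seconds from the round start, same length.
#' @param band_halfwidth Half-width of the optimal band in normalized
#'   rhythm units; default 0.3 (30% of the half-range).
#' @return A `rhythm_trace`: list with `t_rel`, `rhythm`, `optimal`,
#'   `in_band`, counts `n_rhythm`/`n_all`, `band_halfwidth`, and
#'   `degenerate` flag.
#' @export
rhythm_trace <- function(hip_elev, t_rel, band_halfwidth = 0.3) {
  stopifnot(length(hip_elev) == length(t_rel))
  def <- is.finite(hip_elev)
  optimal <- cos(pi * t_rel / 3)
  if (sum(def) < 2L) {
    return(structure(list(t_rel = t_rel, rhythm = rep(NA_real_, length(t_rel)),
                          optimal = optimal, in_band = rep(NA, length(t_rel)),
                          n_rhythm = 0L, n_all = 0L,
                          band_halfwidth = band_halfwidth, degenerate = TRUE),
                     class = "rhythm_trace"))
  }
  h_min <- min(hip_elev[def])
  h_max <- max(hip_elev[def])
  if (h_max - h_min <= .Machine$double.eps * max(1, abs(h_max))) {
    return(structure(list(t_rel = t_rel, rhythm = rep(NA_real_, length(t_rel)),
                          optimal = optimal, in_band = rep(NA, length(t_rel)),
                          n_rhythm = 0L, n_all = sum(def),
                          band_halfwidth = band_halfwidth, degenerate = TRUE),
                     class = "rhythm_trace"))
  }
  rhythm <- 2 * (hip_elev - h_min) / (h_max - h_min) - 1
  in_band <- abs(rhythm - optimal) <= band_halfwidth
  in_band[!def] <- NA
  structure(list(t_rel = t_rel, rhythm = rhythm, optimal = optimal,
                 in_band = in_band,
                 n_rhythm = sum(in_band[def]),
                 n_all = sum(def),
                 band_halfwidth = band_halfwidth, degenerate = FALSE),
            class = "rhythm_trace")
}

#' Score Index 3 (rhythm) from a rhythm trace
#'
#' The in-band fraction f = N_Rhythm / N_All x 100% maps to points:
#' 4 for f >= 80, 3 for 60 <= f < 80, 2 for 40 <= f < 60,
#' 1 for 20 <= f < 40, 0 for f < 20 (lower-closed bands). A degenerate
#' (motionless) trace scores 0.
#'
#' @param trace A [rhythm_trace()].
#' @return List with `points` (0..4), `fraction` (%), and `degenerate`.
#' @export
score_index3 <- function(trace) {
  stopifnot(inherits(trace, "rhythm_trace"))
  if (trace$degenerate || trace$n_all == 0L)
    return(list(points = 0L, fraction = NA_real_, degenerate = TRUE))
  f <- trace$n_rhythm / trace$n_all * 100
  pts <- if (f >= 80) 4L else if (f >= 60) 3L else if (f >= 40) 2L else
    if (f >= 20) 1L else 0L
  list(points = pts, fraction = f, degenerate = FALSE)
}

#' Score one repetition round
#'
#' Applies the three-index rubric to one segmented round of a kinematic
#' series and returns the per-round breakdown (total = Index1 + Index2 +
#' Index3, in 0..10). Diagnostics carry the modal knee-ratio level, the
#' minimum normalized hip height, the in-band rhythm fraction, and a
#' low-quality flag when fewer than half the round's samples are defined.
#'
#' @param series A `kinematic_series`.
#' @param window One row of [segment_fixed()]'s output (a list/data frame
#'   row with `round_index`, `t_start`, `i_start`, `i_end`, `empty`).
#' @param band_halfwidth Rhythm band half-width; default 0.3.
#' @return A `round_score` list: `round_index`, `index1`, `index2`,
#'   `index3`, `total`, `empty`, `diagnostics`.
#' @export
score_round <- function(series, window, band_halfwidth = 0.3) {
  stopifnot(inherits(series, "kinematic_series"))
  ri <- as.integer(window$round_index)
  if (isTRUE(window$empty) || is.na(window$i_start)) {
    return(structure(
      list(round_index = ri, index1 = 0L, index2 = 0L, index3 = 0L,
           total = 0L, empty = TRUE,
           diagnostics = list(modal_level = NA_integer_,
                              min_hip_norm = NA_real_,
                              in_band_fraction = NA_real_,
                              low_quality = TRUE)),
      class = "round_score"))
  }
  idx <- seq.int(window$i_start, window$i_end)
  kr <- series$knee_ratio[idx]
  hn <- series$hip_norm[idx]
  he <- series$hip_elev[idx]
  t_rel <- series$t[idx] - window$t_start
  s1 <- score_index1(kr)
  s2 <- score_index2(hn)
  tr <- rhythm_trace(he, t_rel, band_halfwidth)
  s3 <- score_index3(tr)
  defined_frac <- mean(is.finite(he) & is.finite(kr))
  structure(
    list(round_index = ri,
         index1 = s1$points, index2 = s2$points, index3 = s3$points,
         total = s1$points + s2$points + s3$points,
         empty = FALSE,
         diagnostics = list(modal_level = s1$modal_level,
                            min_hip_norm = s2$min_hip_norm,
                            in_band_fraction = s3$fraction,
                            low_quality = defined_frac < 0.5)),
    class = "round_score")
}

#' Score a full squat set
#'
#' Segments the series into fixed-cadence rounds and scores each; returns
#' the per-round table, per-index column sums (max 30/30/40 over a 10-round
#' set) and the grand total in 0..100. Higher scores represent the optimal
#' squat exercise.
#'
#' @param series A `kinematic_series`.
#' @param cfg A [set_config()].
#' @param t0 Set start time (seconds); default 0.
#' @param band_halfwidth Rhythm band half-width; default 0.3.
#' @return A `set_score`: list with `rounds` (data frame), `round_scores`
#'   (list of `round_score`), `sum_index1`, `sum_index2`, `sum_index3`,
#'   `grand_total`, and the `set_config` used.
#' @export
score_set <- function(series, cfg = set_config(), t0 = 0,
                      band_halfwidth = 0.3) {
  windows <- segment_fixed(series, cfg, t0)
  scores <- lapply(seq_len(nrow(windows)), function(r)
    score_round(series, windows[r, ], band_halfwidth))
  rounds <- data.frame(
    round_index = vapply(scores, `[[`, integer(1), "round_index"),
    index1 = vapply(scores, `[[`, integer(1), "index1"),
    index2 = vapply(scores, `[[`, integer(1), "index2"),
    index3 = vapply(scores, `[[`, integer(1), "index3"),
    total = vapply(scores, `[[`, integer(1), "total"),
    empty = vapply(scores, `[[`, logical(1), "empty"))
  structure(
    list(rounds = rounds,
         round_scores = scores,
         sum_index1 = sum(rounds$index1),
         sum_index2 = sum(rounds$index2),
         sum_index3 = sum(rounds$index3),
         grand_total = sum(rounds$total),
         config = cfg),
    class = "set_score")
}

#' @export
print.set_score <- function(x, ...) {
  cat(sprintf("<set_score> grand total %d/%d\n",
              x$grand_total, 10L * x$config$n_rounds))
  cat(sprintf("  Index 1 (knee width) %d | Index 2 (hip depth) %d | Index 3 (rhythm) %d\n",
              x$sum_index1, x$sum_index2, x$sum_index3))
  print(x$rounds, row.names = FALSE)
  invisible(x)
}
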