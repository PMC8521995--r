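#' Set structure configuration
#'
#' The exercise protocol is a fixed-cadence set: `n_rounds` repetitions of
#' `round_duration` seconds each (defaults 10 x 6 s = 60 s).
#'
#' @param n_rounds Number of repetition rounds; default 10.
#' @param round_duration Round length in seconds; default 6.
#' @return A `set_config` list with derived `set_duration`.
#' @export
set_config <- function(n_rounds = 10, round_duration = 6) {
  stopifnot(n_rounds >= 1, round_duration > 0)
  structure(list(n_rounds = as.integer(n_rounds),
                 round_duration = round_duration,
                 set_duration = n_rounds * round_duration),
            class = "set_config")
}

#' Partition a kinematic series into fixed-cadence rounds
#'
#' Splits `[t0, t0 + set_duration)` into `n_rounds` contiguous half-open
#' windows `[t_start, t_end)` of `round_duration` seconds; a sample exactly
#' on a boundary belongs to the later window. Fixed-cadence segmentation
#' (rather than valley detection) mirrors the deployed voice-paced protocol
#' the rhythm rubric assumes.
#'
#' Windows beyond the end of the series are marked empty; a series shorter
#' than the full set triggers a warning, and one shorter than a single round
#' is an error.
#'
#' @param series A `kinematic_series` from [derive_series()].
#' @param cfg A [set_config()].
#' @param t0 Set start time in seconds (e.g. from [detect_start()]).
#' @return A data frame with one row per round: `round_index`, `t_start`,
#'   `t_end`, `i_start`, `i_end` (sample index range, `NA` when empty), and
#'   `empty`.
#' @export
segment_fixed <- function(series, cfg = set_config(), t0 = 0) {
  stopifnot(inherits(series, "kinematic_series"))
  t <- series$t
  t_last <- t[length(t)]
  # the final sample covers one sample period past its timestamp
  coverage <- t_last + 1 / series$fps - t0
  if (coverage < cfg$round_duration - 1e-9)
    stop("series too short: does not cover one full round", call. = FALSE)
  if (coverage < cfg$set_duration - 1e-9)
    warning(sprintf(
      "series covers %.1f s of a %.1f s set; trailing rounds marked empty",
      coverage, cfg$set_duration), call. = FALSE)
  starts <- t0 + (seq_len(cfg$n_rounds) - 1L) * cfg$round_duration
  ends <- starts + cfg$round_duration
  i_start <- integer(cfg$n_rounds)
  i_end <- integer(cfg$n_rounds)
  for (r in seq_len(cfg$n_rounds)) {
    in_win <- which(t >= starts[r] - 1e-9 & t < ends[r] - 1e-9)
    if (length(in_win)) {
      i_start[r] <- in_win[1]
      i_end[r] <- in_win[length(in_win)]
    } else {
      i_start[r] <- NA_integer_
      i_end[r] <- NA_integer_
    }
  }
  data.frame(round_index = seq_len(cfg$n_rounds),
             t_start = starts, t_end = ends,
             i_start = i_start, i_end = i_end,
             empty = is.na(i_start))
}

#' Detect the start of a squat set from the hip trajectory
#'
#' Offline recordings need a start cue: the deployed system paces the
#' exerciser with a counting voice, so the recording may begin before the
#' first repetition. The cue is the trough of the first descent: the first
#' excursion of normalized hip height below `100 - threshold` percent
#' qualifies as a genuine repetition (rather than jitter), its minimum marks
#' the bottom of that repetition, and the round clock starts half a round
#' (3 s for the 6-s cadence) before the bottom, clipped at 0 so the clock
#' never starts before the recording.
#'
#' @param series A `kinematic_series`.
#' @param threshold Descent threshold as % of baseline; default 10.
#' @param round_duration Round length in seconds; default 6.
#' @return Start time `t0` in seconds.
#' @export
detect_start <- function(series, threshold = 10, round_duration = 6) {
  stopifnot(inherits(series, "kinematic_series"))
  below <- series$hip_norm < 100 - threshold
  i0 <- which(below)[1]
  if (is.na(i0))
    stop("start not found: hip never descends below threshold",
         call. = FALSE)
  i1 <- i0
  n <- length(below)
  while (i1 < n && below[i1 + 1L]) i1 <- i1 + 1L
  trough <- i0 - 1L + which.min(series$hip_norm[i0:i1])
  max(0, series$t[trough] - round_duration / 2)
}
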