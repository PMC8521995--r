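# Shared fixtures: all synthetic, built in code at test time.

# A single standing frame as a pose_frame, with chosen separations.
standing_frame <- function(shoulder_x = c(100, 180),
                           knee_x = c(90, 190),
                           hip_y = 300, knee_y = 400,
                           conf = 0.9) {
  parts <- pose_parts()
  x <- stats::setNames(rep(320, 17), parts)
  y <- stats::setNames(rep(200, 17), parts)
  x["left_shoulder"] <- shoulder_x[1]; x["right_shoulder"] <- shoulder_x[2]
  x["left_knee"] <- knee_x[1]; x["right_knee"] <- knee_x[2]
  y["left_hip"] <- hip_y; y["right_hip"] <- hip_y
  y["left_knee"] <- knee_y; y["right_knee"] <- knee_y
  cf <- stats::setNames(rep(conf, 17), parts)
  seq2 <- pose_sequence(c(0, 1/30),
                        rbind(x, x), rbind(y, y), rbind(cf, cf),
                        nominal_fps = 30)
  pose_frame(seq2, 1)
}

# Constant standing pose sequence of given duration.
standing_sequence <- function(duration = 2, fps = 30,
                              hip_y = 300, knee_y = 400) {
  parts <- pose_parts()
  n <- duration * fps
  x <- matrix(rep(c(320, 330, 310, 338, 302, 360, 280, 390, 250, 420, 220,
                    352, 288, 364, 276, 364, 276), each = n),
              n, 17, dimnames = list(NULL, parts))
  y <- matrix(200, n, 17, dimnames = list(NULL, parts))
  y[, c("left_hip", "right_hip")] <- hip_y
  y[, c("left_knee", "right_knee")] <- knee_y
  y[, c("left_ankle", "right_ankle")] <- knee_y + 70
  conf <- matrix(0.9, n, 17, dimnames = list(NULL, parts))
  pose_sequence((seq_len(n) - 1) / fps, x, y, conf, nominal_fps = fps)
}

# Independent per-sample oracle for the rhythm in-band count: explicit loop
# over samples, no vectorization shared with the implementation.
oracle_in_band_count <- function(hip_elev, t_rel, band = 0.3) {
  def <- which(is.finite(hip_elev))
  h <- hip_elev[def]
  lo <- min(h); hi <- max(h)
  if (hi <= lo) return(NA_integer_)
  count <- 0L
  for (i in def) {
    r <- 2 * (hip_elev[i] - lo) / (hi - lo) - 1
    o <- cos(pi * t_rel[i] / 3)
    if (abs(r - o) <= band) count <- count + 1L
  }
  count
}

# Independent oracle for the knee-width level of one ratio value.
oracle_level1 <- function(r) {
  if (!is.finite(r)) return(NA_integer_)
  if (r >= 100 && r < 125) return(3L)
  if (r >= 125 && r < 150) return(2L)
  if (r >= 150 && r < 175) return(1L)
  0L
}

# Survey records reproducing the published cohort's printed marginal
# counts per age group (synthetic expansion; joint structure is arbitrary).
table1_records <- function() {
  expand_group <- function(n, age, men, inc, not_chg, dec,
                           insufficient, regular) {
    data.frame(
      age = rep(age, n),
      gender = c(rep("men", men), rep("women", n - men)),
      exercise_change = c(rep("increased", inc), rep("not_changed", not_chg),
                          rep("decreased", dec)),
      freq_category = rep("1-2 times/week", n),
      duration_category = rep("30-50 min", n),
      habit = c(rep("insufficient", insufficient), rep("regular", regular)),
      stringsAsFactors = FALSE)
  }
  rbind(
    expand_group(105, 25, men = 61, inc = 20, not_chg = 45, dec = 40,
                 insufficient = 52, regular = 53),
    expand_group(58, 48, men = 22, inc = 14, not_chg = 21, dec = 23,
                 insufficient = 34, regular = 24),
    expand_group(37, 75, men = 20, inc = 8, not_chg = 16, dec = 13,
                 insufficient = 12, regular = 25))
}

# Look up one percentage cell from a cohort summary.
summary_pct <- function(s, group, variable, category) {
  tab <- s$table
  tab$pct[tab$group == group & tab$variable == variable &
            tab$category == category]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
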