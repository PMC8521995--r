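test_that("knee-width levels follow the half-open rubric bands", {
  expect_equal(level_index1(110), 3L)
  expect_equal(level_index1(100), 3L)
  expect_equal(level_index1(125), 2L)
  expect_equal(level_index1(150), 1L)
  expect_equal(level_index1(175), 0L)
  expect_equal(level_index1(90), 0L)
  expect_true(is.na(level_index1(NaN)))
  # agrees with the per-value oracle over a dense sweep
  r <- seq(50, 220, by = 0.25)
  expect_equal(level_index1(r),
               vapply(r, oracle_level1, integer(1)))
})

test_that("Index 1 takes the most frequent level; ties break low", {
  expect_equal(score_index1(rep(110, 180))$points, 3L)
  expect_equal(score_index1(c(rep(110, 60), rep(130, 120)))$points, 2L)
  expect_equal(score_index1(c(rep(110, 90), rep(130, 90)))$points, 2L)
  empty <- score_index1(rep(NaN, 10))
  expect_equal(empty$points, 0L)
  expect_true(empty$empty)
})

test_that("Index 2 scores the minimum normalized hip height, upper-closed", {
  expect_equal(score_index2(c(80, 20, -10, 50))$points, 3L)
  expect_equal(score_index2(c(80, 0))$points, 3L)
  expect_equal(score_index2(c(80, 25))$points, 2L)
  expect_equal(score_index2(c(80, 25.01))$points, 1L)
  expect_equal(score_index2(c(80, 50))$points, 1L)
  expect_equal(score_index2(c(80, 60))$points, 0L)
  expect_true(score_index2(rep(NA_real_, 5))$empty)
})

test_that("rhythm normalization hits its endpoints and flags no-movement", {
  t_rel <- seq(0, 6, by = 1 / 30)[-181]
  h <- 50 + 40 * cos(pi * t_rel / 3)
  tr <- rhythm_trace(h, t_rel)
  expect_equal(tr$rhythm[which.max(h)], 1)
  expect_equal(tr$rhythm[which.min(h)], -1)
  # trajectory on the optimal cosine is in-band at every sample
  expect_true(all(tr$in_band))
  expect_equal(tr$n_rhythm, tr$n_all)
  flat <- rhythm_trace(rep(10, 180), t_rel)
  expect_true(flat$degenerate)
  expect_equal(score_index3(flat)$points, 0L)
})

test_that("Index 3 bands on the in-band fraction are lower-closed", {
  mk <- function(frac, n = 200) {
    # cosine samples, with a chosen share shifted 0.4 off the optimal
    # curve (out of the 0.3 band) while preserving the round's extrema
    t_rel <- (seq_len(n) - 1) * 6 / n
    o <- cos(pi * t_rel / 3)
    h <- o
    k <- round((1 - frac) * n)
    elig <- setdiff(seq_len(n), c(1L, n / 2 + 1L))  # keep max/min samples
    flip <- elig[seq_len(k)]
    h[flip] <- ifelse(o[flip] >= 0, o[flip] - 0.4, o[flip] + 0.4)
    rhythm_trace(h, t_rel)
  }
  expect_equal(score_index3(mk(0.85))$points, 4L)
  expect_equal(score_index3(mk(0.60))$points, 3L)
  expect_equal(score_index3(mk(0.595))$points, 2L)
  expect_equal(score_index3(mk(0.40))$points, 2L)
  expect_equal(score_index3(mk(0.20))$points, 1L)
  expect_equal(score_index3(mk(0.10))$points, 0L)
})

test_that("vectorized in-band count equals a per-sample loop on random traces", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(20:240, 1)
    t_rel <- sort(stats::runif(n, 0, 6))
    h <- stats::runif(n, -50, 150)
    if (i %% 3 == 0) h[sample(n, sample(0:5, 1))] <- NA
    tr <- rhythm_trace(h, t_rel)
    expected <- oracle_in_band_count(h, t_rel)
    if (is.na(expected)) {
      expect_true(tr$degenerate)
    } else {
      expect_equal(tr$n_rhythm, expected)
      expect_equal(tr$n_all, sum(is.finite(h)))
    }
  }
})

test_that("scores stay in bounds on 1000 random rounds", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    s1 <- score_index1(stats::runif(n, 40, 260))$points
    s2 <- score_index2(stats::runif(n, -40, 160))$points
    tr <- rhythm_trace(stats::runif(n, 0, 120), sort(stats::runif(n, 0, 6)))
    s3 <- score_index3(tr)$points
    expect_true(s1 %in% 0:3)
    expect_true(s2 %in% 0:3)
    expect_true(s3 %in% 0:4)
    expect_true(s1 + s2 + s3 <= 10)
  }
})

test_that("Index 2 is monotone in depth and Index 3 in band fraction", {
  # deeper minimum never decreases Index 2
  mins <- seq(90, -20, by = -5)
  pts2 <- vapply(mins, function(m) score_index2(c(100, m))$points, integer(1))
  expect_true(all(diff(pts2) >= 0))
  # larger in-band fraction never decreases Index 3
  n <- 100
  t_rel <- (seq_len(n) - 1) * 6 / n
  h0 <- cos(pi * t_rel / 3)
  elig <- setdiff(seq_len(n), c(1L, n / 2 + 1L))
  pts3 <- vapply(seq(0, length(elig), by = 7), function(k) {
    h <- h0
    flip <- elig[seq_len(k)]
    h[flip] <- ifelse(h0[flip] >= 0, h0[flip] - 0.4, h0[flip] + 0.4)
    score_index3(rhythm_trace(h, t_rel))$points
  }, integer(1))
  expect_true(all(diff(pts3) <= 0))
})

test_that("an ideal simulated round scores 10 and an empty round 0", {
  s <- derive_series(simulate_squat(squat_profile(n_rounds = 2)))
  w <- suppressWarnings(segment_fixed(s, set_config(n_rounds = 3), t0 = 0))
  r1 <- score_round(s, w[1, ])
  expect_equal(c(r1$index1, r1$index2, r1$index3), c(3L, 3L, 4L))
  expect_equal(r1$total, 10L)
  r3 <- score_round(s, w[3, ])
  expect_true(r3$empty)
  expect_equal(r3$total, 0L)
})

test_that("set scoring composes rounds and conserves totals", {
  s <- derive_series(simulate_squat(squat_profile()))
  sc <- score_set(s)
  expect_equal(sc$grand_total, 100L)
  expect_equal(c(sc$sum_index1, sc$sum_index2, sc$sum_index3),
               c(30L, 30L, 40L))
  expect_equal(sc$grand_total, sum(sc$rounds$total))
  expect_equal(sc$rounds$total,
               sc$rounds$index1 + sc$rounds$index2 + sc$rounds$index3)
})

test_that("set totals are invariant under coordinate scaling of the input", {
  seq <- simulate_squat(squat_preset("noisy", seed = 9))
  seq2 <- seq
  seq2$x <- seq$x * 2.5 + 7
  seq2$y <- seq$y * 2.5 - 3
  a <- score_set(derive_series(seq))
  b <- score_set(derive_series(seq2))
  expect_equal(a$rounds, b$rounds)
})

test_that("a motionless set scores 0 with degenerate rhythm throughout", {
  s <- derive_series(standing_sequence(duration = 60))
  sc <- score_set(s)
  expect_equal(sc$sum_index2, 0L)
  expect_equal(sc$sum_index3, 0L)
  fr <- vapply(sc$round_scores, function(r)
    r$diagnostics$in_band_fraction %||% NA_real_, numeric(1))
  expect_true(all(is.na(fr)))
})
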