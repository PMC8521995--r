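test_that("age groups follow the published boundaries", {
  expect_equal(as.character(assign_age_group(c(25, 39, 40, 59, 60, 87, 16))),
               c("younger", "younger", "middle", "middle", "older", "older",
                 "younger"))
  expect_error(assign_age_group(-1), "age")
})

test_that("monthly minutes are midpoint products, monotone in both axes", {
  expect_equal(monthly_minutes("1-2 times/month", "less than 5 min"), 7.5)
  expect_equal(monthly_minutes("over 5 times/week", "over 60 min"), 1200)
  expect_error(monthly_minutes("daily", "over 60 min"), "unknown category")
  cats <- survey_categories()
  freqs <- cats$freq_category       # decreasing activity order
  durs <- cats$duration_category
  m <- outer(freqs, durs, Vectorize(function(f, d) monthly_minutes(f, d)))
  expect_true(all(apply(m, 2, diff) <= 0))   # less frequent -> fewer minutes
  expect_true(all(apply(m, 1, diff) <= 0))   # shorter -> fewer minutes
})

test_that("the 240 min/month habit rule dichotomizes with 240 as regular", {
  expect_equal(as.character(classify_habit(c(239, 240, 1200, 0))),
               c("insufficient", "regular", "regular", "insufficient"))
})

test_that("habit can be derived end-to-end from the categorical answers", {
  rec <- data.frame(
    age = c(30, 70),
    gender = c("men", "women"),
    exercise_change = c("increased", "decreased"),
    freq_category = c("over 5 times/week", "1-2 times/month"),
    duration_category = c("30-50 min", "less than 5 min"),
    stringsAsFactors = FALSE)
  s <- summarize_cohort(rec)
  expect_equal(summary_pct(s, "younger", "habit", "regular"), 100)
  expect_equal(summary_pct(s, "older", "habit", "insufficient"), 100)
})

test_that("re-summarizing the published cohort counts reproduces its percentages", {
  s <- summarize_cohort(table1_records())
  expect_equal(unname(s$n), c(105L, 58L, 37L, 200L))
  expect_equal(summary_pct(s, "all", "gender", "men"), 51.5)
  expect_equal(summary_pct(s, "all", "gender", "women"), 48.5)
  expect_equal(summary_pct(s, "all", "exercise_change", "decreased"), 38.0)
  expect_equal(summary_pct(s, "older", "habit", "regular"), 67.6)
  expect_equal(summary_pct(s, "older", "habit", "insufficient"), 32.4)
  expect_equal(summary_pct(s, "younger", "gender", "men"), 58.1)
  expect_equal(summary_pct(s, "middle", "gender", "women"), 62.1)
  expect_equal(summary_pct(s, "middle", "habit", "regular"), 41.4)
  expect_equal(summary_pct(s, "younger", "habit", "regular"), 50.5)
  expect_equal(summary_pct(s, "middle", "exercise_change", "increased"), 24.1)
  expect_equal(summary_pct(s, "all", "exercise_change", "increased"), 21.0)
})

test_that("within-group percentages sum to 100 up to rounding", {
  s <- summarize_cohort(table1_records())
  tab <- s$table
  for (g in unique(tab$group)) {
    for (v in unique(tab$variable)) {
      tot <- sum(tab$pct[tab$group == g & tab$variable == v])
      expect_lt(abs(tot - 100), 0.2)
    }
  }
})

test_that("a single record is 100% of its own categories", {
  rec <- table1_records()[1, ]
  s <- summarize_cohort(rec)
  expect_equal(summary_pct(s, "all", "gender", "men"), 100)
  expect_equal(summary_pct(s, "all", "gender", "women"), 0)
})

test_that("survey CSV validation names the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,gender,exercise_change,freq_category,duration_category",
               "30,men,increased,1-2 times/week,30-50 min",
               "40,men,sometimes,1-2 times/week,30-50 min"), path)
  expect_error(read_survey_csv(path), "line 3")
  writeLines("age,gender,exercise_change,freq_category,duration_category",
             path)
  expect_error(read_survey_csv(path), "no records")
  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,gender,exercise_change,freq_category,duration_category",
               "30,men,increased,1-2 times/week,30-50 min"), ok)
  expect_equal(as.character(read_survey_csv(ok)$age_group), "younger")
})
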