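#' Closed category sets for the exercise survey
#'
#' The self-reported web survey records gender, the change in exercise due
#' to the COVID-19 pandemic, and an exercise report (weekly frequency and
#' per-session duration) as closed categorical answers.
#'
#' @return Named list of character vectors (`gender`, `exercise_change`,
#'   `freq_category`, `duration_category`).
#' @export
survey_categories <- function() {
  list(gender = c("men", "women"),
       exercise_change = c("increased", "not_changed", "decreased"),
       freq_category = c("over 5 times/week", "3-4 times/week",
                         "1-2 times/week", "1-2 times/month"),
       duration_category = c("over 60 min", "30-50 min", "10-20 min",
                             "less than 5 min"))
}

#' Assign a respondent to an age group
#'
#' Younger (<= 39 years), middle (40-59), older (>= 60). The boundaries
#' follow the study's printed group ranges: 39 is still "younger", 40
#' opens "middle", 60 opens "older".
#'
#' @param age Numeric vector of ages in years (>= 0).
#' @return Factor with levels `younger`, `middle`, `older`.
#' @export
assign_age_group <- function(age) {
  if (any(!is.finite(age)) || any(age < 0))
    stop("age must be a non-negative number", call. = FALSE)
  cut(age, breaks = c(-Inf, 39, 59, Inf),
      labels = c("younger", "middle", "older"))
}

#' Convert categorical exercise answers to minutes per month
#'
#' The survey reports frequency and duration as categories; monthly
#' physical activity is the product of their midpoints:
#' sessions/month — over 5 times/week: 20, 3-4 times/week: 14,
#' 1-2 times/week: 6, 1-2 times/month: 1.5; minutes/session —
#' over 60 min: 60, 30-50 min: 40, 10-20 min: 15, less than 5 min: 5.
#' The mapping is configurable and monotone in both arguments.
#'
#' @param freq Character vector of frequency categories.
#' @param dur Character vector of duration categories.
#' @param sessions_per_month Named numeric mapping for frequencies.
#' @param minutes_per_session Named numeric mapping for durations.
#' @return Numeric vector, minutes of activity per month.
#' @export
monthly_minutes <- function(freq, dur,
                            sessions_per_month = c(
                              "over 5 times/week" = 20,
                              "3-4 times/week" = 14,
                              "1-2 times/week" = 6,
                              "1-2 times/month" = 1.5),
                            minutes_per_session = c(
                              "over 60 min" = 60,
                              "30-50 min" = 40,
                              "10-20 min" = 15,
                              "less than 5 min" = 5)) {
  bad_f <- setdiff(unique(freq), names(sessions_per_month))
  bad_d <- setdiff(unique(dur), names(minutes_per_session))
  if (length(bad_f) || length(bad_d))
    stop(sprintf("unknown category: %s",
                 paste(c(bad_f, bad_d), collapse = ", ")), call. = FALSE)
  unname(sessions_per_month[freq] * minutes_per_session[dur])
}

#' Classify exercise habit from monthly activity minutes
#'
#' A physical activity of 240 min per month is the recommended threshold:
#' below it the habit is `insufficient`, at or above it `regular` (the
#' boundary value 240 is assigned to `regular` so the dichotomy is
#' exhaustive).
#'
#' @param minutes Numeric vector, minutes/month (>= 0).
#' @return Factor with levels `insufficient`, `regular`.
#' @export
classify_habit <- function(minutes) {
  stopifnot(all(minutes >= 0))
  factor(ifelse(minutes >= 240, "regular", "insufficient"),
         levels = c("insufficient", "regular"))
}

# Percentage rounded half-up to one decimal (commercial rounding, matching
# how survey tables are typically printed; R's round() is banker's).
.pct1 <- function(n, total) floor(n / total * 1000 + 0.5) / 10

#' Read survey records from CSV
#'
#' Expects header `age,gender,exercise_change,freq_category,
#' duration_category`. Category values are validated against
#' [survey_categories()]; violations are reported with their line numbers.
#'
#' @param con File path or connection.
#' @return Data frame of validated records with an added `age_group`
#'   column.
#' @export
read_survey_csv <- function(con) {
  df <- utils::read.csv(con, stringsAsFactors = FALSE)
  need <- c("age", "gender", "exercise_change", "freq_category",
            "duration_category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("survey CSV missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!nrow(df)) stop("survey CSV has no records", call. = FALSE)
  cats <- survey_categories()
  for (col in names(cats)) {
    bad <- which(!df[[col]] %in% cats[[col]])
    if (length(bad))
      stop(sprintf("line %d: unknown %s '%s'", bad[1] + 1L, col,
                   df[[col]][bad[1]]), call. = FALSE)
  }
  bad_age <- which(!is.finite(df$age) | df$age < 0)
  if (length(bad_age))
    stop(sprintf("line %d: invalid age", bad_age[1] + 1L), call. = FALSE)
  df$age_group <- assign_age_group(df$age)
  df
}

#' Summarize a survey cohort by age group
#'
#' Reproduces the descriptive table structure of the study: per age group
#' (and over all respondents), counts and within-group percentages by
#' gender, exercise change, and exercise habit, plus the age mean, SD and
#' range. Percentages are rounded half-up to one decimal; within a group
#' each category's percentages sum to 100 up to rounding.
#'
#' Habit is taken from a `habit` column when present; otherwise it is
#' derived from the frequency/duration categories via [monthly_minutes()]
#' and [classify_habit()].
#'
#' @param records Data frame of survey records (see [read_survey_csv()]).
#' @return A `cohort_summary`: list with `n` (named group sizes), `age`
#'   (per-group mean/sd/min/max), and a long data frame `table`
#'   (`group`, `variable`, `category`, `n`, `pct`).
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) stop("no survey records", call. = FALSE)
  df <- records
  if (is.null(df$age_group)) df$age_group <- assign_age_group(df$age)
  if (is.null(df$habit))
    df$habit <- classify_habit(
      monthly_minutes(df$freq_category, df$duration_category))
  df$habit <- factor(df$habit, levels = c("insufficient", "regular"))
  cats <- survey_categories()
  df$gender <- factor(df$gender, levels = cats$gender)
  df$exercise_change <- factor(df$exercise_change,
                               levels = cats$exercise_change)
  groups <- c(levels(df$age_group), "all")
  rows <- list()
  for (g in groups) {
    sub <- if (g == "all") df else df[df$age_group == g, , drop = FALSE]
    ng <- nrow(sub)
    for (var in c("gender", "exercise_change", "habit")) {
      tab <- table(sub[[var]])
      for (lev in names(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = var, category = lev,
          n = as.integer(tab[[lev]]),
          pct = if (ng > 0) .pct1(tab[[lev]], ng) else NA_real_)
      }
    }
  }
  n_by_group <- c(table(df$age_group), all = nrow(df))
  age_stats <- do.call(rbind, lapply(groups, function(g) {
    sub <- if (g == "all") df else df[df$age_group == g, , drop = FALSE]
    data.frame(group = g, n = nrow(sub),
               mean = if (nrow(sub)) mean(sub$age) else NA_real_,
               sd = if (nrow(sub) > 1) stats::sd(sub$age) else NA_real_,
               min = if (nrow(sub)) min(sub$age) else NA_real_,
               max = if (nrow(sub)) max(sub$age) else NA_real_)
  }))
  structure(list(n = n_by_group, age = age_stats,
                 table = do.call(rbind, rows)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n  group sizes: ",
      paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", "), "\n",
      sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
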