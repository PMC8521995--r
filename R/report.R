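#' Write a score report as JSON
#'
#' The report carries the per-round index breakdown with diagnostics, the
#' per-index sums and grand total, and the audio volume envelope, matching
#' the schema shipped in `inst/extdata/schemas/score_report.schema.json`.
#'
#' @param set_score A `set_score` from [score_set()].
#' @param path Output file path or connection.
#' @param envelope Optional precomputed [volume_envelope()]; computed from
#'   `set_score` when `NULL`.
#' @return Invisibly, the report list.
#' @export
write_score_report <- function(set_score, path, envelope = NULL) {
  stopifnot(inherits(set_score, "set_score"))
  if (is.null(envelope)) envelope <- volume_envelope(set_score)
  rounds <- lapply(set_score$round_scores, function(rs) {
    list(round = rs$round_index,
         index1 = rs$index1, index2 = rs$index2, index3 = rs$index3,
         total = rs$total, empty = rs$empty,
         diagnostics = lapply(rs$diagnostics, function(v)
           if (length(v) == 1 && is.na(v)) NULL else v))
  })
  report <- list(
    set = list(n_rounds = set_score$config$n_rounds,
               round_duration = set_score$config$round_duration,
               sum_index1 = set_score$sum_index1,
               sum_index2 = set_score$sum_index2,
               sum_index3 = set_score$sum_index3,
               grand_total = set_score$grand_total),
    rounds = rounds,
    volume_envelope = lapply(seq_len(nrow(envelope)), function(i)
      list(round = envelope$round_index[i],
           bgm_pct = envelope$bgm_pct[i],
           noise_pct = envelope$noise_pct[i])))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}

#' Validate a score report against the shipped structural schema
#'
#' Structural validation of the JSON score report: required fields,
#' score bounds (indices in 0-3/0-3/0-4, totals consistent), and the
#' volume conservation `bgm + noise = 100` per round.
#'
#' @param path Path to a score-report JSON file.
#' @return `TRUE` invisibly on success; otherwise an error describing the
#'   first violation.
#' @export
validate_score_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fail <- function(msg) stop(sprintf("invalid score report: %s", msg),
                             call. = FALSE)
  if (is.null(rep$set) || is.null(rep$rounds)) fail("missing set/rounds")
  tot <- 0L
  for (r in rep$rounds) {
    for (f in c("round", "index1", "index2", "index3", "total"))
      if (is.null(r[[f]])) fail(sprintf("round missing '%s'", f))
    if (r$index1 < 0 || r$index1 > 3 || r$index2 < 0 || r$index2 > 3 ||
        r$index3 < 0 || r$index3 > 4)
      fail("index out of bounds")
    if (r$total != r$index1 + r$index2 + r$index3)
      fail("round total != sum of indices")
    tot <- tot + r$total
  }
  if (!is.null(rep$set$grand_total) && rep$set$grand_total != tot)
    fail("grand_total != sum of round totals")
  for (v in rep$volume_envelope) {
    if (abs(v$bgm_pct + v$noise_pct - 100) > 1e-9)
      fail("volume envelope not conserved")
  }
  invisible(TRUE)
}

#' Write a volume envelope as CSV
#'
#' @param envelope A [volume_envelope()] data frame.
#' @param path Output file path or connection.
#' @return Invisibly, `path`.
#' @export
write_envelope_csv <- function(envelope, path) {
  utils::write.csv(envelope[, c("round_index", "bgm_pct", "noise_pct")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort summary as CSV and/or JSON
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the summary.
#' @export
write_cohort_summary <- function(summary, csv_path = NULL,
                                 json_path = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (!is.null(csv_path))
    utils::write.csv(summary$table, csv_path, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(n = as.list(summary$n),
           age = summary$age,
           table = summary$table),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(summary)
}

#' Score a pose recording end to end
#'
#' Convenience wrapper chaining [derive_series()], optional
#' [detect_start()], and [score_set()].
#'
#' @param seq A [pose_sequence()].
#' @param cleaning A [cleaning_config()].
#' @param set_cfg A [set_config()].
#' @param t0 Set start time in seconds, or `"auto"` to detect it from the
#'   first descent.
#' @param band_halfwidth Rhythm band half-width; default 0.3.
#' @return A `set_score`.
#' @export
score_pose_sequence <- function(seq, cleaning = cleaning_config(),
                                set_cfg = set_config(), t0 = 0,
                                band_halfwidth = 0.3) {
  series <- derive_series(seq, cleaning)
  if (identical(t0, "auto"))
    t0 <- detect_start(series, round_duration = set_cfg$round_duration)
  score_set(series, set_cfg, t0, band_halfwidth)
}
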