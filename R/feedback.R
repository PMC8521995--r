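#' Map set scores to the audio-feedback volume envelope
#'
#' During playback the background music (BGM) and a masking audio noise are
#' mixed per round, with volumes driven by the round's squat score: better
#' rounds get clearer music. The mapping is linear in the round total over
#' its 0..10 range — `bgm = total / 10 x 100%`, `noise = 100 - bgm` — so a
#' round scoring 8 of 10 plays BGM at 80% of maximum and noise at 20%.
#'
#' @param set_score A `set_score` from [score_set()].
#' @return A data frame with one row per round: `round_index`, `total`,
#'   `bgm_pct`, `noise_pct` (percent of maximum volume; the two always sum
#'   to 100).
#' @export
volume_envelope <- function(set_score) {
  stopifnot(inherits(set_score, "set_score"))
  r <- set_score$rounds
  bgm <- r$total / 10 * 100
  data.frame(round_index = r$round_index,
             total = r$total,
             bgm_pct = bgm,
             noise_pct = 100 - bgm)
}
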