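#' Score self-reported musculoskeletal discomfort
#'
#' Converts a per-region pain report — a frequency rank (1 = 1–2 times/week,
#' 2 = 3–4 times/week, 3 = once daily, 4 = several times daily) and a
#' severity rank (0 = no pain, 1 = mild, 2 = moderate, 3 = severe, 4 = very
#' severe) — into a 0–16 discomfort score (the product of the two ranks) and
#' its 5-level classification.
#'
#' When `severity == 0` the worker reported no pain, so the score is 0
#' regardless of `frequency`, and `frequency` may be `NA` (questionnaires
#' routinely leave the frequency blank on "no pain" rows).
#'
#' @param frequency Integer vector of frequency ranks in 1–4; `NA` permitted
#'   only where `severity` is 0.
#' @param severity Integer vector of severity ranks in 0–4.
#' @return A data frame with integer columns `score` (0–16) and `level`
#'   (0–4, see [bin_discomfort()]).
#' @examples
#' score_discomfort(frequency = 4, severity = 4)          # score 16, level 4
#' score_discomfort(frequency = c(3, 2), severity = c(0, 2))
#' @seealso [bin_discomfort()]
#' @export
score_discomfort <- function(frequency, severity) {
  n <- max(length(frequency), length(severity))
  frequency <- rep_len(as.vector(frequency), n)
  severity <- rep_len(as.vector(severity), n)
  severity <- check_rank(severity, "severity", 0, 4)
  check_rank(frequency[severity > 0], "frequency", 1, 4)
  check_rank(frequency, "frequency", 1, 4, allow_na = TRUE)
  score <- ifelse(severity == 0L, 0L,
                  as.integer(frequency) * severity)
  data.frame(score = as.integer(score), level = bin_discomfort(score))
}

#' Bin a discomfort score into the 5-level classification
#'
#' Maps the 0–16 discomfort score onto levels 0 (no discomfort, score 0),
#' 1 (mild, 1–2), 2 (moderate, 3–4), 3 (severe, 5–8) and 4 (very severe,
#' 9–16).
#'
#' @param score Integer vector of discomfort scores in 0–16.
#' @return Integer vector of levels 0–4.
#' @examples
#' bin_discomfort(c(0, 2, 4, 8, 9))
#' @export
bin_discomfort <- function(score) {
  score <- check_rank(score, "score", 0, 16)
  as.integer(findInterval(score, c(1L, 3L, 5L, 9L)))
}
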