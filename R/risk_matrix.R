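# The combined health-risk-assessment (HRA) matrix: self-reported
# discomfort level (rows, 0-4, the "likelihood" axis) crossed with the RULA
# ergonomics-risk level (columns, 1-4, the "severity of exposure" axis).

#' Combine discomfort and RULA levels into an MSD health risk
#'
#' The matrix score is the product `discomfort_level * rula_level`. The
#' zero-discomfort row has a footnoted exception: a worker reporting no
#' discomfort whose posture is nonetheless rated high (RULA level 3) or very
#' high (level 4) is flagged at low rather than acceptable risk (scores 1
#' and 2 respectively), so that high observed exposure is never completely
#' masked by the absence of symptoms. `override = FALSE` disables the
#' exception and uses the plain product everywhere; prevalence at moderate
#' risk or above is identical under both settings, since the override only
#' moves workers between the acceptable and low bands.
#'
#' @param discomfort_level Integer vector in 0–4 (see [bin_discomfort()]).
#' @param rula_level Integer vector in 1–4 (see [bin_rula()]).
#' @param override Apply the zero-discomfort exception (default `TRUE`).
#' @return A data frame with integer columns `matrix_score` (0–16) and
#'   `hra_level` (0–4; 0 acceptable, 1 low, 2 moderate, 3 high, 4 very
#'   high).
#' @examples
#' combine_risk(3, 4)                      # score 12, very high
#' combine_risk(0, 4)                      # score 2, low (override)
#' combine_risk(0, 4, override = FALSE)    # score 0, acceptable
#' @export
combine_risk <- function(discomfort_level, rula_level, override = TRUE) {
  n <- max(length(discomfort_level), length(rula_level))
  d <- check_rank(rep_len(discomfort_level, n), "discomfort_level", 0, 4)
  r <- check_rank(rep_len(rula_level, n), "rula_level", 1, 4)
  score <- d * r
  if (override) {
    score[d == 0L & r == 3L] <- 1L
    score[d == 0L & r == 4L] <- 2L
  }
  data.frame(matrix_score = score, hra_level = bin_hra(score))
}

#' Bin a matrix score into the 5-level health-risk classification
#'
#' Score 0 is level 0 (acceptable), 1–2 level 1 (low), 3–4 level 2
#' (moderate), 5–8 level 3 (high) and 9–16 level 4 (very high). The
#' published bands skip from "3–4" to "6–8"; a score of 5 cannot arise as a
#' product of the level ranges, but for totality it is assigned to level 3,
#' the band containing its neighbours 4(+) and 6.
#'
#' @param matrix_score Integer vector in 0–16.
#' @return Integer HRA level in 0–4.
#' @examples
#' bin_hra(c(0, 2, 4, 6, 16))
#' @export
bin_hra <- function(matrix_score) {
  s <- check_rank(matrix_score, "matrix_score", 0, 16)
  as.integer(findInterval(s, c(1L, 3L, 5L, 9L)))
}

#' The full 5 x 4 health-risk matrix
#'
#' Enumerates every (discomfort level, RULA level) combination and returns
#' the matrix of scores, with the per-cell risk-band labels available via
#' [bin_hra()]. Printing shows the grid with discomfort levels as rows
#' (highest first, as usually typeset) and a legend of the risk bands.
#'
#' @inheritParams combine_risk
#' @return An integer matrix with class `"hra_matrix"`, rows named by
#'   discomfort level 0–4 and columns by RULA level 1–4; attribute
#'   `"hra_level"` holds the matching matrix of HRA levels.
#' @examples
#' hra_matrix()
#' @export
hra_matrix <- function(override = TRUE) {
  grid <- expand.grid(discomfort = 0:4, rula = 1:4)
  res <- combine_risk(grid$discomfort, grid$rula, override = override)
  m <- matrix(res$matrix_score, nrow = 5, ncol = 4,
              dimnames = list(discomfort = 0:4, rula = 1:4))
  lv <- matrix(res$hra_level, nrow = 5, ncol = 4,
               dimnames = dimnames(m))
  structure(m, hra_level = lv, override = override, class = "hra_matrix")
}

#' @export
print.hra_matrix <- function(x, ...) {
  cat("MSD health-risk matrix (discomfort level x RULA ergonomics-risk level)\n")
  m <- unclass(x)[5:1, , drop = FALSE]
  attr(m, "hra_level") <- NULL
  attr(m, "override") <- NULL
  print(m)
  cat(if (isTRUE(attr(x, "override")))
        "zero-discomfort override ON: no discomfort + RULA 3/4 -> low risk\n"
      else "zero-discomfort override OFF: plain product everywhere\n")
  cat("risk bands:\n")
  for (l in 0:4)
    cat(sprintf("  level %d (%s): %s\n", l, hra_level_labels[as.character(l)],
                hra_level_actions[as.character(l)]))
  invisible(x)
}
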