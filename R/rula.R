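# RULA (Rapid Upper Limb Assessment) engine.
#
# The three scoring tables of the published RULA worksheet (McAtamney &
# Corlett's method) are shipped as long-format CSV fixtures under extdata,
# transcribed cell by cell, so the transcription can be audited and is
# guarded by dimension/range/monotonicity/checksum tests rather than being
# buried in code. Adjustment modifiers (shoulder raised, arm abducted, wrist
# deviation, ...) are the observer's responsibility: posture codes arrive
# already adjusted.

.rula_cache <- new.env(parent = emptyenv())

#' RULA scoring tables
#'
#' Returns the three RULA lookup tables as dense arrays: Table A
#' (`6 x 3 x 4 x 2`, indexed by upper-arm, lower-arm, wrist and wrist-twist
#' codes), Table B (`6 x 6 x 2`, neck, trunk, legs) and Table C (`8 x 8`,
#' arm/wrist score C by neck/trunk/leg score D; the published column "7+" is
#' carried as columns 7 and 8). Parsed once per session from the versioned
#' CSV fixtures installed with the package.
#'
#' @return A list with elements `A`, `B` and `C`.
#' @examples
#' rula_tables()$C[1, 1]
#' @export
rula_tables <- function() {
  if (!is.null(.rula_cache$tables)) return(.rula_cache$tables)
  path <- function(f) system.file("extdata", f, package = "msdrisk",
                                  mustWork = TRUE)
  ta <- utils::read.csv(path("rula_table_a.csv"))
  tb <- utils::read.csv(path("rula_table_b.csv"))
  tc <- utils::read.csv(path("rula_table_c.csv"))
  A <- array(NA_integer_, dim = c(6, 3, 4, 2))
  A[cbind(ta$upper_arm, ta$lower_arm, ta$wrist, ta$wrist_twist)] <- ta$score
  B <- array(NA_integer_, dim = c(6, 6, 2))
  B[cbind(tb$neck, tb$trunk, tb$legs)] <- tb$score
  C <- matrix(NA_integer_, 8, 8)
  C[cbind(tc$score_c, tc$score_d)] <- tc$grand_score
  stopifnot(!anyNA(A), !anyNA(B), !anyNA(C))
  .rula_cache$tables <- list(A = A, B = B, C = C)
  .rula_cache$tables
}

#' RULA Table A: upper-limb posture score
#'
#' @param upper_arm,lower_arm,wrist,wrist_twist Integer posture codes in
#'   1–6, 1–3, 1–4 and 1–2 respectively (vectorised, recycled).
#' @return Integer posture score A in 1–9.
#' @examples
#' rula_score_a(1, 1, 1, 1)  # 1
#' rula_score_a(6, 3, 4, 2)  # 9
#' @export
rula_score_a <- function(upper_arm, lower_arm, wrist, wrist_twist) {
  n <- max(length(upper_arm), length(lower_arm), length(wrist),
           length(wrist_twist))
  ua <- check_rank(rep_len(upper_arm, n), "upper_arm", 1, 6)
  la <- check_rank(rep_len(lower_arm, n), "lower_arm", 1, 3)
  w <- check_rank(rep_len(wrist, n), "wrist", 1, 4)
  wt <- check_rank(rep_len(wrist_twist, n), "wrist_twist", 1, 2)
  rula_tables()$A[cbind(ua, la, w, wt)]
}

#' RULA Table B: neck/trunk/leg posture score
#'
#' @param neck,trunk Integer posture codes in 1–6.
#' @param legs Integer posture code in 1–2.
#' @return Integer posture score B in 1–9.
#' @examples
#' rula_score_b(1, 1, 1)  # 1
#' rula_score_b(6, 6, 2)  # 9
#' @export
rula_score_b <- function(neck, trunk, legs) {
  n <- max(length(neck), length(trunk), length(legs))
  nk <- check_rank(rep_len(neck, n), "neck", 1, 6)
  tr <- check_rank(rep_len(trunk, n), "trunk", 1, 6)
  lg <- check_rank(rep_len(legs, n), "legs", 1, 2)
  rula_tables()$B[cbind(nk, tr, lg)]
}

#' RULA Table C: grand score
#'
#' Combines score C (posture A plus muscle-use and force increments) and
#' score D (posture B plus increments) into the 1–7 grand score. Values of
#' 8 or more are capped at 8 before the lookup, as on the published
#' worksheet.
#'
#' @param score_c,score_d Positive integers.
#' @return Integer grand score in 1–7.
#' @examples
#' rula_grand_score(1, 1)    # 1
#' rula_grand_score(12, 9)   # 7, same as (8, 8)
#' @export
rula_grand_score <- function(score_c, score_d) {
  n <- max(length(score_c), length(score_d))
  sc <- check_rank(rep_len(score_c, n), "score_c", 1, .Machine$integer.max)
  sd_ <- check_rank(rep_len(score_d, n), "score_d", 1, .Machine$integer.max)
  rula_tables()$C[cbind(pmin(sc, 8L), pmin(sd_, 8L))]
}

#' Bin a RULA grand score into an ergonomics-risk level
#'
#' Two binning schemes are provided. `"action_levels"` (default) is the
#' standard RULA action-level mapping: grand score 1–2 is level 1
#' (acceptable), 3–4 level 2 (investigate further), 5–6 level 3 (investigate
#' and change soon), 7 level 4 (investigate and change immediately); this is
#' the only mapping that can produce level-4 outcomes at all, since the
#' grand score never exceeds 7. `"survey_bins"` is an alternative seen in
#' survey instruments that reuse the discomfort-score bands (1–2, 3–4, 5–8,
#' 9–16); under it level 4 is unreachable and grand scores 5–7 all map to
#' level 3. It is provided for fidelity to instruments printed that way.
#'
#' @param grand_score Integer vector in 1–7.
#' @param scheme `"action_levels"` or `"survey_bins"`.
#' @return Integer ergonomics-risk level in 1–4.
#' @examples
#' bin_rula(1:7)
#' bin_rula(7, scheme = "survey_bins")  # 3
#' @export
bin_rula <- function(grand_score, scheme = c("action_levels", "survey_bins")) {
  scheme <- match.arg(scheme)
  g <- check_rank(grand_score, "grand_score", 1, 7)
  breaks <- if (scheme == "action_levels") c(1L, 3L, 5L, 7L)
            else c(1L, 3L, 5L, 9L)
  as.integer(findInterval(g, breaks))
}

#' Assess RULA from posture codes
#'
#' Runs the full worksheet: Table A on the arm/wrist codes and Table B on
#' the neck/trunk/leg codes, adds the muscle-use (0/1, static or repeated)
#' and force/load (0–3) increments of each group to form scores C and D,
#' looks up the grand score in Table C, and bins it to the 4-level
#' ergonomics-risk level.
#'
#' @param postures A data frame (one row per assessment) with integer
#'   columns `upper_arm` (1–6), `lower_arm` (1–3), `wrist` (1–4),
#'   `wrist_twist` (1–2), `neck` (1–6), `trunk` (1–6), `legs` (1–2),
#'   `muscle_use_a`, `muscle_use_b` (0/1) and `force_a`, `force_b` (0–3).
#'   A named list works for a single assessment.
#' @param scheme Binning scheme passed to [bin_rula()].
#' @return A data frame with columns `posture_a`, `posture_b`, `score_c`,
#'   `score_d`, `grand_score` and `level`; the scheme is kept in attribute
#'   `"scheme"`.
#' @examples
#' assess_rula(data.frame(
#'   upper_arm = 3, lower_arm = 2, wrist = 2, wrist_twist = 1,
#'   neck = 2, trunk = 2, legs = 1,
#'   muscle_use_a = 1, force_a = 0, muscle_use_b = 1, force_b = 1))
#' @export
assess_rula <- function(postures, scheme = c("action_levels", "survey_bins")) {
  scheme <- match.arg(scheme)
  postures <- as.data.frame(postures)
  need <- rula_posture_columns
  missing <- setdiff(need, names(postures))
  if (length(missing))
    stop("missing posture columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pa <- rula_score_a(postures$upper_arm, postures$lower_arm,
                     postures$wrist, postures$wrist_twist)
  pb <- rula_score_b(postures$neck, postures$trunk, postures$legs)
  ma <- check_rank(postures$muscle_use_a, "muscle_use_a", 0, 1)
  mb <- check_rank(postures$muscle_use_b, "muscle_use_b", 0, 1)
  fa <- check_rank(postures$force_a, "force_a", 0, 3)
  fb <- check_rank(postures$force_b, "force_b", 0, 3)
  sc <- pa + ma + fa
  sd_ <- pb + mb + fb
  g <- rula_grand_score(sc, sd_)
  out <- data.frame(posture_a = pa, posture_b = pb, score_c = sc,
                    score_d = sd_, grand_score = g,
                    level = bin_rula(g, scheme))
  attr(out, "scheme") <- scheme
  out
}

#' @rdname assess_rula
#' @format `rula_posture_columns` is the character vector of the 11 posture
#'   input columns, in canonical order.
#' @export
rula_posture_columns <- c(
  "upper_arm", "lower_arm", "wrist", "wrist_twist", "neck", "trunk", "legs",
  "muscle_use_a", "force_a", "muscle_use_b", "force_b"
)
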