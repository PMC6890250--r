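# Builders for small deterministic cohorts used across the tests.

# all-quiet cohort: every region severity 0, frequency blank
blank_cohort <- function(n, rula_level = 1L) {
  df <- data.frame(worker_id = sprintf("T%04d", seq_len(n)),
                   department = rep("packing", n),
                   rula_level = as.integer(rep_len(rula_level, n)))
  for (reg in body_regions) {
    df[[paste0(reg, "_freq")]] <- rep(NA_integer_, n)
    df[[paste0(reg, "_sev")]] <- rep(0L, n)
  }
  df
}

# frequency rank that makes the discomfort level equal the severity rank
# (f*s falls in the severity's own band): s=1 -> f1 (score 1), s=2 -> f2
# (4), s=3 -> f2 (6), s=4 -> f3 (12)
freq_realizing_level <- c(`1` = 1L, `2` = 2L, `3` = 2L, `4` = 3L)

set_region_levels <- function(cohort, region, levels) {
  sev <- as.integer(levels)
  freq <- ifelse(sev == 0L, NA_integer_,
                 freq_realizing_level[as.character(sev)])
  cohort[[paste0(region, "_sev")]] <- sev
  cohort[[paste0(region, "_freq")]] <- as.integer(freq)
  cohort
}

# cohort whose RULA-level counts are exactly `counts` (levels 1..4)
cohort_from_rula_counts <- function(counts) {
  blank_cohort(sum(counts), rula_level = rep(1:4, counts))
}

# cohort whose discomfort-level counts for `region` are exactly `counts`
cohort_from_discomfort_counts <- function(region, counts) {
  set_region_levels(blank_cohort(sum(counts)), region, rep(0:4, counts))
}

# cohort whose HRA-level counts for `region` are exactly `counts`, using
# override-invariant (discomfort level, RULA level) combos per target level
cohort_from_hra_counts <- function(region, counts) {
  combo <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 3L),
                `3` = c(2L, 3L), `4` = c(3L, 4L))
  target <- rep(0:4, counts)
  d <- vapply(combo[as.character(target)], `[`, integer(1), 1)
  r <- vapply(combo[as.character(target)], `[`, integer(1), 2)
  set_region_levels(blank_cohort(sum(counts), rula_level = r), region, d)
}

# a batch of valid random posture-code rows
random_postures <- function(n, seed) {
  with_fixed_seed(seed, data.frame(
    upper_arm = sample(1:6, n, TRUE), lower_arm = sample(1:3, n, TRUE),
    wrist = sample(1:4, n, TRUE), wrist_twist = sample(1:2, n, TRUE),
    neck = sample(1:6, n, TRUE), trunk = sample(1:6, n, TRUE),
    legs = sample(1:2, n, TRUE),
    muscle_use_a = sample(0:1, n, TRUE), force_a = sample(0:3, n, TRUE),
    muscle_use_b = sample(0:1, n, TRUE), force_b = sample(0:3, n, TRUE)))
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# random simplex point
rsimplex <- function(k) { x <- stats::rexp(k); x / sum(x) }

# counts per level from a classified long table, for one region
hra_counts <- function(classified, region) {
  as.integer(table(factor(
    classified$hra_level[classified$region == region], levels = 0:4)))
}
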