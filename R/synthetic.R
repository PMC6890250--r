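# Synthetic cohorts with the categorical structure of a repetitive-work
# food-processing workforce: per-worker department, a whole-body RULA
# ergonomics-risk level, and per-region pain frequency/severity ranks.
# Only the marginal distributions are controlled; the discomfort-RULA joint
# is steered by a single Gaussian-copula association parameter, because the
# joint distribution of real screening data of this kind is typically not
# published.

#' Specify a synthetic cohort
#'
#' Collects everything that determines a generated cohort: the size, the
#' department mix, the RULA-level marginal, per-region severity (5
#' categories, 0–4) and frequency (4 categories, 1–4) marginals, a
#' severity–RULA association in \[-1, 1\] (a Gaussian-copula correlation
#' between each region's latent severity draw and the latent RULA draw;
#' 0 = independence), and the RNG seed. All probability vectors must be
#' simplex points (non-negative, summing to 1 within 1e-9).
#'
#' `default_cohort_spec()` is the spec of the reference workforce the
#' package emulates: 107 workers across four departments (cool room 17,
#' process 11, packing 71, warehouse 8), RULA levels 1–4 with counts
#' (0, 3, 21, 83)/107, and per-region severity marginals matching the
#' observed discomfort tables (e.g. trunk (59, 36, 9, 2, 1)/107).
#' Frequency marginals are uniform over 1–4 — frequency conditional on pain
#' is rarely published, and severity dominates the level binning — and the
#' association defaults to 0 (independence).
#'
#' @param n Number of workers.
#' @param department_probs Length-4 simplex named by [departments].
#' @param rula_level_probs Length-4 simplex over RULA levels 1–4.
#' @param severity_probs Named list, one length-5 simplex per body region
#'   (severity 0–4).
#' @param frequency_probs Named list, one length-4 simplex per body region
#'   (frequency 1–4).
#' @param association Real in \[-1, 1\].
#' @param seed Integer RNG seed; fully determines the cohort.
#' @return An object of class `"cohort_spec"`.
#' @examples
#' spec <- default_cohort_spec(seed = 1)
#' spec$rula_level_probs
#' @export
cohort_spec <- function(n, department_probs, rula_level_probs, severity_probs,
                        frequency_probs, association = 0, seed = 1L) {
  if (length(n) != 1 || is.na(n) || n < 0 || n != floor(n))
    stop("n must be a single non-negative integer", call. = FALSE)
  check_simplex(department_probs, "department_probs", 4)
  check_simplex(rula_level_probs, "rula_level_probs", 4)
  stopifnot(setequal(names(severity_probs), body_regions),
            setequal(names(frequency_probs), body_regions))
  for (reg in body_regions) {
    check_simplex(severity_probs[[reg]], paste0("severity_probs$", reg), 5)
    check_simplex(frequency_probs[[reg]], paste0("frequency_probs$", reg), 4)
  }
  if (length(association) != 1 || is.na(association) ||
      abs(association) > 1)
    stop("association must be a single value in [-1, 1]", call. = FALSE)
  structure(list(n = as.integer(n),
                 department_probs = stats::setNames(as.numeric(department_probs),
                                                    departments),
                 rula_level_probs = as.numeric(rula_level_probs),
                 severity_probs = lapply(severity_probs[body_regions],
                                         as.numeric),
                 frequency_probs = lapply(frequency_probs[body_regions],
                                          as.numeric),
                 association = as.numeric(association),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_spec <- function(n = 107, association = 0, seed = 1L) {
  sev <- list(
    neck        = c(85, 17, 3, 1, 1) / 107,
    upper_limbs = c(67, 31, 6, 2, 1) / 107,
    trunk       = c(59, 36, 9, 2, 1) / 107,
    lower_limbs = c(72, 25, 4, 4, 2) / 107
  )
  freq <- stats::setNames(rep(list(rep(0.25, 4)), 4), body_regions)
  cohort_spec(
    n = n,
    department_probs = c(cool_room = 17, process = 11, packing = 71,
                         warehouse = 8) / 107,
    rula_level_probs = c(0, 3, 21, 83) / 107,
    severity_probs = sev,
    frequency_probs = freq,
    association = association,
    seed = seed
  )
}

#' Generate a synthetic worker cohort
#'
#' Draws `spec$n` worker records. The latent-variable construction is a
#' one-factor Gaussian copula: one standard-normal draw per worker sets the
#' RULA level through the inverse CDF of `rula_level_probs`; each region's
#' severity uses a latent normal correlated with it at `spec$association`
#' (so `association = 0` gives exact independence and the sign of the
#' association is the sign of the induced rank correlation). Frequencies and
#' departments are independent categorical draws. Demographics (sex, age,
#' tenure) are generated from fixed distributions typical of the emulated
#' workforce (76% female; age uniform on 21–43; tenure 6 months plus a
#' gamma with overall mean 20.6 months) and only feed the descriptive
#' statistics. The seed fully determines the cohort and the caller's RNG
#' state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return A cohort data frame in the [read_cohort()] schema, with the RULA
#'   input supplied as a precomputed `rula_level` column.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(n = 10, seed = 3))
#' head(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  if (n == 0) {
    empty <- data.frame(worker_id = character(), department = character(),
                        sex = character(), age_years = integer(),
                        tenure_months = numeric(), rula_level = integer())
    for (reg in body_regions) {
      empty[[paste0(reg, "_freq")]] <- integer()
      empty[[paste0(reg, "_sev")]] <- integer()
    }
    return(empty[cohort_column_order(empty)])
  }
  a <- spec$association
  with_seed(spec$seed, {
    dept <- departments[cut_categorical(stats::runif(n),
                                        spec$department_probs, 1L)]
    z0 <- stats::rnorm(n)
    rula_level <- cut_categorical(stats::pnorm(z0), spec$rula_level_probs, 1L)
    out <- data.frame(
      worker_id = sprintf("W%04d", seq_len(n)),
      department = dept,
      sex = ifelse(stats::runif(n) < 0.7568, "female", "male"),
      age_years = as.integer(sample(21:43, n, replace = TRUE)),
      tenure_months = round(6 + stats::rgamma(n, shape = 2,
                                              scale = 14.59 / 2), 1),
      rula_level = rula_level
    )
    for (reg in body_regions) {
      z <- a * z0 + sqrt(1 - a^2) * stats::rnorm(n)
      out[[paste0(reg, "_sev")]] <-
        cut_categorical(stats::pnorm(z), spec$severity_probs[[reg]], 0L)
      out[[paste0(reg, "_freq")]] <-
        cut_categorical(stats::runif(n), spec$frequency_probs[[reg]], 1L)
    }
    out[cohort_column_order(out)]
  })
}

cohort_column_order <- function(df) {
  lead <- c("worker_id", "department", "sex", "age_years", "tenure_months")
  regions <- as.vector(rbind(region_freq_cols(), region_sev_cols()))
  c(intersect(lead, names(df)), intersect(regions, names(df)),
    setdiff(names(df), c(lead, regions)))
}

#' Recover empirical marginals from a cohort
#'
#' The parameter-recovery companion of [generate_cohort()]: computes the
#' empirical category frequencies of every `cohort_spec` field from a
#' cohort data frame, plus an association estimate (the mean over regions
#' of the Spearman rank correlation between severity and RULA level; `NA`
#' when a variable is constant). Useful for goodness-of-fit checks of the
#' generator and for profiling real cohorts.
#'
#' @param cohort A non-empty cohort data frame with a `rula_level` column
#'   (or resolvable RULA input).
#' @return A list shaped like a [cohort_spec()] (class `"cohort_spec"`),
#'   with `seed = NA` and `association` set to the estimate.
#' @examples
#' spec <- default_cohort_spec(n = 500, seed = 9)
#' recover_marginals(generate_cohort(spec))$rula_level_probs
#' @export
recover_marginals <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0) stop("empty cohort: nothing to recover",
                              call. = FALSE)
  n <- nrow(cohort)
  prop <- function(x, levels) as.vector(table(factor(x, levels = levels))) / n
  rula <- resolve_rula(cohort, "action_levels")$level
  rho <- vapply(body_regions, function(reg) {
    sev <- cohort[[paste0(reg, "_sev")]]
    if (stats::sd(sev) == 0 || stats::sd(rula) == 0) return(NA_real_)
    stats::cor(sev, rula, method = "spearman")
  }, numeric(1))
  structure(list(
    n = n,
    department_probs = stats::setNames(prop(cohort$department, departments),
                                       departments),
    rula_level_probs = prop(rula, 1:4),
    severity_probs = stats::setNames(lapply(body_regions, function(reg)
      prop(cohort[[paste0(reg, "_sev")]], 0:4)), body_regions),
    frequency_probs = stats::setNames(lapply(body_regions, function(reg)
      prop(cohort[[paste0(reg, "_freq")]], 1:4)), body_regions),
    association = if (all(is.na(rho))) NA_real_ else mean(rho, na.rm = TRUE),
    seed = NA_integer_
  ), class = "cohort_spec")
}
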