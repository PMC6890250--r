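# Cohort-level classification and prevalence summaries.
#
# A cohort is a plain data frame, one row per worker, in the schema written
# by write_cohort(): worker_id, department, optional sex / age_years /
# tenure_months, per-region <region>_freq and <region>_sev columns, and one
# of three forms of RULA input: the 11 posture-code columns prefixed rula_
# (e.g. rula_upper_arm), a precomputed rula_grand (1-7), or a precomputed
# rula_level (1-4). Posture codes take precedence over a grand score, which
# takes precedence over a level, row by row.

region_freq_cols <- function() paste0(body_regions, "_freq")
region_sev_cols <- function() paste0(body_regions, "_sev")
rula_code_cols <- function() paste0("rula_", rula_posture_columns)

# per-row RULA resolution; returns data.frame(grand_score, level)
resolve_rula <- function(cohort, scheme) {
  n <- nrow(cohort)
  grand <- rep(NA_integer_, n)
  level <- rep(NA_integer_, n)
  codes <- rula_code_cols()
  if (all(codes %in% names(cohort))) {
    have <- stats::complete.cases(cohort[codes])
    if (any(have)) {
      p <- cohort[have, codes]
      names(p) <- rula_posture_columns
      res <- assess_rula(p, scheme = scheme)
      grand[have] <- res$grand_score
      level[have] <- res$level
    }
  }
  if ("rula_grand" %in% names(cohort)) {
    use <- is.na(level) & !is.na(cohort$rula_grand)
    if (any(use)) {
      g <- check_rank(cohort$rula_grand[use], "rula_grand", 1, 7)
      grand[use] <- g
      level[use] <- bin_rula(g, scheme)
    }
  }
  if ("rula_level" %in% names(cohort)) {
    use <- is.na(level) & !is.na(cohort$rula_level)
    if (any(use))
      level[use] <- check_rank(cohort$rula_level[use], "rula_level", 1, 4)
  }
  if (anyNA(level)) {
    ids <- cohort$worker_id[is.na(level)]
    stop("no RULA input (posture codes, grand score or level) for worker(s): ",
         paste(utils::head(ids, 5), collapse = ", "),
         if (length(ids) > 5) sprintf(" (and %d more)", length(ids) - 5),
         call. = FALSE)
  }
  data.frame(grand_score = grand, level = level)
}

#' Classify every worker in a cohort
#'
#' Scores each worker's four regional self-reports ([score_discomfort()]),
#' resolves the worker's single whole-body RULA level (from posture codes,
#' a precomputed grand score, or a precomputed level, in that order of
#' precedence), and crosses the two in the risk matrix
#' ([combine_risk()]). The one RULA level per worker is applied to every
#' region's matrix row.
#'
#' @param cohort Cohort data frame (see [read_cohort()] for the schema).
#' @param scheme RULA binning scheme, see [bin_rula()].
#' @param override Zero-discomfort override, see [combine_risk()].
#' @return A long data frame, one row per worker x region, with columns
#'   `worker_id`, `department`, `region` (ordered factor), `frequency`,
#'   `severity`, `discomfort_score`, `discomfort_level`, `rula_grand`
#'   (`NA` when only a level was supplied), `rula_level`, `matrix_score`
#'   and `hra_level`.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(n = 5, seed = 42))
#' classify_cohort(cohort)
#' @export
classify_cohort <- function(cohort, scheme = c("action_levels", "survey_bins"),
                            override = TRUE) {
  scheme <- match.arg(scheme)
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0) stop("empty cohort: no worker records", call. = FALSE)
  need <- c("worker_id", region_freq_cols(), region_sev_cols())
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("missing cohort columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rula <- resolve_rula(cohort, scheme)
  dept <- if ("department" %in% names(cohort)) cohort$department
          else rep(NA_character_, nrow(cohort))
  out <- lapply(body_regions, function(reg) {
    freq <- cohort[[paste0(reg, "_freq")]]
    sev <- cohort[[paste0(reg, "_sev")]]
    disc <- score_discomfort(freq, sev)
    risk <- combine_risk(disc$level, rula$level, override = override)
    data.frame(worker_id = cohort$worker_id, department = dept,
               region = reg, frequency = as.integer(freq),
               severity = as.integer(sev),
               discomfort_score = disc$score, discomfort_level = disc$level,
               rula_grand = rula$grand_score, rula_level = rula$level,
               matrix_score = risk$matrix_score, hra_level = risk$hra_level)
  })
  out <- do.call(rbind, out)
  out$region <- factor(out$region, levels = body_regions, ordered = TRUE)
  out <- out[order(match(out$worker_id, cohort$worker_id), out$region), ]
  rownames(out) <- NULL
  attr(out, "config") <- list(scheme = scheme, override = override)
  out
}

#' @rdname classify_cohort
#' @param record A single worker record (one-row data frame or named list).
#' @export
classify_worker <- function(record, scheme = c("action_levels", "survey_bins"),
                            override = TRUE) {
  record <- as.data.frame(record)
  if (nrow(record) != 1)
    stop("classify_worker expects exactly one record; use classify_cohort ",
         "for a cohort", call. = FALSE)
  classify_cohort(record, scheme = scheme, override = override)
}

level_table <- function(x, levels, labels, n) {
  count <- as.integer(table(factor(x, levels = levels)))
  data.frame(level = levels, label = unname(labels[as.character(levels)]),
             count = count, pct = round_half_up(100 * count / n, 2))
}

#' Summarise a cohort into prevalence tables
#'
#' Produces the three per-level count/percentage tables of an MSD screening
#' report: the RULA ergonomics-risk distribution (one level per worker),
#' the self-report discomfort distribution per body region, and the
#' combined health-risk (HRA) distribution per body region — plus
#' descriptive statistics for age and tenure when those columns are
#' present. Percentages are `100 * count / n` rounded half-up to two
#' decimals.
#'
#' @inheritParams classify_cohort
#' @param by Optional grouping column of the cohort (e.g. `"department"`):
#'   when given, returns a named list with one summary per group.
#' @return An object of class `"msd_summary"`: a list with elements `n`,
#'   `rula` (data frame level/label/count/pct), `discomfort` and `hra`
#'   (the same per region), `descriptives`, and `config`.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 7))
#' s <- summarize_cohort(cohort)
#' s$rula
#' moderate_or_above(s, "hra", "trunk")
#' @export
summarize_cohort <- function(cohort, scheme = c("action_levels", "survey_bins"),
                             override = TRUE, by = NULL) {
  scheme <- match.arg(scheme)
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0) stop("empty cohort: no worker records", call. = FALSE)
  if (!is.null(by)) {
    if (!by %in% names(cohort))
      stop("grouping column not found: ", by, call. = FALSE)
    groups <- split(cohort, cohort[[by]])
    return(lapply(groups, summarize_cohort, scheme = scheme,
                  override = override))
  }
  cls <- classify_cohort(cohort, scheme = scheme, override = override)
  n <- nrow(cohort)
  per_worker <- cls[!duplicated(cls$worker_id), ]
  rula <- level_table(per_worker$rula_level, 1:4, rula_level_labels, n)
  by_region <- function(col, levels, labels) {
    out <- lapply(body_regions, function(reg) {
      tab <- level_table(cls[[col]][cls$region == reg], levels, labels, n)
      cbind(region = reg, tab)
    })
    do.call(rbind, out)
  }
  disc <- by_region("discomfort_level", 0:4, discomfort_level_labels)
  hra <- by_region("hra_level", 0:4, hra_level_labels)
  descr <- lapply(c(age = "age_years", tenure = "tenure_months"), function(v) {
    if (!v %in% names(cohort)) return(NULL)
    x <- cohort[[v]][!is.na(cohort[[v]])]
    if (!length(x)) return(NULL)
    c(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
      min = min(x), max = max(x))
  })
  structure(list(n = n, rula = rula, discomfort = disc, hra = hra,
                 descriptives = descr[!vapply(descr, is.null, logical(1))],
                 config = list(scheme = scheme, override = override)),
            class = "msd_summary")
}

#' @export
print.msd_summary <- function(x, ...) {
  fmt <- function(tab) sprintf("%d (%.2f)", tab$count, tab$pct)
  cat(sprintf("MSD risk summary (n = %d; scheme = %s, override = %s)\n\n",
              x$n, x$config$scheme, x$config$override))
  cat("Ergonomics risk by RULA [count (%)]\n")
  print(data.frame(level = paste(x$rula$level, x$rula$label),
                   `n (pct)` = fmt(x$rula), check.names = FALSE),
        row.names = FALSE)
  wide <- function(long) {
    m <- matrix(fmt(long), nrow = length(body_regions), byrow = TRUE,
                dimnames = list(body_regions, unique(long$label)))
    as.data.frame(m)
  }
  cat("\nSelf-report discomfort by region [count (%)]\n")
  print(wide(x$discomfort))
  cat("\nCombined health risk (HRA) by region [count (%)]\n")
  print(wide(x$hra))
  if (length(x$descriptives)) {
    cat("\nDescriptives\n")
    print(do.call(rbind, lapply(x$descriptives, round, 2)))
  }
  invisible(x)
}

#' Prevalence at or above a level
#'
#' `pct_at_or_above()` turns a vector of per-level counts into the half-up
#' two-decimal percentage of subjects at or above a given level.
#' `moderate_or_above()` applies it to a table of an [summarize_cohort()]
#' result at level 2 ("moderate"), the conventional screening threshold.
#'
#' @param counts Integer counts per level, ordered from `first_level`
#'   upward.
#' @param min_level Lowest level included in the numerator.
#' @param first_level Level of `counts[1]` (0 for discomfort/HRA tables,
#'   1 for RULA).
#' @param n Denominator; defaults to `sum(counts)`.
#' @return A percentage rounded half-up to 2 decimals.
#' @examples
#' pct_at_or_above(c(59, 36, 9, 2, 1), min_level = 2)  # discomfort, trunk
#' @export
pct_at_or_above <- function(counts, min_level = 2, first_level = 0,
                            n = sum(counts)) {
  if (any(counts < 0) || n <= 0)
    stop("counts must be non-negative with positive total", call. = FALSE)
  keep <- (seq_along(counts) - 1 + first_level) >= min_level
  round_half_up(100 * sum(counts[keep]) / n, 2)
}

#' @rdname pct_at_or_above
#' @param summary An `"msd_summary"` object.
#' @param table One of `"hra"`, `"discomfort"`, `"rula"`.
#' @param region Body region, required for `"hra"` and `"discomfort"`.
#' @export
moderate_or_above <- function(summary, table = c("hra", "discomfort", "rula"),
                              region = NULL) {
  table <- match.arg(table)
  stopifnot(inherits(summary, "msd_summary"))
  if (table == "rula") {
    tab <- summary$rula
    first <- 1L
  } else {
    if (is.null(region) || !region %in% body_regions)
      stop("region must be one of: ", paste(body_regions, collapse = ", "),
           call. = FALSE)
    long <- summary[[table]]
    tab <- long[long$region == region, ]
    first <- 0L
  }
  pct_at_or_above(tab$count, min_level = 2, first_level = first, n = summary$n)
}
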