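# CSV I/O and the end-to-end pipeline run.
#
# File dialect: comma-separated, UTF-8, header row mandatory, empty string =
# missing. One row per worker.

#' Read a cohort CSV
#'
#' Expected columns: `worker_id`, `department`, optional `sex`,
#' `age_years`, `tenure_months`; per-region `<region>_freq` (1–4, may be
#' empty when the matching severity is 0) and `<region>_sev` (0–4) with
#' region prefixes exactly `neck`, `upper_limbs`, `trunk`, `lower_limbs`;
#' and at least one RULA input: the 11 `rula_`-prefixed posture-code
#' columns, `rula_grand` (1–7) or `rula_level` (1–4). Every row either
#' becomes a valid record or is listed in the validation report with its
#' row number, column and reason; invalid rows are dropped unless
#' `strict = TRUE`, in which case any invalid row is an error.
#'
#' @param path Path to a CSV file.
#' @param strict Fail on any invalid row instead of dropping it.
#' @return The cohort data frame of valid rows, with the validation report
#'   (a data frame with columns `row`, `column`, `reason`) in attribute
#'   `"validation_report"`.
#' @seealso [write_cohort()], [generate_cohort()]
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  mandatory <- c("worker_id", "department", region_freq_cols(),
                 region_sev_cols())
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("cohort file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  has_codes <- all(rula_code_cols() %in% names(raw))
  if (!has_codes && !any(c("rula_grand", "rula_level") %in% names(raw)))
    stop("cohort file lacks a RULA input: posture-code columns, ",
         "rula_grand or rula_level", call. = FALSE)
  report <- validate_cohort_rows(raw)
  if (strict && nrow(report) > 0)
    stop(sprintf("invalid cohort rows in strict mode (%d problem(s)); first: row %d, %s: %s",
                 nrow(report), report$row[1], report$column[1],
                 report$reason[1]), call. = FALSE)
  bad <- unique(report$row)
  cohort <- if (length(bad)) raw[-bad, , drop = FALSE] else raw
  rownames(cohort) <- NULL
  attr(cohort, "validation_report") <- report
  cohort
}

# row-wise checks; returns data.frame(row, column, reason)
validate_cohort_rows <- function(raw) {
  problems <- list()
  note <- function(rows, column, reason) {
    if (length(rows))
      problems[[length(problems) + 1]] <<-
        data.frame(row = rows, column = column, reason = reason)
  }
  in_range <- function(x, lo, hi)
    !is.na(x) & suppressWarnings(!is.na(as.numeric(x))) &
      as.numeric(x) >= lo & as.numeric(x) <= hi &
      as.numeric(x) == floor(as.numeric(x))
  note(which(is.na(raw$worker_id) | raw$worker_id == ""), "worker_id",
       "missing worker id")
  note(which(!raw$department %in% departments), "department",
       paste0("department not one of: ", paste(departments, collapse = ", ")))
  for (reg in body_regions) {
    sev_col <- paste0(reg, "_sev")
    freq_col <- paste0(reg, "_freq")
    sev <- raw[[sev_col]]
    freq <- raw[[freq_col]]
    note(which(!in_range(sev, 0, 4)), sev_col, "severity rank outside 0..4")
    ok_sev <- in_range(sev, 0, 4)
    note(which(!is.na(freq) & !in_range(freq, 1, 4)), freq_col,
         "frequency rank outside 1..4")
    note(which(is.na(freq) & ok_sev & as.numeric(sev) > 0), freq_col,
         "frequency missing with nonzero severity")
  }
  has_codes <- all(rula_code_cols() %in% names(raw))
  code_ok <- if (has_codes) stats::complete.cases(raw[rula_code_cols()])
             else rep(FALSE, nrow(raw))
  grand <- if ("rula_grand" %in% names(raw)) raw$rula_grand
           else rep(NA, nrow(raw))
  level <- if ("rula_level" %in% names(raw)) raw$rula_level
           else rep(NA, nrow(raw))
  note(which(!is.na(grand) & !in_range(grand, 1, 7)), "rula_grand",
       "grand score outside 1..7")
  note(which(!is.na(level) & !in_range(level, 1, 4)), "rula_level",
       "RULA level outside 1..4")
  if (has_codes) {
    lims <- list(upper_arm = c(1, 6), lower_arm = c(1, 3), wrist = c(1, 4),
                 wrist_twist = c(1, 2), neck = c(1, 6), trunk = c(1, 6),
                 legs = c(1, 2), muscle_use_a = c(0, 1), force_a = c(0, 3),
                 muscle_use_b = c(0, 1), force_b = c(0, 3))
    for (nm in names(lims)) {
      col <- paste0("rula_", nm)
      x <- raw[[col]]
      note(which(!is.na(x) & !in_range(x, lims[[nm]][1], lims[[nm]][2])),
           col, sprintf("posture code outside %d..%d", lims[[nm]][1],
                        lims[[nm]][2]))
    }
  }
  note(which(!code_ok & is.na(grand) & is.na(level)), "rula_level",
       "no RULA input (posture codes, grand score or level)")
  if (!length(problems))
    return(data.frame(row = integer(), column = character(),
                      reason = character()))
  out <- do.call(rbind, problems)
  out <- out[order(out$row), ]
  rownames(out) <- NULL
  out
}

#' Write a cohort CSV
#'
#' Writes the schema read back by [read_cohort()]; missing values become
#' empty fields. Round-tripping a cohort through `write_cohort()` then
#' [read_cohort()] is the identity.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the whole screening pipeline
#'
#' Takes a cohort — a CSV path, a cohort data frame, or a [cohort_spec()]
#' to simulate from — classifies every worker, and writes the run
#' artifacts into `output_dir`: the per-worker classification
#' (`classified.csv`), the three prevalence tables (`summary_rula.csv`,
#' `summary_discomfort.csv`, `summary_hra.csv`), an aligned plain-text
#' report (`summary.txt`), the cohort itself when it was simulated
#' (`cohort.csv`), and `run_config.json` recording everything needed to
#' regenerate the run (scheme, override flag, strict flag, seed and
#' generator spec when simulated, n, row counts in/out).
#'
#' @param input CSV path, cohort data frame, or `cohort_spec`.
#' @param output_dir Directory for artifacts (created if needed).
#' @inheritParams classify_cohort
#' @param strict Passed to [read_cohort()] when `input` is a path.
#' @return The [summarize_cohort()] result, invisibly.
#' @export
run_pipeline <- function(input, output_dir,
                         scheme = c("action_levels", "survey_bins"),
                         override = TRUE, strict = FALSE) {
  scheme <- match.arg(scheme)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- inherits(input, "cohort_spec")
  rows_read <- NA_integer_
  if (simulated) {
    cohort <- generate_cohort(input)
    write_cohort(cohort, file.path(output_dir, "cohort.csv"))
  } else if (is.character(input)) {
    cohort <- read_cohort(input, strict = strict)
    rows_read <- nrow(cohort) + length(unique(
      attr(cohort, "validation_report")$row))
  } else {
    cohort <- as.data.frame(input)
  }
  cls <- classify_cohort(cohort, scheme = scheme, override = override)
  s <- summarize_cohort(cohort, scheme = scheme, override = override)
  utils::write.csv(cls, file.path(output_dir, "classified.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(s$rula, file.path(output_dir, "summary_rula.csv"),
                   row.names = FALSE)
  utils::write.csv(s$discomfort,
                   file.path(output_dir, "summary_discomfort.csv"),
                   row.names = FALSE)
  utils::write.csv(s$hra, file.path(output_dir, "summary_hra.csv"),
                   row.names = FALSE)
  writeLines(utils::capture.output(print(s)),
             file.path(output_dir, "summary.txt"))
  config <- list(
    scheme = scheme, zero_discomfort_override = override, strict = strict,
    n = s$n, rows_read = rows_read,
    input = if (is.character(input)) input
            else if (simulated) "simulated" else "data.frame",
    generator_spec = if (simulated) unclass(input) else NULL,
    seed = if (simulated) input$seed else NULL
  )
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                       file.path(output_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(s)
}
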