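# Cohort classification and prevalence summaries.

test_that("classify_worker crosses each region with the single RULA level", {
  quiet <- blank_cohort(1)
  cls <- classify_worker(quiet[1, ])
  expect_equal(nrow(cls), 4L)
  expect_equal(as.character(cls$region), body_regions)
  expect_true(all(cls$hra_level == 0L))

  w <- set_region_levels(blank_cohort(1, rula_level = 4L), "trunk", 4)
  w$trunk_freq <- 3L; w$trunk_sev <- 3L   # score 9, very severe
  cls <- classify_worker(w)
  trunk <- cls[cls$region == "trunk", ]
  expect_equal(trunk$discomfort_score, 9L)
  expect_equal(trunk$discomfort_level, 4L)
  expect_equal(trunk$matrix_score, 16L)
  expect_equal(trunk$hra_level, 4L)
  # the whole-body RULA level also reaches the untouched regions
  expect_true(all(cls$rula_level == 4L))

  w <- blank_cohort(1, rula_level = 3L)
  w$neck_freq <- 1L; w$neck_sev <- 1L
  neck <- classify_worker(w)
  neck <- neck[neck$region == "neck", ]
  expect_equal(neck$discomfort_level, 1L)
  expect_equal(neck$matrix_score, 3L)
  expect_equal(neck$hra_level, 2L)
})

test_that("RULA input precedence is posture codes, then grand, then level", {
  co <- blank_cohort(3)
  for (col in rula_posture_columns) co[[paste0("rula_", col)]] <- NA_integer_
  co[1, paste0("rula_", rula_posture_columns)] <-
    as.list(c(6, 3, 4, 2, 6, 6, 2, 1, 3, 1, 3))  # grand 7
  co$rula_grand <- c(NA, 3L, NA)                  # level 2
  co$rula_level <- c(1L, 1L, 2L)                  # used only for row 3
  cls <- classify_cohort(co)
  per_worker <- cls[!duplicated(cls$worker_id), ]
  expect_equal(per_worker$rula_level, c(4L, 2L, 2L))
  expect_equal(per_worker$rula_grand, c(7L, 3L, NA))
  # a worker with no input at all is named in the error
  co2 <- blank_cohort(2)
  co2$rula_level <- c(2L, NA)
  expect_error(classify_cohort(co2), "T0002")
})

test_that("summary counts always sum to n, in every table", {
  co <- generate_cohort(default_cohort_spec(n = 150, seed = 11,
                                            association = 0.4))
  s <- summarize_cohort(co)
  expect_equal(sum(s$rula$count), s$n)
  for (reg in body_regions) {
    expect_equal(sum(s$discomfort$count[s$discomfort$region == reg]), s$n)
    expect_equal(sum(s$hra$count[s$hra$region == reg]), s$n)
  }
  # unrounded percentages are a partition of 100
  expect_equal(sum(100 * s$rula$count / s$n), 100)
})

test_that("summaries are invariant to the order of worker records", {
  co <- generate_cohort(default_cohort_spec(n = 80, seed = 5))
  perm <- with_fixed_seed(99, sample(nrow(co)))
  expect_equal(summarize_cohort(co[perm, ]), summarize_cohort(co))
})

test_that("toggling the override only moves mass between levels 0 and 1", {
  for (seed in c(2, 13)) {
    co <- generate_cohort(default_cohort_spec(n = 120, seed = seed))
    on_ <- summarize_cohort(co, override = TRUE)$hra
    off <- summarize_cohort(co, override = FALSE)$hra
    keep <- on_$level >= 2
    expect_equal(on_$count[keep], off$count[keep])
    # mass below moderate is only redistributed, never created or lost
    for (reg in body_regions) {
      low <- !keep & on_$region == reg
      expect_equal(sum(on_$count[low]), sum(off$count[low]))
    }
    for (reg in body_regions) {
      expect_equal(moderate_or_above(summarize_cohort(co, override = TRUE),
                                     "hra", reg),
                   moderate_or_above(summarize_cohort(co, override = FALSE),
                                     "hra", reg))
    }
  }
})

test_that("percentages are rounded half-up to two decimals", {
  s <- summarize_cohort(cohort_from_rula_counts(c(0, 3, 21, 83)))
  expect_equal(s$rula$pct, c(0, 2.80, 19.63, 77.57))
  # half-up at the boundary, where round() would go to even
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.345, 2), 2.35)
})

test_that("moderate-or-above matches direct count arithmetic", {
  s <- summarize_cohort(cohort_from_discomfort_counts("trunk",
                                                      c(59, 36, 9, 2, 1)))
  expect_equal(moderate_or_above(s, "discomfort", "trunk"), 11.21)
  expect_equal(moderate_or_above(s, "discomfort", "neck"), 0)
  expect_equal(pct_at_or_above(c(59, 36, 9, 2, 1)), 11.21)
  s <- summarize_cohort(cohort_from_hra_counts("trunk", c(59, 1, 35, 9, 3)))
  expect_equal(moderate_or_above(s, "hra", "trunk"),
               round_half_up(100 * 47 / 107, 2))
  expect_error(moderate_or_above(s, "hra"), "region")
})

test_that("degenerate cohorts are handled explicitly", {
  one <- blank_cohort(1)
  s <- summarize_cohort(one)
  expect_equal(sum(s$rula$pct == 100), 1L)
  for (reg in body_regions)
    expect_equal(sum(s$hra$pct[s$hra$region == reg] == 100), 1L)
  expect_error(summarize_cohort(blank_cohort(0)), "empty cohort")
  expect_error(classify_worker(blank_cohort(2)), "exactly one")
})

test_that("department stratification returns one summary per group", {
  co <- generate_cohort(default_cohort_spec(n = 200, seed = 21))
  by_dept <- summarize_cohort(co, by = "department")
  expect_setequal(names(by_dept), unique(co$department))
  expect_equal(sum(vapply(by_dept, `[[`, numeric(1), "n")), 200)
  expect_error(summarize_cohort(co, by = "shift"), "shift")
})
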