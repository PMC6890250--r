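#' Body regions, departments and level labels
#'
#' Fixed categorical vocabularies used throughout the package. The four body
#' regions are the self-report anatomical groupings (neck; upper limbs =
#' shoulders, forearms, hands/wrists; trunk = upper and lower back; lower
#' limbs = legs, feet), always in this order. Departments are the four
#' production units of the workforce the synthetic generator emulates.
#'
#' @format Character vectors. `discomfort_level_labels` is named by level
#'   0–4, `rula_level_labels` by level 1–4, `hra_level_labels` by level 0–4.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
body_regions <- c("neck", "upper_limbs", "trunk", "lower_limbs")

#' @rdname vocabularies
#' @export
departments <- c("cool_room", "process", "packing", "warehouse")

#' @rdname vocabularies
#' @export
discomfort_level_labels <- c(
  `0` = "no discomfort", `1` = "mild", `2` = "moderate",
  `3` = "severe", `4` = "very severe"
)

#' @rdname vocabularies
#' @export
rula_level_labels <- c(
  `1` = "low", `2` = "moderate", `3` = "high", `4` = "very high"
)

#' @rdname vocabularies
#' @export
hra_level_labels <- c(
  `0` = "acceptable", `1` = "low", `2` = "moderate",
  `3` = "high", `4` = "very high"
)

# recommended follow-up per HRA level, used when printing the risk matrix
hra_level_actions <- c(
  `0` = "acceptable risk",
  `1` = "low risk; surveillance suggested",
  `2` = "moderate risk; controls and training",
  `3` = "high risk; control measures, training or workstation modification",
  `4` = "very high risk; immediate safety management and engineering design"
)
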