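#' Round half away from zero
#'
#' Percentages in prevalence tables are rounded half-up (0.005 rounds to
#' 0.01), the convention of the survey tables this package reproduces, rather
#' than base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep (default 2).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(100 * 83 / 107)  # 77.57
#' round_half_up(2.345)           # 2.35, where round(2.345, 2) gives 2.34
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the tiny offset counters binary representation of values like x.xx5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# integer-range validation; names the offending field and value in the error
check_rank <- function(x, field, lo, hi, allow_na = FALSE) {
  x <- as.numeric(x)
  bad <- if (allow_na) !is.na(x) & (x < lo | x > hi | x != floor(x))
         else is.na(x) | x < lo | x > hi | x != floor(x)
  if (any(bad)) {
    v <- x[bad][1]
    stop(sprintf("%s: value %s outside %d..%d", field,
                 if (is.na(v)) "NA" else format(v), lo, hi), call. = FALSE)
  }
  invisible(as.integer(x))
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# categorical draw by inverse-CDF on a uniform; category indices start at
# `first`; zero-probability categories are never drawn
cut_categorical <- function(u, probs, first = 0L) {
  as.integer(findInterval(u, cumsum(probs[-length(probs)])) + first)
}

check_simplex <- function(p, field, len, tol = 1e-9) {
  if (length(p) != len)
    stop(sprintf("%s: expected %d probabilities, got %d", field, len,
                 length(p)), call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop(sprintf("%s: probabilities must be non-negative and sum to 1",
                 field), call. = FALSE)
  invisible(as.numeric(p))
}
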