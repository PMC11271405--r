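#' Round half away from zero
#'
#' Percent reporting in this package rounds halves away from zero
#' (42.97 -> 43, 54.64 -> 55, 0.5 -> 1), unlike base [round()] which rounds
#' halves to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded with ties away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5))   # 1  2 -1
#' round_half_up(100 * 53 / 97)       # 55
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded to whole percent
#'
#' @param k numerator count(s).
#' @param n denominator count.
#' @return integer percent(s), rounded half away from zero.
#' @export
pct <- function(k, n) {
  stopifnot(n > 0)
  out <- as.integer(round_half_up(100 * k / n))
  names(out) <- names(k)
  out
}

abort <- function(..., class = "pgtkit_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar NA-tolerant helpers used by the validators
is_na_or <- function(x, pred) is.na(x) | pred(x)
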