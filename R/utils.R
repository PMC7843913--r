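#' @importFrom rlang %||% abort warn .data
#' @importFrom stats pnorm qnorm pchisq pbinom quantile setNames rbinom rnorm runif
NULL

#' Round half up at a decimal resolution
#'
#' Decimal rounding with ties going away from zero, as used on clinical report
#' sheets (base R's `round()` rounds half to even, which turns 82.55 into
#' 82.5). Values are first snapped to 8 decimals to absorb binary
#' floating-point representation error, so `(76.9 + 88.2) / 2` rounds to 82.6.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(82.55, 32.35, 69.74), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  y <- round(x * 10^digits, 8)
  sign(y) * floor(abs(y) + 0.5) / 10^digits
}

# stop unless all values are finite numbers
check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(paste0("`", what, "` must be finite numeric"))
  }
  invisible(x)
}

check_integerish_range <- function(x, lo, hi, what) {
  check_finite(x, what)
  if (any(x != round(x)) || any(x < lo) || any(x > hi)) {
    abort(sprintf("`%s` must be integers in [%d, %d]", what, lo, hi))
  }
  invisible(x)
}

# collapse note strings, dropping empties
join_notes <- function(...) {
  parts <- c(...)
  parts <- parts[nzchar(parts)]
  paste(parts, collapse = "; ")
}
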