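#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals: exact halves move away
#' from zero, unlike [base::round()]'s round-half-even. Used by the
#' printed-precision mode so whole-percent and two-decimal intermediates match
#' the convention of published tables.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(0.5)   # 1
#' round_half_away(-0.5)  # -1
#' round_half_away(2.345, 2)
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a relative epsilon so values stored as 77.49999999 from decimal
  # arithmetic still round like the exact half
  z <- abs(x) * p
  z <- floor(z + 0.5 + sqrt(.Machine$double.eps))
  sign(x) * z / p
}

# internal: stop with a classed condition so callers/tests can target errors
abort_radsyn <- function(msg, class) {
  stop(structure(
    class = c(class, "radsyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
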