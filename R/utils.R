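#' Round half away from zero
#'
#' Fixed-point rounding with halves going up (away from zero), the convention
#' used when reporting agreement percentages.  `base::round()` rounds half to
#' even, which would turn 83.335 into 83.34 or 83.33 depending on the
#' floating-point neighbourhood; validation tables use strict half-up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(90.476, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# population standard deviation (divisor n, not n - 1)
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent error class so callers can test on condition class
abort_starchbsa <- function(msg, class) {
  stop(structure(
    class = c(class, "starchbsa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
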