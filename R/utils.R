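#' Round half away from zero
#'
#' Commercial rounding used for all reported dollar amounts and percentages:
#' ties round away from zero (4508.5 -> 4509, -9855.5 -> -9856), unlike base
#' [round()], which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_away(4508.595)  # 4509
#' round_half_away(0.5)       # 1, where round(0.5) gives 0
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Shared validator: a single finite, non-negative number.
assert_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single finite number >= 0, got: %s",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Stage-tagged re-raise used by the pipeline so a validation failure in any
# stage aborts with the offending stage in the message.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}
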