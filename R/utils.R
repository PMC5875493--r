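# Internal numeric helpers shared across the package.

#' Round half away from zero
#'
#' Commercial dosimetry tables round ties away from zero (so 20.475 -> 20.5),
#' unlike [base::round()]'s round-half-even.  Used only at display/reporting
#' boundaries; all internal arithmetic is full precision.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(20.475, 1)  # 20.5, where round() gives 20.5 or 20.4
#' round_half_away(-0.125, 2)  # -0.13
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulp so values that are exact halves after decimal
  # representation (e.g. 20.475 stored as 20.47499...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("brachyqa_invalid_parameter", "brachyqa_error")))
}

stop_range <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("brachyqa_out_of_range", "brachyqa_error")))
}

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0)
    stop_invalid(name, " must be > 0 (got ", x, ")")
  invisible(x)
}
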