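#' Round half away from zero
#'
#' Report-time rounding used throughout: ties round away from zero
#' (so 0.05 -> 0.1 at one decimal), mirroring how the tabulated
#' histomorphometric values are printed. Internal computations are never
#' rounded; this is applied only when formatting results.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_report(254.125, 1) # 254.1
#' round_report(0.05, 1)    # 0.1, not 0.0
#' @export
round_report <- function(x, digits = 1) {
  scale <- 10^digits
  # add a whisker of slack so values that are exactly .5 after decimal
  # arithmetic (e.g. 654.05 stored as 654.049999...) still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# stop() with a consistent prefix naming the pipeline stage
abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 0
}

is_scalar_number <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x)
}
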