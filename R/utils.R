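#' Round half away from zero
#'
#' Base `round()` rounds half to even; published percentage tables in
#' drug-utilization work conventionally round half up. Used only for display
#' columns; internal arithmetic stays unrounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, 2.5), digits = c(2, 0)[1])
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # epsilon guards against binary representation pushing an exact .5 tie
  # just below it (e.g. 0.15 * 10 == 1.4999...)
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Parse ISO-8601 dates strictly; anything not %Y-%m-%d becomes NA.
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

fmt_iso <- function(d) format(d, "%Y-%m-%d")

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "adinit_input_error")
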