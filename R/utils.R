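# Shared internal helpers: condition classes, formatting, small checks.

# Ordered states used by every study variable.
.states3 <- c("low", "moderate", "high")

stop_input <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("noisebn_input_error", "noisebn_error")))
}

stop_compute <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("noisebn_compute_error", "noisebn_error")))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

#' Format a percentage the way descriptive tables print it
#'
#' One decimal place, except that integer values are printed without a
#' decimal (so 30.97 renders as "31" and 38.496 as "38.5").
#'
#' @param p Numeric vector of percentages (0-100 scale).
#' @return Character vector.
#' @export
#' @examples
#' format_percent(c(70, 87, 69) / 226 * 100)
format_percent <- function(p) {
  r <- round(p, 1)
  vapply(r, function(x) sprintf("%g", x), character(1))
}

#' Format a delta-p value in percentage points
#'
#' Rounds to one decimal, prints an explicit sign, and appends a percent
#' sign; an exact (rounded) zero prints as "0 %".
#'
#' @param pp Numeric vector of changes in percentage points.
#' @return Character vector such as "-9.4 %", "+5 %", "0 %".
#' @export
#' @examples
#' format_pp(c(-9.4, 5, 0, 10.6))
format_pp <- function(pp) {
  r <- round(pp, 1)
  vapply(r, function(x) {
    if (x == 0) "0 %" else sprintf("%+g %%", x)
  }, character(1))
}

# round probabilities to 3 decimals and repair the largest entry so the
# printed row still sums to 1.000
round_probs_repair <- function(p, digits = 3) {
  r <- round(p, digits)
  gap <- round(1 - sum(r), digits)
  if (gap != 0) {
    i <- which.max(p)
    r[i] <- r[i] + gap
  }
  r
}
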