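# Internal numeric helpers shared across modules.

#' Round half-up at a fixed number of decimals
#'
#' Commercial ("half-up") rounding: ties at .5 always round away from zero
#' (inputs here are non-negative, so upward). Base R's `round()` uses
#' banker's rounding, which does not reproduce percentage tables produced
#' with spreadsheet conventions, so reporting boundaries use this helper
#' instead. A small epsilon absorbs binary floating-point representation
#' error (e.g. 55.7100000000001).
#'
#' @param x numeric vector, assumed non-negative.
#' @param digits integer number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.5)        # 3, not 2
#' round_half_up(0.1096, 2)  # 0.11
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Apply one of the configurable integer rounding modes.
apply_rounding <- function(x, mode) {
  switch(mode,
    floor = floor(x + 1e-9),
    half_up = round_half_up(x),
    ceiling = ceiling(x - 1e-9),
    stop("unknown rounding mode: ", mode, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent error for argument-domain violations.
stop_domain <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
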