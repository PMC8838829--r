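# Internal helpers: condition classes, seeded evaluation, rounding.

fb_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "filletbend_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_invalid    <- function(msg) fb_stop(msg, "fb_invalid_argument")
stop_no_object  <- function(msg) fb_stop(msg, "fb_no_object")
stop_not_found  <- function(msg) fb_stop(msg, "fb_not_found")
stop_format     <- function(msg) fb_stop(msg, "fb_format_error")
stop_degenerate <- function(msg) fb_stop(msg, "fb_degenerate_shape")
stop_degen_fit  <- function(msg) fb_stop(msg, "fb_degenerate_fit")
stop_incomplete <- function(msg) fb_stop(msg, "fb_incomplete_grid")
stop_empty_out  <- function(msg) fb_stop(msg, "fb_empty_output")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library code never perturbs it.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.0005 -> 0.001), the convention used
#' when rendering report tables; R's `round()` rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
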