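# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

# derive a per-stage seed from a global one, staying inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483629L
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    stop_domain("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

# day-of-year -> calendar month (365-day year, no leap day)
month_of_day <- function(day) {
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(day - 1, c(0, ends[-12])) # 1..12
}
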