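# Internal helpers shared across modules.

clamp01 <- function(x) pmin(1, pmax(0, x))

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop(sprintf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
check_count <- function(x, name, lower = 0) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stop(sprintf("'%s' must be an integer count", name), call. = FALSE)
  invisible(as.integer(x))
}

#' Derive a per-entity RNG seed from a master seed
#'
#' One RNG stream per bee or trace is derived from (master seed, entity id) so
#' simulated cohorts are reproducible regardless of generation order. The
#' result is always a valid 32-bit seed.
#'
#' @param master Master integer seed.
#' @param id Integer entity index (bee number, trace number, ...).
#' @return A single integer seed between 0 and 2^31 - 2.
#' @export
derive_seed <- function(master, id) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(id) * 16807 + 1) %% 2147483647)
}
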