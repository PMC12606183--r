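# Internal helpers shared across modules.

# "05:30" -> 5.5 (decimal hours)
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 60, numeric(1))
}

# decimal hour-of-day of a POSIXct, in UTC
clock_hours <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

check_count <- function(x, name, min = 1) {
  if (!is_scalar_integerish(x) || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.",
                  name, min, deparse(substitute(x))),
          class = "elevrange_input_error")
  }
  as.integer(x)
}

check_range <- function(x, name) {
  if (length(x) != 2 || any(!is.finite(x)) || x[1] >= x[2]) {
    abort(sprintf("`%s` must be an ordered pair (lo < hi).", name),
          class = "elevrange_input_error")
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be finite and >= 0.", name),
          class = "elevrange_input_error")
  }
  x
}

# Stable sub-seed derivation: keeps derived seeds positive and < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
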