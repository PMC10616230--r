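# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a child seed from a master seed and a stage label, deterministically
## and below 2^31 so it is a valid R integer seed.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

## Great-circle distance in km between (lat, lon) degree pairs.
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

## Lag-1 autocorrelation about the mean; NA-free numeric input.
acf_lag1 <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom <= 0) return(NA_real_)
  sum(z[-1] * z[-n]) / denom
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

## Check a scalar is a finite number.
assert_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  invisible(x)
}
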