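#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Round half away from zero
#'
#' Fixed-point rounding used for the percentage tables (half-up, as the
#' printed tables use), as opposed to base R's banker's rounding.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## derive a child seed from a master seed; kept below 2^31 - 1
child_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in ix) s <- (s * 48271 + as.double(i) * 9973 + 1) %% 2147483647
  as.integer(s)
}

## van der Corput base-2 low-discrepancy sequence (nested under doubling n)
vdc <- function(n) {
  vapply(seq_len(n), function(i) {
    x <- 0; f <- 0.5; k <- i
    while (k > 0) { x <- x + f * (k %% 2); k <- k %/% 2; f <- f / 2 }
    x
  }, numeric(1))
}

## quadratic a*t^2 + b*t + c <= 0 solved for an interval, vectorized.
## Assumes a > 0 elementwise (checked by callers). Returns lo/hi, NA = empty.
quad_interval <- function(a, b, c) {
  disc <- b * b - 4 * a * c
  ok <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  lo <- (-b - sq) / (2 * a)
  hi <- (-b + sq) / (2 * a)
  lo[!ok] <- NA_real_
  hi[!ok] <- NA_real_
  list(lo = lo, hi = hi)
}

## intersect two intervals given as lo/hi vectors (NA = empty)
int_intersect <- function(lo1, hi1, lo2, hi2) {
  lo <- pmax(lo1, lo2)
  hi <- pmin(hi1, hi2)
  empty <- is.na(lo) | is.na(hi) | lo > hi
  lo[empty] <- NA_real_
  hi[empty] <- NA_real_
  list(lo = lo, hi = hi)
}
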