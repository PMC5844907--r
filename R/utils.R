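#' @keywords internal
"_PACKAGE"

## Deterministic per-plane / per-stage RNG substreams.
##
## Every randomized step draws from a seed derived from (master seed, stage
## label, index) so that serial, reversed and parallel execution of the
## per-plane loop give bit-identical results.

#' Derive a deterministic substream seed
#'
#' Combines a master seed with a stage label and an integer index into a
#' 31-bit seed via a splitmix-style integer hash, so independent planes get
#' independent, order-insensitive random streams.
#'
#' @param seed master seed (integer).
#' @param stage character stage label (e.g. "xy", "noise").
#' @param index integer index (e.g. plane number), default 0.
#' @return a single integer in [0, 2^31 - 1].
#' @export
substream_seed <- function(seed, stage = "", index = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  h <- (h * 131 + (as.numeric(index) %% 2147483647)) %% 2147483647
  # one round of multiplicative mixing keeps nearby (seed, index) pairs apart
  h <- (h * 48271) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, stage, index, code) {
  withr::with_seed(substream_seed(seed, stage, index), code)
}

#' Round half-up and clip to the representable intensity range
#'
#' Converts real-valued intensities to integer analog-to-digital units (ADU):
#' values are rounded half-up (10.5 -> 11) then clipped to
#' [0, 2^bit_depth - 1].
#'
#' @param x numeric vector/matrix of intensities.
#' @param bit_depth 8 or 16.
#' @return object of the same shape, integer-valued (stored as numeric).
#' @export
quantize_adu <- function(x, bit_depth) {
  hi <- 2^bit_depth - 1
  pmin(pmax(floor(x + 0.5), 0), hi)
}

## Quantile rank grid k/(Q+1), k = 1..Q; interior ranks avoid the 0/1
## endpoints hitting the sample extremes.
quantile_ranks <- function(n_quantiles) {
  seq_len(n_quantiles) / (n_quantiles + 1)
}

## Empirical quantile at arbitrary ranks, linear interpolation between order
## statistics (classical type-7 definition).
empirical_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

## Inverse of the type-7 empirical quantile function: the continuous rank p
## such that empirical_quantile(x, p) == v.  Flat stretches (duplicated
## values) resolve to the highest rank attaining v, matching the "fraction of
## pixels <= v" reading.  Clamped to [0, 1] outside the data range.
empirical_rank <- function(x, v) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L || v >= s[n]) return(1)
  if (v <= s[1]) return(0)
  stats::approx(s, seq(0, 1, length.out = n), xout = v, ties = max)$y
}

is_odd <- function(n) n %% 2 == 1

## Coerce an even window to the next odd value (with a note-worthy flag).
coerce_odd <- function(n) if (is_odd(n)) as.integer(n) else as.integer(n + 1)
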