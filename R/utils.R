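#' The four escape-response labels
#'
#' Order is fixed across the package: stop (freezing), slow_down,
#' speed_up (running), no_reaction.
#'
#' @return Character vector of length 4.
#' @export
response_labels <- function() c("stop", "slow_down", "speed_up", "no_reaction")

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer mixing used for per-fly / per-genotype seed
#' spawning; all arithmetic stays below 2^53 so the result is exact, and the
#' returned value is a valid 32-bit seed.
#'
#' @param seed Master seed (integer-valued scalar).
#' @param i Child index (integer-valued scalar).
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, i) {
  a <- as.double(seed) %% 2147483647
  v <- (a * 69069 + as.double(i) * 104729 + 12345) %% 2147483629
  as.integer(v)
}

# Run set.seed only when a seed was supplied.
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

# Centered moving average with edge windows clipped to the available range
# (window k = offsets -floor(k/2) .. ceiling(k/2)-1, matching a k-bin
# average centered between samples for even k).
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  lo <- floor(k / 2)
  hi <- ceiling(k / 2) - 1L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}
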