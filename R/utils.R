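`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

## equal-tailed weighted quantiles of a sample (type-4 style interpolation
## on the weighted ecdf)
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0))
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  }, numeric(1))
}

## deterministic substream seed derived from a master seed (kept < 2^31)
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
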