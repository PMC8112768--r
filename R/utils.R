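# Internal helpers: seeded evaluation, deterministic string hashing,
# weighted quantiles.

MOD31 <- 2147483647  # 2^31 - 1; all derived seeds stay below R's integer max

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never disturb the
#' caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Deterministic 31-bit hash of a string (polynomial rolling hash)
#' @noRd
hash_string <- function(s) {
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% MOD31
  h
}

#' Derive a stream seed from a root seed and a label
#' @noRd
derive_seed <- function(seed, label) {
  (as.numeric(seed) %% MOD31 * 2654435761 + hash_string(label)) %% MOD31
}

#' Weighted quantiles of a sample
#'
#' Inverse of the weighted empirical CDF with linear interpolation between
#' adjacent order statistics: the k-th sorted value is assigned cumulative
#' probability `(c_k - w_k/2) / W` (`c_k` = cumulative weight, `W` = total),
#' and quantiles interpolate linearly between these points. With equal
#' weights this is the Hazen convention; results are invariant to uniform
#' rescaling of the weights and monotone in the probability level.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `probs`.
#' @examples
#' weighted_quantile(1:4, rep(1, 4), 0.5)  # 2.5
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs >= 0 & probs <= 1))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  p <- (cw - w / 2) / cw[length(cw)]
  if (length(x) == 1L) return(rep(x, length(probs)))
  stats::approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Weighted mean wrapper tolerating zero-weight entries
#' @noRd
wmean <- function(x, w) sum(x * w) / sum(w)

`%||%` <- function(a, b) if (is.null(a)) b else a
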