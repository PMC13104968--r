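# Internal numerical helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when a == b (within fp).
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp requires a >= b")
  if (!is.finite(a)) return(-Inf)
  d <- b - a
  if (d >= 0) return(-Inf)
  a + log1p(-exp(d))
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

variant_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Cut n items (in given order) into k approximately equal contiguous blocks.
contiguous_blocks <- function(n, k) {
  if (k < 1L) stop("need at least one block")
  k <- min(k, n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Leave-one-block-out jackknife of a mean
#'
#' Cuts an ordered vector into contiguous blocks, recomputes the mean with
#' each block left out, and returns the delete-block jackknife standard
#' error. Used throughout the package wherever a genome-ordered statistic
#' needs a standard error robust to local correlation.
#'
#' @param x numeric vector in genome (or other meaningful) order.
#' @param n_blocks number of contiguous blocks (reduced to `length(x)` if
#'   larger).
#' @return list with `estimate` (full-sample mean), `loo` (leave-one-out
#'   means), `se` (jackknife SE) and `n_blocks` actually used.
#' @export
block_jackknife <- function(x, n_blocks = 200L) {
  n <- length(x)
  if (n < 2L) stop("need at least two observations")
  blk <- contiguous_blocks(n, n_blocks)
  k <- max(blk)
  tot <- sum(x)
  bsum <- tapply(x, blk, sum)
  bn <- tabulate(blk, nbins = k)
  loo <- (tot - bsum) / (n - bn)
  est <- tot / n
  se <- jackknife_se(loo)
  list(estimate = est, loo = as.numeric(loo), se = se, n_blocks = k)
}

# Delete-block jackknife SE from leave-one-out estimates.
jackknife_se <- function(loo) {
  loo <- loo[is.finite(loo)]
  k <- length(loo)
  if (k < 2L) return(NA_real_)
  sqrt((k - 1) / k * sum((loo - mean(loo))^2))
}
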