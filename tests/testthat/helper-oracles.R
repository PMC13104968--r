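# Independent oracles used by the tests. These deliberately avoid the
# package's log-space / closed-form implementations: plain arithmetic,
# exhaustive enumeration, or brute-force recurrences only.

# Direct-arithmetic colocalization oracle: per-variant ABFs on the natural
# scale, hypothesis sums by explicit enumeration. Returns NULL when the
# natural-scale arithmetic overflows/underflows to non-finite values.
coloc_oracle <- function(locus, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w = 0.04) {
  va <- 1 / locus$n_a
  vb <- 1 / locus$n_b
  ra <- w / (va + w)
  rb <- w / (vb + w)
  A <- sqrt(1 - ra) * exp(ra * locus$z_a^2 / 2)
  B <- sqrt(1 - rb) * exp(rb * locus$z_b^2 / 2)
  if (any(!is.finite(A)) || any(!is.finite(B))) return(NULL)
  m <- length(A)
  h0 <- 1
  h1 <- p1 * sum(A)
  h2 <- p2 * sum(B)
  h3 <- 0
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (j != k) h3 <- h3 + A[j] * B[k]
  }
  h3 <- p1 * p2 * h3
  h4 <- p12 * sum(A * B)
  tot <- h0 + h1 + h2 + h3 + h4
  if (!is.finite(tot)) return(NULL)
  list(pp = c(PP_H0 = h0, PP_H1 = h1, PP_H2 = h2, PP_H3 = h3,
              PP_H4 = h4) / tot,
       h4_posterior = A * B / sum(A * B),
       pip_a = A / sum(A))
}

random_locus <- function(m, seed) {
  set.seed(seed)
  data.frame(pos = sort(sample.int(1e6, m)) ,
             z_a = stats::rnorm(m, sd = sample(c(1, 2, 4), 1)),
             z_b = stats::rnorm(m, sd = sample(c(1, 2, 4), 1)),
             n_a = sample(c(1e3, 1e4, 1e5), 1),
             n_b = sample(c(1e3, 1e4, 1e5), 1))
}

# Hypergeometric upper-tail oracle by exhaustive enumeration of all
# C(N, n) draws from the universe (feasible for small N only).
hyper_oracle_combn <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  in_pathway <- seq_len(K)   # first K universe elements form the pathway
  hits <- apply(draws, 2L, function(d) sum(d %in% in_pathway) >= k)
  mean(hits)
}

# Hypergeometric upper-tail oracle by direct combinatorial summation with
# exact choose() terms (independent of stats::phyper).
hyper_oracle_choose <- function(k, K, N, n) {
  i <- max(k, 0):min(K, n)
  if (length(i) == 0L || max(K, 0) < k) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small hand-buildable cohort: dosages supplied directly.
toy_cohort <- function(dosage, date_bp, ancestry = NULL,
                       pseudohaploid = NULL) {
  n <- nrow(dosage)
  V <- ncol(dosage)
  if (is.null(ancestry)) ancestry <- matrix(1, n, 1)
  if (is.null(pseudohaploid)) pseudohaploid <- rep(FALSE, n)
  ancient_cohort(
    individual_id = sprintf("I%03d", seq_len(n)),
    date_bp = date_bp, ancestry = ancestry, dosage = dosage,
    pseudohaploid = pseudohaploid,
    variants = data.frame(chrom = 1L, pos = seq_len(V) * 1000L,
                          ref = "A", alt = "G", stringsAsFactors = FALSE)
  )
}

# Binomial dosage matrix with mean trend 2 * p(t): used for scan oracles.
trend_dosages <- function(n, V, t_kyr, slope, base = 1, seed = 1) {
  set.seed(seed)
  p <- (base + slope * t_kyr) / 2
  p <- pmin(pmax(p, 0.02), 0.98)
  matrix(stats::rbinom(n * V, 2L, rep(p, V)), n, V)
}
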