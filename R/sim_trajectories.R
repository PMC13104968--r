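#' Forward-simulate allele-frequency trajectories
#'
#' Wright-Fisher binomial resampling with additive selection, run
#' independently within each ancestral component. The expected
#' next-generation frequency is `p + s * p * (1 - p)` (first-order additive
#' selection on the alternate allele), followed by binomial sampling of
#' `2 * pop_size` gametes; frequencies absorb at 0 and 1. Neutral variants
#' have `s = 0`.
#'
#' @param config a [sim_config()].
#' @param deterministic if `TRUE`, skip binomial sampling (the infinite
#'   population-size limit): paths follow the selection recurrence exactly
#'   and drift is absent.
#' @return object of class `wf_trajectories`: list with `freq` (array of
#'   dim generations+1 x variants x components), `s` (per-variant selection
#'   coefficient on the alternate allele), `p0` (initial component
#'   frequencies), `deterministic`, and the `config`.
#' @export
simulate_trajectories <- function(config, deterministic = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pop_size < 10) stop("pop_size must be at least 10")
  if (config$generations < 2) stop("generations must be at least 2")
  set.seed(config$seed)

  V <- config$n_variants
  K <- config$n_ancestries
  G <- config$generations
  N2 <- 2 * config$pop_size

  p_base <- if (is.null(config$p0)) stats::runif(V, 0.05, 0.95)
            else rep_len(config$p0, V)
  f <- config$fst
  if (f > 0) {
    a <- p_base * (1 - f) / f
    b <- (1 - p_base) * (1 - f) / f
    p0 <- matrix(stats::rbeta(V * K, rep(a, K), rep(b, K)), V, K)
  } else {
    p0 <- matrix(p_base, V, K)
  }

  s <- numeric(V)
  n_sel <- round(config$frac_selected * V)
  if (n_sel > 0) {
    idx <- sample.int(V, n_sel)
    mag <- stats::runif(n_sel, min(config$s_range), max(config$s_range))
    s[idx] <- mag * sample(c(-1, 1), n_sel, replace = TRUE)
  }

  freq <- array(NA_real_, dim = c(G + 1L, V, K))
  freq[1L, , ] <- p0
  p <- p0
  for (g in seq_len(G)) {
    q <- p + s * p * (1 - p)
    q[q < 0] <- 0
    q[q > 1] <- 1
    if (!deterministic)
      q <- matrix(stats::rbinom(V * K, N2, q), V, K) / N2
    freq[g + 1L, , ] <- q
    p <- q
  }

  structure(list(freq = freq, s = s, p0 = p0,
                 deterministic = deterministic, config = config),
            class = "wf_trajectories")
}
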