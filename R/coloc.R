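# Enumeration-based colocalization and single-causal fine-mapping.

#' Wakefield log approximate Bayes factor
#'
#' For a Z-score with effect variance `v` (default `1/n`, the standardized
#' scale) and prior effect variance `w`,
#' `log ABF = 0.5 * log(1 - r) + r * z^2 / 2` with `r = w / (v + w)`.
#' Vectorized over `z` and `n`.
#'
#' @param z Z-score(s); must be finite.
#' @param n sample size(s) (used only through the default `v`).
#' @param w prior variance of the standardized effect (> 0 unless exactly
#'   0, the point-mass prior limit where the ABF is 1).
#' @param v variance of the effect estimate (> 0); default `1/n`.
#' @return log approximate Bayes factor(s) in favour of a nonzero effect.
#' @export
wakefield_abf <- function(z, n, w = 0.04, v = 1 / n) {
  if (any(!is.finite(z))) stop("z must be finite")
  if (any(v <= 0)) stop("v must be positive")
  if (any(w < 0)) stop("w must be non-negative")
  r <- w / (v + w)
  0.5 * log1p(-r) + r * z^2 / 2
}

#' Colocalization of two association tracks at a locus
#'
#' Exact enumeration of the five causal configurations under at most one
#' causal variant per track: H0 (no association), H1/H2 (one track only),
#' H3 (both, different variants), H4 (both, shared variant). Per-variant
#' Wakefield ABFs are combined in log space:
#' `H1 = p1 * sum_j ABF_a_j`, `H2 = p2 * sum_j ABF_b_j`,
#' `H3 = p1 * p2 * (sum_j ABF_a_j * sum_k ABF_b_k - sum_j ABF_a_j ABF_b_j)`,
#' `H4 = p12 * sum_j ABF_a_j * ABF_b_j`, normalized against H0 = 1.
#' The per-variant posterior of being the shared causal variant
#' (conditional on H4) is the softmax of `logABF_a + logABF_b`.
#'
#' @param locus data frame with aligned per-variant columns `pos`, `z_a`,
#'   `z_b`, `n_a`, `n_b` (optionally `v_a`, `v_b` overriding `1/n`);
#'   at least 2 variants, both tracks in the same order.
#' @param p1,p2,p12 prior probabilities that a variant is causal for track
#'   a only, track b only, or both.
#' @param w_a,w_b prior effect variances per track.
#' @return object of class `coloc_result`: `pp` (named PP_H0..PP_H4),
#'   `h4_posterior` (per-variant, sums to 1), `log_bf` (per-hypothesis log
#'   Bayes factors vs H0), `labf_a`, `labf_b`, `priors`, `pos`.
#' @export
coloc_abf <- function(locus, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      w_a = 0.04, w_b = 0.04) {
  if (nrow(locus) < 2L) stop("a locus needs at least 2 variants")
  v_a <- if ("v_a" %in% names(locus)) locus$v_a else 1 / locus$n_a
  v_b <- if ("v_b" %in% names(locus)) locus$v_b else 1 / locus$n_b
  la <- wakefield_abf(locus$z_a, v = v_a, w = w_a)
  lb <- wakefield_abf(locus$z_b, v = v_b, w = w_b)

  lsum_a <- logsumexp(la)
  lsum_b <- logsumexp(lb)
  lsum_ab <- logsumexp(la + lb)

  lH0 <- 0
  lH1 <- log(p1) + lsum_a
  lH2 <- log(p2) + lsum_b
  lH4 <- log(p12) + lsum_ab
  # H3 sums ABF_a_j * ABF_b_k over j != k. Writing it as
  # sum_a * sum_b - sum_ab cancels catastrophically when one variant
  # dominates both tracks, so instead sum la_j + log(sum_{k != j} ABF_b_k)
  # with the dominant variant's complement formed by explicit summation.
  jmax <- which.max(lb)
  lcomp_b <- vapply(seq_along(lb), function(j) {
    if (j == jmax) logsumexp(lb[-j]) else logdiffexp(lsum_b, lb[j])
  }, 0)
  lH3 <- log(p1) + log(p2) + logsumexp(la + lcomp_b)
  lbf <- c(H0 = lH0, H1 = lH1, H2 = lH2, H3 = lH3, H4 = lH4)
  denom <- logsumexp(lbf)
  pp <- exp(lbf - denom)
  names(pp) <- paste0("PP_", names(lbf))

  h4 <- exp(la + lb - lsum_ab)
  structure(list(pp = pp, h4_posterior = h4, log_bf = lbf,
                 labf_a = la, labf_b = lb,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 pos = locus$pos),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("colocalization posterior probabilities:\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Single-causal-variant fine-mapping with a 95% credible set
#'
#' Posterior inclusion probabilities are normalized Wakefield ABFs under a
#' uniform causal prior (exactly one causal variant). The credible set is
#' the minimal prefix of variants in descending-PIP order (ties broken by
#' ascending position) whose cumulative PIP reaches `coverage`.
#'
#' @param locus data frame with columns `pos`, `z` and `n` (or `v`).
#' @param w prior effect variance.
#' @param coverage credible-set coverage (default 0.95).
#' @return object of class `finemap_result`: `pip` (data frame pos, pip,
#'   in_credible_set), `credible_set` (positions), `cs_size`.
#' @export
finemap_single <- function(locus, w = 0.04, coverage = 0.95) {
  if (nrow(locus) < 2L) stop("a locus needs at least 2 variants")
  v <- if ("v" %in% names(locus)) locus$v else 1 / locus$n
  labf <- wakefield_abf(locus$z, v = v, w = w)
  pip <- exp(labf - logsumexp(labf))
  ord <- order(-pip, locus$pos)
  cum <- cumsum(pip[ord])
  cs_size <- which(cum >= coverage)[1L]
  if (is.na(cs_size)) cs_size <- length(pip)
  in_cs <- logical(length(pip))
  in_cs[ord[seq_len(cs_size)]] <- TRUE
  structure(list(pip = data.frame(pos = locus$pos, pip = pip,
                                  in_credible_set = in_cs),
                 credible_set = locus$pos[ord[seq_len(cs_size)]],
                 cs_size = cs_size),
            class = "finemap_result")
}

#' Joint shared-causal-variant posterior
#'
#' Combines a colocalization result into per-variant posteriors: `PIP_S`
#' and `PIP_G` are the single-causal fine-mapping posteriors of each track
#' alone; `PIP_SG` is the per-variant shared-causal posterior conditional
#' on colocalization multiplied by PP_H4 (the unconditional probability
#' that the variant is the shared causal one).
#'
#' @param coloc a [coloc_abf()] result.
#' @return data frame pos, PIP_S, PIP_G, PIP_SG.
#' @export
joint_pip <- function(coloc) {
  stopifnot(inherits(coloc, "coloc_result"))
  data.frame(
    pos = coloc$pos,
    PIP_S = exp(coloc$labf_a - logsumexp(coloc$labf_a)),
    PIP_G = exp(coloc$labf_b - logsumexp(coloc$labf_b)),
    PIP_SG = coloc$h4_posterior * coloc$pp[["PP_H4"]]
  )
}

#' Define loci around selection signals
#'
#' Seeds are variants with `|Z| >= z_threshold`; each seed opens a window
#' of `window_kb` kilobases on each side, and windows on the same
#' chromosome closer than `merge_kb` are merged. Intervals are 1-based
#' inclusive.
#'
#' @param sumstats position-sorted summary statistics (CHR, POS, Z).
#' @param z_threshold absolute-Z seed threshold.
#' @param window_kb half-window around each seed, kb.
#' @param merge_kb merge windows separated by less than this, kb.
#' @return data frame chrom, start, end, n_seeds (empty if no seed).
#' @export
define_loci <- function(sumstats, z_threshold = 4, window_kb = 250,
                        merge_kb = 250) {
  seeds <- sumstats[abs(sumstats$Z) >= z_threshold, c("CHR", "POS")]
  if (nrow(seeds) == 0L)
    return(data.frame(chrom = integer(0), start = numeric(0),
                      end = numeric(0), n_seeds = integer(0)))
  out <- list()
  for (ch in unique(seeds$CHR)) {
    pos <- sort(seeds$POS[seeds$CHR == ch])
    start <- pmax(1, pos - window_kb * 1000)
    end <- pos + window_kb * 1000
    cur_s <- start[1L]; cur_e <- end[1L]; cur_n <- 1L
    for (i in seq_along(pos)[-1L]) {
      if (start[i] - cur_e < merge_kb * 1000) {
        cur_e <- max(cur_e, end[i]); cur_n <- cur_n + 1L
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                              end = cur_e, n_seeds = cur_n)
        cur_s <- start[i]; cur_e <- end[i]; cur_n <- 1L
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                          end = cur_e, n_seeds = cur_n)
  }
  do.call(rbind, out)
}
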