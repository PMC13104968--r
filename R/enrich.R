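# Hypergeometric pathway enrichment, BH FDR, and the size-adjusted
# permutation test of immune-label excess among enriched pathways.

#' Hypergeometric enrichment of a prioritized gene set across pathways
#'
#' Each pathway is intersected with the caller's gene universe before
#' testing (the universe is the set of genes that could have entered the
#' prioritized set, never the whole genome). The upper-tail hypergeometric
#' p is the probability of an overlap at least as large as observed when
#' `n` genes are drawn from the universe without replacement; the odds
#' ratio comes from the 2x2 membership table with Haldane's 0.5 correction
#' when any cell is zero; q-values are Benjamini-Hochberg across all
#' tested pathways.
#'
#' @param prioritized character vector of prioritized genes (must be a
#'   subset of `universe`).
#' @param collection a `gene_set_collection`.
#' @param universe character vector of testable genes.
#' @return data frame: pathway, k (overlap), K (pathway size in universe),
#'   n (prioritized size), N (universe size), odds_ratio, p, q, immune.
#' @export
hypergeom_enrich <- function(prioritized, collection, universe) {
  universe <- unique(universe)
  prioritized <- unique(prioritized)
  if (length(universe) == 0L) stop("empty universe")
  if (length(prioritized) == 0L) stop("empty prioritized set")
  if (!all(prioritized %in% universe))
    stop("prioritized genes must be a subset of the universe")

  N <- length(universe)
  n <- length(prioritized)
  rows <- lapply(collection, function(p) {
    P <- intersect(p$genes, universe)
    K <- length(P)
    k <- length(intersect(P, prioritized))
    pval <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = p$id, k = k, K = K, n = n, N = N,
               odds_ratio = haldane_or(k, n - k, K - k, N - K - (n - k)),
               p = pval, immune = isTRUE(p$immune),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[, c("pathway", "k", "K", "n", "N", "odds_ratio", "p", "q", "immune")]
}

haldane_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Benjamini-Hochberg q-values
#'
#' Validated step-up BH adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in [0, 1]; must be finite.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p))) stop("p-values must be finite")
  assert_prob(p, "p")
  stats::p.adjust(p, method = "BH")
}

#' Odds ratio of a 2x2 table
#'
#' `(a/b) / (c/d)` with Haldane's 0.5 correction when any single cell is
#' zero; plain arithmetic otherwise (exact in double precision for integer
#' counts). Errors when two zero cells share a margin, where the odds
#' ratio is undefined.
#'
#' @param table 2x2 matrix (rows = outcome, columns = group) or length-4
#'   vector `c(a, b, c, d)` read row-wise.
#' @return the odds ratio.
#' @export
overlap_odds_ratio <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L || any(x < 0)) stop("need a 2x2 table of counts")
  a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop("odds ratio undefined: a margin of the table is zero")
  haldane_or(a, b, c, d)
}

#' Permutation test of immune-label excess among enriched pathways
#'
#' Fits a logistic regression of the enriched indicator (q below
#' `q_threshold`) on the immune flag plus log pathway size, reporting the
#' immune odds ratio. Significance comes from a permutation null that
#' re-draws the prioritized gene set uniformly from the universe (same
#' size) and reruns the enrichment and the regression; resampling the
#' gene set, rather than the labels, preserves the redundancy of gene
#' content across pathways under the null.
#'
#' @param results output of [hypergeom_enrich()] (carries q and immune).
#' @param collection the pathway collection used for `results`.
#' @param universe the gene universe used for `results`.
#' @param B permutation draws.
#' @param seed integer seed.
#' @param q_threshold FDR threshold defining "enriched" (default 0.10).
#' @return object of class `label_assoc_result`: `odds_ratio`, `p`
#'   (= (1 + #\{OR_null >= OR_obs\}) / (1 + B)), `B`, `flagged` (TRUE when
#'   the regression was degenerate/separated and the odds ratio fell back
#'   to the Haldane 2x2 estimate).
#' @export
immune_label_test <- function(results, collection, universe, B = 199L,
                              seed = NULL, q_threshold = 0.10) {
  if (!is.null(seed)) set.seed(seed)
  immune <- results$immune
  if (length(unique(immune)) < 2L || min(table(immune)) < 2L) {
    return(structure(list(odds_ratio = NA_real_, p = NA_real_, B = B,
                          flagged = TRUE,
                          reason = "need >= 2 pathways per label"),
                     class = "label_assoc_result"))
  }
  universe <- unique(universe)
  N <- length(universe)
  n <- results$n[1L]
  logK <- log(pmax(results$K, 1L))

  fit1 <- function(enriched) {
    or2 <- haldane_or(sum(enriched & immune), sum(!enriched & immune),
                      sum(enriched & !immune), sum(!enriched & !immune))
    if (length(unique(enriched)) < 2L) return(c(or2, 1))
    fit <- suppressWarnings(
      stats::glm(enriched ~ immune + logK, family = stats::binomial()))
    co <- stats::coef(fit)["immuneTRUE"]
    if (!fit$converged || is.na(co) || abs(co) > 15)
      c(or2, 1) else c(exp(unname(co)), 0)
  }

  obs <- fit1(results$q < q_threshold)
  or_obs <- obs[1L]; flagged <- obs[2L] == 1

  # pathway x universe incidence for fast permutation overlaps
  G <- vapply(collection, function(p) universe %in% p$genes,
              logical(N))                       # N x n_pathways
  K <- results$K
  or_null <- numeric(B)
  for (b in seq_len(B)) {
    draw <- logical(N)
    draw[sample.int(N, n)] <- TRUE
    k <- as.integer(colSums(G & draw))
    pv <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    or_null[b] <- fit1(bh_fdr(pv) < q_threshold)[1L]
  }
  p <- (1 + sum(or_null >= or_obs)) / (1 + B)
  structure(list(odds_ratio = or_obs, p = p, B = B, flagged = flagged),
            class = "label_assoc_result")
}

#' @export
print.label_assoc_result <- function(x, ...) {
  cat(sprintf("immune-label excess: OR = %.3f, permutation p = %.4g (B = %d)%s\n",
              x$odds_ratio, x$p, x$B,
              if (isTRUE(x$flagged)) " [degenerate fit: 2x2 fallback]" else ""))
  invisible(x)
}
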