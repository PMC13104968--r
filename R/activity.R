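# Signed pathway-activity inference from selection-pQTL genetic covariance.

#' Per-gene selection-pQTL genetic covariance
#'
#' Harmonizes the gene's pQTL track against the selection track, keeps
#' qualifying variants with `|Z| > z_min` on BOTH tracks, and averages the
#' per-variant products of standardized effects
#' `(Z_sel / sqrt(N_sel)) * (Z_pqtl / sqrt(N_pqtl))`. Variant positions
#' and contributions are retained for block jackknifing upstream.
#'
#' @param selection selection summary statistics (CHR, POS, A1, A2, Z, N).
#' @param pqtl one gene's pQTL summary statistics, same columns.
#' @param z_min qualifying-variant threshold on |Z| (default 3).
#' @return object of class `gene_covariance`: `covariance` (NA when no
#'   variant qualifies), `n_qualifying`, `pos`, `contrib`, `qualified`.
#' @export
gene_covariance <- function(selection, pqtl, z_min = 3) {
  h <- harmonize_sumstats(selection, pqtl)
  qual <- abs(h$a$Z) > z_min & abs(h$b$Z) > z_min
  if (!any(qual)) {
    return(structure(list(covariance = NA_real_, n_qualifying = 0L,
                          pos = numeric(0), contrib = numeric(0),
                          qualified = FALSE),
                     class = "gene_covariance"))
  }
  a <- h$a[qual, ]; b <- h$b[qual, ]
  contrib <- (a$Z / sqrt(a$N)) * (b$Z / sqrt(b$N))
  ord <- order(a$CHR, a$POS)
  structure(list(covariance = mean(contrib),
                 n_qualifying = sum(qual),
                 pos = a$POS[ord], contrib = contrib[ord],
                 qualified = TRUE),
            class = "gene_covariance")
}

#' Signed pathway-activity statistic with block jackknife
#'
#' The pathway statistic is the mean over regulator genes of
#' `sign_g x covariance_g`, where `sign_g` is +1 for positive regulators
#' and -1 for negative regulators, so a positive statistic always means
#' the adaptive alleles increase the process's activity. The genome-
#' ordered union of qualifying variants across the pathway's genes is cut
#' into `n_blocks` approximately equal contiguous blocks (shared across
#' genes, so co-regulation covariance is respected); a gene is dropped
#' when removing any single block would empty its qualifying set, and the
#' drop is iterated to a fixed point so re-running on the retained genes
#' drops nothing further. Leave-one-block-out recomputation gives the
#' jackknife SE, Z and two-tailed p.
#'
#' @param selection selection summary statistics.
#' @param pqtl_tables named list of per-gene pQTL summary statistics.
#' @param pathway signed pathway: list with `id`, named `signs` (+1/-1
#'   per gene) and optional `immune` flag (see [signed_pathways()]).
#' @param n_blocks jackknife blocks over the qualifying-variant union.
#' @param z_min qualifying threshold passed to [gene_covariance()].
#' @param gene_filter optional character vector of gene ids allowed into
#'   the pathway (e.g. genes passing a selection-pQTL colocalization
#'   gate); `NULL` admits all.
#' @param gene_covs optional named list of precomputed [gene_covariance()]
#'   results (avoids recomputation when many pathways share genes).
#' @return object of class `activity_result`: `pathway`, `statistic`,
#'   `se`, `z`, `p`, `direction` ("increased" iff statistic > 0),
#'   `n_genes`, `genes_used`, `dropped` (named reasons), `immune`,
#'   `n_blocks`.
#' @export
pathway_activity <- function(selection, pqtl_tables, pathway,
                             n_blocks = 200L, z_min = 3,
                             gene_filter = NULL, gene_covs = NULL) {
  signs <- pathway$signs
  if (is.null(signs) || length(signs) < 1L || !all(signs %in% c(-1, 1)))
    stop("pathway must carry named regulator signs in {-1, +1}")
  dropped <- character(0)

  if (!is.null(gene_filter)) {
    out <- setdiff(names(signs), gene_filter)
    dropped[out] <- "failed gene filter"
    signs <- signs[setdiff(names(signs), out)]
  }
  missing_tab <- setdiff(names(signs), names(pqtl_tables))
  dropped[missing_tab] <- "no pQTL table"
  signs <- signs[setdiff(names(signs), missing_tab)]

  covs <- lapply(names(signs), function(g) {
    if (!is.null(gene_covs) && g %in% names(gene_covs)) gene_covs[[g]]
    else gene_covariance(selection, pqtl_tables[[g]], z_min = z_min)
  })
  names(covs) <- names(signs)
  unqual <- names(signs)[!vapply(covs, `[[`, TRUE, "qualified")]
  dropped[unqual] <- "no qualifying variants"
  signs <- signs[setdiff(names(signs), unqual)]

  # Iterated drop rule: blocks are recut on the retained genes' variant
  # union until no gene's qualifying set is confined to a single block.
  repeat {
    if (length(signs) == 0L)
      stop("all genes dropped: ",
           paste(sprintf("%s (%s)", names(dropped), dropped), collapse = "; "))
    union_pos <- sort(unique(unlist(lapply(covs[names(signs)], `[[`, "pos"))))
    k <- min(n_blocks, length(union_pos))
    blk_of_pos <- contiguous_blocks(length(union_pos), k)
    gene_blocks <- lapply(covs[names(signs)], function(gc)
      blk_of_pos[match(gc$pos, union_pos)])
    single <- vapply(gene_blocks, function(b) length(unique(b)) < 2L, TRUE)
    if (!any(single)) break
    dropped[names(signs)[single]] <- "qualifying variants in a single block"
    signs <- signs[!single]
  }

  genes <- names(signs)
  stat_full <- mean(vapply(genes, function(g)
    signs[[g]] * covs[[g]]$covariance, 0))

  # per-gene per-block sums for fast leave-one-out means
  loo_stat <- vapply(seq_len(k), function(b) {
    mean(vapply(genes, function(g) {
      inb <- gene_blocks[[g]] == b
      signs[[g]] * mean(covs[[g]]$contrib[!inb])
    }, 0))
  }, 0)
  se <- jackknife_se(loo_stat)
  z <- stat_full / se
  structure(list(pathway = pathway$id, statistic = stat_full, se = se,
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 direction = if (stat_full > 0) "increased" else "decreased",
                 n_genes = length(genes), genes_used = genes,
                 dropped = dropped, immune = isTRUE(pathway$immune),
                 n_blocks = k),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("%s: activity %s (stat %.3g, SE %.3g, Z = %.2f, p = %.3g; %d genes, %d blocks)\n",
              x$pathway, x$direction, x$statistic, x$se, x$z, x$p,
              x$n_genes, x$n_blocks))
  invisible(x)
}

#' Score a list of signed pathways and attach BH q-values
#'
#' Runs [pathway_activity()] over a list of signed pathways, collects the
#' per-pathway statistics into a table, and adds Benjamini-Hochberg
#' q-values across the analyzed pathways. Pathways whose genes all drop
#' are skipped with a warning.
#'
#' @inheritParams pathway_activity
#' @param pathways list of signed pathways (see [signed_pathways()]).
#' @return data frame: pathway, statistic, se, z, p, q, direction,
#'   n_genes, immune.
#' @export
score_pathways <- function(selection, pqtl_tables, pathways,
                           n_blocks = 200L, z_min = 3,
                           gene_filter = NULL) {
  all_genes <- unique(unlist(lapply(pathways, function(p) names(p$signs))))
  all_genes <- intersect(all_genes, names(pqtl_tables))
  gene_covs <- lapply(all_genes, function(g)
    gene_covariance(selection, pqtl_tables[[g]], z_min = z_min))
  names(gene_covs) <- all_genes
  rows <- list()
  for (p in pathways) {
    res <- tryCatch(
      pathway_activity(selection, pqtl_tables, p, n_blocks = n_blocks,
                       z_min = z_min, gene_filter = gene_filter,
                       gene_covs = gene_covs),
      error = function(e) {
        warning("skipping ", p$id, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = res$pathway, statistic = res$statistic, se = res$se,
      z = res$z, p = res$p, direction = res$direction,
      n_genes = res$n_genes, immune = res$immune,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no pathway could be scored")
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Activation summary: direction-by-immune counts and odds ratio
#'
#' Among pathways significant at `q_threshold`, tabulates inferred
#' direction (increased/decreased) against the immune label, computes the
#' odds ratio for immune processes being called "increased" via
#' [overlap_odds_ratio()], and attaches a one-tailed permutation p-value
#' obtained by shuffling the immune flags.
#'
#' @param results data frame from [score_pathways()] (needs `direction`,
#'   `q`, `immune`).
#' @param q_threshold FDR threshold (default 0.10).
#' @param B label-shuffle draws.
#' @param seed integer seed.
#' @return object of class `activation_summary`: `table` (2x2 counts:
#'   rows increased/decreased, cols immune/non-immune), `odds_ratio` (NA
#'   with `flagged = TRUE` when a margin is zero), `p_permutation`,
#'   `n_significant`.
#' @export
activation_summary <- function(results, q_threshold = 0.10, B = 999L,
                               seed = NULL) {
  if (!"q" %in% names(results)) stop("results must carry q-values")
  if (!is.null(seed)) set.seed(seed)
  sig <- results[results$q < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(structure(list(table = matrix(0L, 2, 2), odds_ratio = NA_real_,
                          p_permutation = NA_real_, n_significant = 0L,
                          flagged = TRUE),
                     class = "activation_summary"))
  }
  inc <- sig$direction == "increased"
  imm <- sig$immune
  tab <- matrix(c(sum(inc & imm), sum(!inc & imm),
                  sum(inc & !imm), sum(!inc & !imm)),
                2, 2, dimnames = list(c("increased", "decreased"),
                                      c("immune", "non_immune")))
  or <- tryCatch(overlap_odds_ratio(c(tab[1, 1], tab[2, 1],
                                      tab[1, 2], tab[2, 2])),
                 error = function(e) NA_real_)
  p_perm <- NA_real_
  if (is.finite(or)) {
    or_null <- vapply(seq_len(B), function(b) {
      sh <- sample(imm)
      tryCatch(overlap_odds_ratio(c(sum(inc & sh), sum(!inc & sh),
                                    sum(inc & !sh), sum(!inc & !sh))),
               error = function(e) NA_real_)
    }, 0)
    p_perm <- (1 + sum(or_null >= or, na.rm = TRUE)) / (1 + B)
  }
  structure(list(table = tab, odds_ratio = or, p_permutation = p_perm,
                 n_significant = nrow(sig), flagged = !is.finite(or)),
            class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat(sprintf("activation summary over %d significant pathways:\n",
              x$n_significant))
  print(x$table)
  cat(sprintf("immune-increased odds ratio: %.4g (permutation p = %.4g)%s\n",
              x$odds_ratio, x$p_permutation,
              if (isTRUE(x$flagged)) " [undefined on a zero margin]" else ""))
  invisible(x)
}
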