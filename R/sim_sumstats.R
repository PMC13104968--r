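# Generators for summary-statistic tracks with block LD structure.
#
# Marginal Z-scores are produced by LD-propagating standardized causal
# effects: within a block with exchangeable correlation matrix R,
#   Z = sqrt(N) * R %*% beta + chol-correlated N(0, R) noise,
# so that E[Z_j^2] = 1 + N * l_j * h2 / M and, for two tracks with causal
# effect covariance rho/M, E[Z_a Z_b] = sqrt(N_a N_b) * l_j * rho / M --
# exactly the relationships the LD-score regressions estimate.

# R %*% b for exchangeable R_b = (1-r_b) I + r_b 11': closed form per block.
exch_mult <- function(b, block_r, block) {
  sums <- tapply(b, block, sum)
  rj <- block_r[block]
  (1 - rj) * b + rj * as.numeric(sums[block])
}

# Correlated N(0, R_b) noise, block-diagonal exchangeable R_b; one chol per
# distinct within-block correlation.
exch_noise <- function(block_r, m) {
  z <- matrix(stats::rnorm(length(block_r) * m), nrow = m)
  for (r in unique(block_r)) {
    cols <- which(block_r == r)
    R <- matrix(r, m, m); diag(R) <- 1
    z[, cols] <- t(chol(R)) %*% z[, cols, drop = FALSE]
  }
  as.vector(z)
}

propagate_z <- function(ld, beta, n, noise = TRUE) {
  blk <- ld$variants$block_id
  z <- sqrt(n) * exch_mult(beta, ld$block_r, blk)
  if (noise) z <- z + exch_noise(ld$block_r, ld$block_size)
  z
}

sumstats_frame <- function(ld, z, n) {
  data.frame(CHR = ld$variants$chrom, POS = ld$variants$pos,
             A1 = "G", A2 = "A", Z = z, N = n)
}

#' Draw a standardized selection-effect truth table
#'
#' Creates a truth table on an LD reference's variant map with a
#' per-variant standardized selection effect: causal variants (a fraction
#' `frac_selected`) draw effects N(0, h2_sel / (M * frac_selected)), so the
#' effects sum in expectation to `h2_sel` on the standardized scale. This
#' is the dense polygenic counterpart of the sparse Wright-Fisher truth
#' table and feeds the coupled summary-statistic generators.
#'
#' @param ld an [make_ld_reference()] object.
#' @param h2_sel total standardized selection signal.
#' @param frac_selected fraction of causal variants.
#' @param seed integer seed.
#' @return data frame chrom, pos, ref, alt, block_id, sel_effect with
#'   attribute `h2_sel`.
#' @export
simulate_truth_effects <- function(ld, h2_sel = 0.5, frac_selected = 1,
                                   seed = 1L) {
  set.seed(seed)
  M <- ld$M
  causal <- stats::runif(M) < frac_selected
  eff <- numeric(M)
  eff[causal] <- stats::rnorm(sum(causal),
                              sd = sqrt(h2_sel / (M * frac_selected)))
  truth <- data.frame(chrom = ld$variants$chrom, pos = ld$variants$pos,
                      ref = "A", alt = "G",
                      block_id = ld$variants$block_id, sel_effect = eff)
  attr(truth, "h2_sel") <- h2_sel
  truth
}

#' Simulate a selection summary-statistic track from a truth table
#'
#' LD-propagates the truth table's standardized selection effects to
#' marginal Z-scores at effective sample size `n_sel`.
#'
#' @param truth truth table carrying a `sel_effect` column.
#' @param ld matching LD reference.
#' @param n_sel effective sample size for the selection track.
#' @param seed integer seed.
#' @param noise include the sampling-noise component (disable for exact
#'   no-noise limit checks).
#' @return summary-statistic data frame (CHR, POS, A1, A2, Z, N).
#' @export
simulate_selection_zscores <- function(truth, ld, n_sel, seed = 1L,
                                       noise = TRUE) {
  set.seed(seed)
  sumstats_frame(ld, propagate_z(ld, truth$sel_effect, n_sel, noise), n_sel)
}

#' Simulate GWAS summary statistics genetically correlated with selection
#'
#' Draws standardized GWAS causal effects jointly with the truth table's
#' selection effects at correlation `rg_target`, then LD-propagates them to
#' marginal Z-scores. The selection effects are standardized by their
#' theoretical per-variant scale so the target correlation is exact in
#' expectation regardless of architecture sparsity.
#'
#' @param truth truth table with `sel_effect` and attribute `h2_sel`.
#' @param ld matching LD reference.
#' @param n_gwas GWAS sample size (> 1).
#' @param rg_target target genetic correlation with selection, in [-1, 1].
#' @param seed integer seed.
#' @param h2_gwas GWAS heritability on the standardized scale.
#' @param noise include the sampling-noise component.
#' @return summary-statistic data frame with attribute `true_beta`.
#' @export
simulate_gwas_sumstats <- function(truth, ld, n_gwas, rg_target, seed = 1L,
                                   h2_gwas = 0.5, noise = TRUE) {
  if (rg_target < -1 || rg_target > 1) stop("rg_target must lie in [-1, 1]")
  if (n_gwas <= 1) stop("n_gwas must exceed 1")
  set.seed(seed)
  M <- ld$M
  h2s <- attr(truth, "h2_sel")
  u <- if (!is.null(h2s) && h2s > 0) truth$sel_effect / sqrt(h2s / M)
       else if (stats::sd(truth$sel_effect) > 0)
         truth$sel_effect / stats::sd(truth$sel_effect)
       else numeric(M)
  beta <- sqrt(h2_gwas / M) *
    (rg_target * u + sqrt(1 - rg_target^2) * stats::rnorm(M))
  out <- sumstats_frame(ld, propagate_z(ld, beta, n_gwas, noise), n_gwas)
  attr(out, "true_beta") <- beta
  out
}

#' Tile a gene map over an LD reference
#'
#' Assigns `n_genes` non-overlapping cis windows of consecutive variants
#' along the simulated map (1-based inclusive coordinates).
#'
#' @param ld an LD reference.
#' @param n_genes number of genes to tile.
#' @param seed unused placeholder kept for generator-signature symmetry.
#' @return data frame gene_id, chrom, start, end.
#' @export
make_gene_map <- function(ld, n_genes, seed = 1L) {
  span <- ld$M %/% n_genes
  if (span < 1L) stop("more genes than variants")
  idx0 <- (seq_len(n_genes) - 1L) * span + 1L
  pos <- ld$variants$pos
  data.frame(gene_id = sprintf("GENE%03d", seq_len(n_genes)),
             chrom = ld$variants$chrom[1L],
             start = pos[idx0], end = pos[idx0 + span - 1L])
}

#' Simulate per-gene plasma pQTL summary-statistic tables
#'
#' Each gene's standardized genetic effect track is the sum of a
#' genome-wide component coupled to the selection effects (scaled by the
#' gene's signed `coupling`) and an independent cis component over the
#' gene's window; marginal Z-scores are LD-propagated at sample size
#' `n_pqtl`. Positive coupling makes variants that raise selection
#' statistics also raise the protein's level, which is what the signed
#' pathway-activity statistic detects. With `noise = FALSE` and
#' `h2_cis = 0` the track is exactly proportional to the coupling, so
#' flipping all coupling signs negates downstream covariance statistics
#' exactly.
#'
#' @param truth truth table with `sel_effect` and attribute `h2_sel`.
#' @param ld matching LD reference.
#' @param genes gene map from [make_gene_map()].
#' @param n_pqtl pQTL sample size.
#' @param coupling named numeric vector, gene_id -> signed coupling to the
#'   selection effects.
#' @param seed integer seed.
#' @param h2_cis standardized cis-effect scale per gene.
#' @param noise include the sampling-noise component.
#' @return named list of per-gene summary-statistic data frames.
#' @export
simulate_pqtl_tables <- function(truth, ld, genes, n_pqtl, coupling,
                                 seed = 1L, h2_cis = 0.2, noise = TRUE) {
  unknown <- setdiff(names(coupling), genes$gene_id)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  M <- ld$M
  pos <- ld$variants$pos
  out <- vector("list", length(coupling))
  names(out) <- names(coupling)
  for (g in names(coupling)) {
    row <- genes[genes$gene_id == g, ]
    cis <- which(pos >= row$start & pos <= row$end)
    beta <- coupling[[g]] * truth$sel_effect
    if (h2_cis > 0 && length(cis))
      beta[cis] <- beta[cis] +
        stats::rnorm(length(cis), sd = sqrt(h2_cis / length(cis)))
    out[[g]] <- sumstats_frame(ld, propagate_z(ld, beta, n_pqtl, noise),
                               n_pqtl)
  }
  out
}
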