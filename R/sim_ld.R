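#' Block-diagonal LD reference
#'
#' Builds an LD reference with exchangeable within-block genotype
#' correlation and no between-block correlation. Under that structure
#' each variant's LD score is analytic:
#' `l_j = 1 + (block_size - 1) * r_b^2` (sum of squared correlations with
#' variants in its block, including itself), which makes the LD-score
#' regression relationship exactly checkable. By default the correlation
#' varies across blocks (an even spread over [0.15, 0.85]) so LD scores
#' carry the variation the regressions need; a scalar `r` gives the
#' homogeneous special case used in closed-form checks.
#'
#' @param n_blocks number of LD blocks.
#' @param variants_per_block variants in each block.
#' @param r within-block correlation: `NULL` (default spread), a scalar,
#'   or a length-`n_blocks` vector; entries in [0, 1).
#' @param chrom chromosome label for the generated variants.
#' @param spacing base-pair spacing between adjacent variants.
#' @return object of class `ld_reference`: list with `variants` (data
#'   frame chrom, pos, block_id, r, ld_score), `M`, `block_r` and
#'   `block_size`.
#' @export
make_ld_reference <- function(n_blocks, variants_per_block, r = NULL,
                              chrom = 1L, spacing = 10000L) {
  n_blocks <- as.integer(n_blocks)
  if (is.null(r)) r <- seq(0.15, 0.85, length.out = n_blocks)
  block_r <- rep_len(r, n_blocks)
  if (any(block_r < 0 | block_r >= 1)) stop("`r` entries must lie in [0, 1)")
  m <- as.integer(variants_per_block)
  M <- n_blocks * m
  variants <- data.frame(
    chrom = chrom,
    pos = seq_len(M) * spacing,
    block_id = rep(seq_len(n_blocks), each = m),
    r = rep(block_r, each = m)
  )
  variants$ld_score <- 1 + (m - 1) * variants$r^2
  structure(list(variants = variants, M = M, block_r = block_r,
                 block_size = m),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("ld_reference: %d variants in %d blocks of %d (r in [%.2f, %.2f])\n",
              x$M, length(x$block_r), x$block_size,
              min(x$block_r), max(x$block_r)))
  invisible(x)
}
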