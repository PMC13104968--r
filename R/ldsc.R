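# LD-score regressions: heritability-scale parameters, cross-track genetic
# correlation, covariance-aware meta-analysis, and annotation partitioning.
#
# All standard errors are delete-one-block jackknives over contiguous
# variant blocks (shared block layout across traits so pseudovalues can be
# pooled by meta_gls).

# Weighted least squares with per-block leave-one-out coefficients.
# X: n x p design, y, w: weights, block: contiguous block ids.
wls_jackknife <- function(X, y, w, block) {
  p <- ncol(X)
  k <- max(block)
  Xw <- X * w
  A <- crossprod(Xw, X)                 # p x p
  bvec <- crossprod(Xw, y)              # p x 1
  coef <- solve(A, bvec)

  # per-block contributions
  Ab <- array(0, dim = c(k, p, p))
  bb <- matrix(0, k, p)
  for (i in seq_len(p)) {
    bb[, i] <- rowsum(Xw[, i] * y, block)[, 1L]
    for (j in i:p) {
      s <- rowsum(Xw[, i] * X[, j], block)[, 1L]
      Ab[, i, j] <- s
      Ab[, j, i] <- s
    }
  }
  loo <- matrix(NA_real_, k, p)
  for (b in seq_len(k)) {
    loo[b, ] <- tryCatch(
      solve(A - Ab[b, , ], bvec - bb[b, ]),
      error = function(e) rep(NA_real_, p)
    )
  }
  list(coef = as.numeric(coef), loo = loo, n_blocks = k)
}

# Floor a model-variance vector at a small positive value that scales
# with the data (keeps weights scale-consistent under Z -> cZ, N -> c^2 N).
floor_denom <- function(x) {
  m <- stats::median(abs(x))
  if (!is.finite(m) || m == 0) m <- 1
  pmax(x, 0.05 * m)
}

align_to_ld <- function(sumstats, ld) {
  key_s <- variant_key(sumstats$CHR, sumstats$POS)
  key_l <- variant_key(ld$variants$chrom, ld$variants$pos)
  idx <- match(key_s, key_l)
  if (anyNA(idx))
    stop("summary statistics contain variants absent from the LD reference")
  ord <- order(idx)
  list(sumstats = sumstats[ord, , drop = FALSE],
       ld_idx = idx[ord])
}

#' Heritability-scale parameter from summary statistics
#'
#' Regresses Z^2 on `N * l_j / M` with a free intercept. Weights follow
#' the standard two-step scheme: an unweighted pass supplies initial slope
#' and intercept estimates, then each variant is weighted by the inverse
#' of twice its squared model-implied variance. The slope is the
#' heritability-analog on the standardized scale; the free intercept
#' absorbs confounding inflation. Standard errors come from a
#' delete-one-block jackknife over `n_blocks` contiguous position blocks.
#'
#' @param sumstats data frame with CHR, POS, Z, N.
#' @param ld an [make_ld_reference()] (or compatible) LD reference; all
#'   LD scores must be positive.
#' @param n_blocks jackknife blocks (needs >= 10 variants per block).
#' @param weights optional fixed regression weights (overrides the
#'   two-step scheme; used for regression-algebra checks).
#' @return object of class `h2_result`: `h2`, `intercept`, `se`
#'   (jackknife), `loo` (leave-one-block-out h2 estimates), `n_blocks`,
#'   `weights`.
#' @export
estimate_h2 <- function(sumstats, ld, n_blocks = 200L, weights = NULL) {
  if (any(ld$variants$ld_score <= 0)) stop("LD scores must be positive")
  al <- align_to_ld(sumstats, ld)
  ss <- al$sumstats
  M <- ld$M
  ell <- ld$variants$ld_score[al$ld_idx]
  n <- nrow(ss)
  if (n < 10L * n_blocks)
    stop("need at least 10 variants per jackknife block; reduce n_blocks")

  x <- ss$N * ell / M
  y <- ss$Z^2
  X <- cbind(1, x)
  block <- contiguous_blocks(n, n_blocks)

  if (is.null(weights)) {
    f0 <- stats::lm.fit(X, y)$coefficients
    denom <- floor_denom(f0[1L] + pmax(f0[2L], 0) * x)
    weights <- 1 / (2 * denom^2)
  }
  fit <- wls_jackknife(X, y, weights, block)
  structure(list(h2 = fit$coef[2L], intercept = fit$coef[1L],
                 se = jackknife_se(fit$loo[, 2L]),
                 loo = fit$loo[, 2L], loo_intercept = fit$loo[, 1L],
                 n_blocks = fit$n_blocks, weights = weights),
            class = "h2_result")
}

#' Cross-track genetic correlation with block-jackknife SE
#'
#' Regresses `Z_a * Z_b` on `sqrt(N_a * N_b) * l_j / M` with a free
#' intercept (which absorbs sample overlap / shared confounding), giving
#' the genetic covariance `rho_g`; the two univariate fits supply the
#' heritability-analogs, and `rg = rho_g / sqrt(h2_a * h2_b)`. The
#' jackknife leaves out each contiguous block and recomputes the full
#' ratio; the leave-one-out series is retained for covariance-aware
#' meta-analysis across traits sharing the block layout. `rg` is reported
#' as `NA` when either heritability estimate is non-positive (a fabricated
#' correlation would be worse than a missing one).
#'
#' @param sumstats_a,sumstats_b harmonized summary statistics on the same
#'   variants, in the same order.
#' @param ld LD reference.
#' @param n_blocks jackknife blocks.
#' @return object of class `rg_result`: `rg`, `se_rg`, `rho_g`, `h2_a`,
#'   `h2_b`, intercepts, `loo_rg`, `loo_rho`, `n_blocks`.
#' @export
estimate_rg <- function(sumstats_a, sumstats_b, ld, n_blocks = 200L) {
  if (nrow(sumstats_a) != nrow(sumstats_b) ||
      !all(variant_key(sumstats_a$CHR, sumstats_a$POS) ==
           variant_key(sumstats_b$CHR, sumstats_b$POS)))
    stop("variant sets differ; harmonize the tables first")

  ha <- estimate_h2(sumstats_a, ld, n_blocks)
  hb <- estimate_h2(sumstats_b, ld, n_blocks)

  al <- align_to_ld(sumstats_a, ld)
  ss_a <- al$sumstats
  ss_b <- align_to_ld(sumstats_b, ld)$sumstats
  ell <- ld$variants$ld_score[al$ld_idx]
  M <- ld$M
  n <- nrow(ss_a)

  x <- sqrt(ss_a$N * ss_b$N) * ell / M
  y <- ss_a$Z * ss_b$Z
  X <- cbind(1, x)
  block <- contiguous_blocks(n, n_blocks)

  f0 <- stats::lm.fit(X, y)$coefficients
  xa <- ss_a$N * ell / M
  xb <- ss_b$N * ell / M
  va <- floor_denom(ha$intercept + pmax(ha$h2, 0) * xa)
  vb <- floor_denom(hb$intercept + pmax(hb$h2, 0) * xb)
  w <- 1 / (va * vb + (f0[1L] + f0[2L] * x)^2)

  fit <- wls_jackknife(X, y, w, block)
  rho <- fit$coef[2L]
  rg <- if (ha$h2 > 0 && hb$h2 > 0) rho / sqrt(ha$h2 * hb$h2) else NA_real_

  loo_rho <- fit$loo[, 2L]
  loo_rg <- ifelse(ha$loo > 0 & hb$loo > 0,
                   loo_rho / sqrt(ha$loo * hb$loo), NA_real_)
  structure(list(rg = rg, se_rg = jackknife_se(loo_rg), rho_g = rho,
                 h2_a = ha$h2, h2_b = hb$h2,
                 intercept_a = ha$intercept, intercept_b = hb$intercept,
                 intercept_ab = fit$coef[1L],
                 loo_rg = loo_rg, loo_rho = loo_rho,
                 n_blocks = fit$n_blocks),
            class = "rg_result")
}

#' @export
print.rg_result <- function(x, ...) {
  cat(sprintf("rg = %.4f (jackknife SE %.4f); rho_g = %.4g; h2 = %.4g / %.4g; %d blocks\n",
              x$rg, x$se_rg, x$rho_g, x$h2_a, x$h2_b, x$n_blocks))
  invisible(x)
}

#' Covariance-aware (GLS) meta-analysis of correlated estimates
#'
#' Pools estimates whose sampling covariance is computed from shared
#' jackknife pseudovalues: with `B` shared blocks and leave-one-out series
#' `theta_(-b)`, pseudovalues are `B * theta - (B - 1) * theta_(-b)` and
#' `Sigma = cov(pseudovalues) / B` across traits. The pooled estimate is
#' the GLS mean `(1' Sigma^-1 r) / (1' Sigma^-1 1)` with standard error
#' `(1' Sigma^-1 1)^(-1/2)`. `Sigma` is ridge-regularized by
#' `eps * trace(Sigma) / k` on the diagonal when its condition number
#' exceeds 1e6. With a diagonal `Sigma` this reduces exactly to
#' inverse-variance weighting.
#'
#' @param estimates numeric vector of per-trait estimates.
#' @param loo matrix of leave-one-block-out estimates (traits x blocks),
#'   all traits sharing the same block layout; required unless `Sigma`
#'   is supplied.
#' @param Sigma optional estimate covariance matrix (overrides `loo`).
#' @param eps ridge factor applied when needed.
#' @param alternative direction of the one-tailed Z-test (`"less"`,
#'   `"greater"`, or `"two.sided"`).
#' @return object of class `meta_result`: `estimate`, `se`, `z`, `p`,
#'   `condition_number`, `Sigma`, `alternative`.
#' @export
meta_gls <- function(estimates, loo = NULL, Sigma = NULL, eps = 1e-3,
                     alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  k <- length(estimates)
  if (is.null(Sigma)) {
    if (is.null(loo)) stop("supply either `loo` or `Sigma`")
    loo <- as.matrix(loo)
    if (nrow(loo) != k)
      stop("`loo` must have one row per estimate")
    if (anyNA(loo)) stop("leave-one-out series contain missing values")
    B <- ncol(loo)
    if (B < 2L) stop("inconsistent block counts: need >= 2 shared blocks")
    pseudo <- B * estimates - (B - 1) * loo          # k x B
    Sigma <- stats::cov(t(pseudo)) / B
  } else {
    Sigma <- as.matrix(Sigma)
    if (!all(dim(Sigma) == k)) stop("Sigma must be k x k")
  }
  cond <- kappa(Sigma, exact = TRUE)
  if (is.finite(cond) && cond > 1e6)
    Sigma <- Sigma + diag(eps * sum(diag(Sigma)) / k, k)
  Sinv1 <- solve(Sigma, rep(1, k))
  denom <- sum(Sinv1)
  est <- sum(Sinv1 * estimates) / denom
  se <- 1 / sqrt(denom)
  z <- est / se
  p <- switch(alternative,
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  structure(list(estimate = est, se = se, z = z, p = p,
                 condition_number = cond, Sigma = Sigma,
                 alternative = alternative),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("GLS meta-analysis: %.4g (SE %.4g), Z = %.3f, %s p = %.3g\n",
              x$estimate, x$se, x$z, x$alternative, x$p))
  invisible(x)
}

#' Partition signal between an annotation and its complement
#'
#' Stratified version of [estimate_h2()]: regresses Z^2 on two
#' annotation-specific LD-score columns (annotation and complement,
#' computed analytically from the block structure) with a free intercept.
#' Each slope is a per-variant signal density; the annotation's share of
#' total signal and its per-variant enrichment ratio (share of signal /
#' share of variants) are jackknifed over contiguous blocks.
#'
#' @param sumstats summary statistics (CHR, POS, Z, N).
#' @param ld LD reference (block-exchangeable).
#' @param annotation logical vector over the LD reference's variants, or a
#'   vector of annotated positions; must be non-empty and not all
#'   variants.
#' @param n_blocks jackknife blocks.
#' @return object of class `partition_result`: `proportion`, `se`
#'   (jackknife SE of the proportion), `enrichment`, `tau`
#'   (per-variant densities), `M_annotation`, `loo_proportion`.
#' @export
partition_signal <- function(sumstats, ld, annotation, n_blocks = 200L) {
  M <- ld$M
  if (!is.logical(annotation)) {
    annotation <- ld$variants$pos %in% annotation
  }
  if (length(annotation) != M)
    stop("annotation must cover the LD reference's variants")
  M_ann <- sum(annotation)
  if (M_ann == 0L || M_ann == M)
    stop("annotation must be non-empty and not all variants")

  al <- align_to_ld(sumstats, ld)
  ss <- al$sumstats
  idx <- al$ld_idx
  blk_ld <- ld$variants$block_id
  n_ann_blk <- tapply(annotation, blk_ld, sum)
  n_blk <- tabulate(blk_ld)
  ann_j <- annotation[idx]
  bid <- blk_ld[idx]
  r2 <- ld$block_r[bid]^2
  l_ann <- ann_j + r2 * (n_ann_blk[bid] - ann_j)
  l_comp <- (!ann_j) + r2 * ((n_blk[bid] - n_ann_blk[bid]) - !ann_j)
  l_ann <- as.numeric(l_ann); l_comp <- as.numeric(l_comp)

  X <- cbind(1, ss$N * l_ann, ss$N * l_comp)
  if (qr(X)$rank < 3L)
    stop("annotation LD scores are collinear with their complement; ",
         "the partition is not identifiable under this block structure")
  y <- ss$Z^2
  n <- nrow(ss)
  block <- contiguous_blocks(n, n_blocks)

  f0 <- stats::lm.fit(X, y)$coefficients
  denom <- floor_denom(f0[1L] + pmax(f0[2L], 0) * X[, 2L] +
                         pmax(f0[3L], 0) * X[, 3L])
  w <- 1 / (2 * denom^2)
  fit <- wls_jackknife(X, y, w, block)

  share <- function(cf) {
    h_ann <- cf[2L] * M_ann
    h_comp <- cf[3L] * (M - M_ann)
    h_ann / (h_ann + h_comp)
  }
  prop <- share(fit$coef)
  loo_prop <- apply(fit$loo, 1L, share)
  structure(list(proportion = prop,
                 se = jackknife_se(loo_prop),
                 enrichment = prop / (M_ann / M),
                 tau = fit$coef[2:3], intercept = fit$coef[1L],
                 M_annotation = M_ann, loo_proportion = loo_prop,
                 n_blocks = fit$n_blocks),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition: proportion = %.3f (SE %.3f), enrichment = %.2f (M_ann = %d)\n",
              x$proportion, x$se, x$enrichment, x$M_annotation))
  invisible(x)
}
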