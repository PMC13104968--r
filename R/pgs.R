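#' Per-individual polygenic scores in a dated cohort
#'
#' Matches the weight table to the cohort's variants by chromosome and
#' position, orienting each weight to the cohort's counted (alt) allele,
#' then computes for each individual the weighted dosage sum over
#' non-missing matched variants divided by that individual's non-missing
#' count. The per-individual normalization prevents date-correlated
#' missingness from masquerading as a temporal trend. Pseudo-haploid
#' dosages enter as-is.
#'
#' @param cohort an [ancient_cohort()].
#' @param weights data frame with CHR, POS, A1 (effect allele) and BETA.
#' @return numeric vector of scores, one per individual (NA where an
#'   individual has no non-missing matched variant).
#' @export
compute_pgs <- function(cohort, weights) {
  m <- match_weights(cohort, weights)
  D <- cohort$dosage[, m$col, drop = FALSE]
  obs <- !is.na(D)
  D[!obs] <- 0
  num <- as.vector(D %*% m$beta)
  den <- rowSums(obs)
  ifelse(den > 0, num / den, NA_real_)
}

match_weights <- function(cohort, weights) {
  if (anyDuplicated(variant_key(weights$CHR, weights$POS)))
    stop("duplicate variant keys in the weight table")
  key_c <- variant_key(cohort$variants$chrom, cohort$variants$pos)
  key_w <- variant_key(weights$CHR, weights$POS)
  iw <- match(key_c, key_w)
  col <- which(!is.na(iw))
  iw <- iw[col]
  a1 <- toupper(weights$A1[iw])
  alt <- toupper(cohort$variants$alt[col])
  ref <- toupper(cohort$variants$ref[col])
  sign <- ifelse(a1 == alt, 1, ifelse(a1 == ref, -1, NA))
  ok <- !is.na(sign)
  col <- col[ok]
  if (!length(col)) stop("no overlapping variants between weights and cohort")
  list(col = col, beta = weights$BETA[iw][ok] * sign[ok])
}

#' Polygenic-score trajectory test
#'
#' Estimates the slope of per-individual polygenic scores on analysis time
#' `t = -date_bp / 1000` with ancestry covariates (the trajectory
#' statistic: PGS units per 1,000 years toward the present), and calibrates
#' it against an empirical null built by random sign-flips of the
#' per-variant weights, drawn within minor-allele-frequency quintiles so
#' the flip scheme respects the weights' frequency profile. The flips
#' destroy any coupling between weight signs and frequency trends while
#' preserving the cohort's drift/structure covariance.
#'
#' Because both the scores and the fitted slope are linear in the weights,
#' each permuted slope is an exact inner product and the null costs almost
#' nothing beyond the observed fit.
#'
#' @param cohort an [ancient_cohort()].
#' @param weights data frame with CHR, POS, A1, BETA.
#' @param B number of sign-flip draws (>= 100).
#' @param seed integer seed for the flips.
#' @param covariates as in [scan_config()]: `"ancestry"`, `"none"`, or a
#'   matrix.
#' @return object of class `trajectory_result`: `gamma_sign`,
#'   `se_analytic`, `p_empirical` = (1 + #\{|gamma_null| >= |gamma_obs|\}) /
#'   (1 + B), `B`, `scores`, `n_variants`.
#' @export
gamma_test <- function(cohort, weights, B = 999L, seed = NULL,
                       covariates = "ancestry") {
  if (B < 100L) stop("B must be at least 100")
  if (length(unique(cohort$date_bp)) < 3L)
    stop("need at least 3 distinct dates")
  if (!is.null(seed)) set.seed(seed)

  m <- match_weights(cohort, weights)
  D <- cohort$dosage[, m$col, drop = FALSE]
  obs <- !is.na(D)
  D[!obs] <- 0
  den <- rowSums(obs)
  den[den == 0] <- NA
  Mnorm <- D / den            # scores are Mnorm %*% beta

  t_kyr <- -cohort$date_bp / 1000
  C <- scan_covariates(cohort, covariates)
  X <- cbind(1, t_kyr, C)
  usable <- is.finite(den)
  Xu <- X[usable, , drop = FALSE]
  Mu <- Mnorm[usable, , drop = FALSE]
  # slope extractor: row of (X'X)^-1 X' for the time coefficient
  a <- solve(crossprod(Xu), t(Xu))[2L, ]
  contrib <- as.vector(crossprod(Mu, a))   # per-variant slope contribution
  gamma_obs <- sum(m$beta * contrib)

  scores <- as.vector(Mnorm %*% m$beta)
  fit <- stats::lm.fit(Xu, scores[usable])
  rss <- sum(fit$residuals^2)
  df <- sum(usable) - ncol(Xu)
  XtXinv <- chol2inv(fit$qr$qr[seq_len(ncol(Xu)), , drop = FALSE])
  se_analytic <- sqrt(rss / df * XtXinv[2L, 2L])

  # maf-quintile grouping of the flip draws
  maf_v <- pmin(colMeans(cohort$dosage[, m$col, drop = FALSE],
                         na.rm = TRUE) / 2,
                1 - colMeans(cohort$dosage[, m$col, drop = FALSE],
                             na.rm = TRUE) / 2)
  q <- cut(rank(maf_v, ties.method = "first"), breaks = 5L, labels = FALSE)
  nv <- length(contrib)
  gamma_null <- numeric(B)
  bc <- m$beta * contrib
  for (g in sort(unique(q))) {
    idx <- which(q == g)
    S <- matrix(sample(c(-1, 1), length(idx) * B, replace = TRUE),
                nrow = length(idx))
    gamma_null <- gamma_null + as.vector(crossprod(S, bc[idx]))
  }
  p_emp <- (1 + sum(abs(gamma_null) >= abs(gamma_obs))) / (1 + B)

  structure(list(gamma_sign = gamma_obs, se_analytic = se_analytic,
                 p_empirical = p_emp, B = B, scores = scores,
                 n_variants = nv),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("trajectory test: gamma_sign = %.4g (analytic SE %.3g), empirical p = %.4g (B = %d, %d variants)\n",
              x$gamma_sign, x$se_analytic, x$p_empirical, x$B, x$n_variants))
  invisible(x)
}

#' Per-group mean polygenic score with 95% confidence intervals
#'
#' @param scores per-individual scores (as from [compute_pgs()]).
#' @param cohort the cohort the scores belong to.
#' @param groups named character vector or factor mapping individual id to
#'   group label (ids must exist in the cohort).
#' @return data frame: group, n, mean, lo, hi (normal-theory 95% CI; NA
#'   for singleton groups, where the SE is undefined).
#' @export
group_means <- function(scores, cohort, groups) {
  ids <- names(groups)
  if (is.null(ids)) stop("`groups` must be named by individual id")
  unknown <- setdiff(ids, cohort$individual_id)
  if (length(unknown))
    stop("unknown individual id(s): ", paste(unknown, collapse = ", "))
  idx <- match(ids, cohort$individual_id)
  lab <- as.character(groups)
  out <- do.call(rbind, lapply(split(idx, lab), function(ii) {
    x <- scores[ii]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) stop("empty group after removing missing scores")
    m <- mean(x)
    se <- if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
    data.frame(n = n, mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se)
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
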