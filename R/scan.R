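#' Selection-scan configuration
#'
#' @param covariates `"ancestry"` (use the cohort's ancestry matrix, first
#'   component dropped to avoid collinearity with the intercept),
#'   `"none"`, or a numeric matrix with one row per individual.
#' @param maf_min minor-allele-frequency filter in [0, 0.5).
#' @param min_n minimum non-missing genotypes per variant (>= 3).
#' @param genomic_control inflate SEs by sqrt(lambda) with
#'   lambda = median(Z^2) / 0.4549364 (the median of a 1-df chi-square).
#' @param pseudohaploid_weight regression weight for pseudo-haploid
#'   individuals (their \{0, 2\} calls carry one read's information).
#' @return object of class `scan_config`.
#' @export
scan_config <- function(covariates = "ancestry", maf_min = 0.01,
                        min_n = 30L, genomic_control = FALSE,
                        pseudohaploid_weight = 0.5) {
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  if (min_n < 3L) stop("min_n must be at least 3")
  structure(list(covariates = covariates, maf_min = maf_min,
                 min_n = as.integer(min_n),
                 genomic_control = genomic_control,
                 pseudohaploid_weight = pseudohaploid_weight),
            class = "scan_config")
}

#' Per-variant selection scan on a dated cohort
#'
#' For each variant, regresses dosage on analysis time
#' `t = -date_bp / 1000` (so positive slopes mean the alternate allele is
#' rising toward the present) plus covariates, by weighted least squares
#' with pseudo-haploid individuals down-weighted. Complete-case over
#' missing genotypes. Variants that are monomorphic, below the MAF filter,
#' or observed in fewer than `min_n` individuals are dropped. Two-tailed
#' p-values from the normal approximation; optional genomic-control SE
#' inflation absorbs residual overdispersion.
#'
#' @param cohort an [ancient_cohort()].
#' @param config a [scan_config()].
#' @return data frame of selection summary statistics: CHR, POS, A1 (the
#'   allele whose dosage trend is measured, i.e. alt), A2, BETA (dosage
#'   change per 1,000 years toward the present), SE, Z, P, N, MAF. The
#'   genomic-control lambda (if applied) is stored in attribute `lambda`.
#' @export
run_scan <- function(cohort, config = scan_config()) {
  stopifnot(inherits(cohort, "ancient_cohort"))
  t_kyr <- -cohort$date_bp / 1000

  C <- scan_covariates(cohort, config$covariates)
  X <- cbind(`(Intercept)` = 1, t = t_kyr, C)
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank-deficient (columns: ",
         paste(colnames(X), collapse = ", "),
         "); drop collinear covariates")

  w <- ifelse(cohort$pseudohaploid, config$pseudohaploid_weight, 1)
  D <- cohort$dosage
  V <- ncol(D)

  n_used <- colSums(!is.na(D))
  pbar <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(pbar, 1 - pbar)
  keep <- which(n_used >= config$min_n & maf >= config$maf_min & maf > 0)
  if (!length(keep)) stop("all variants removed by the MAF/N filters")

  p_mod <- ncol(X)
  beta <- se <- rep(NA_real_, length(keep))

  complete <- !anyNA(D[, keep, drop = FALSE])
  if (complete) {
    # One shared design: closed-form WLS for every variant at once.
    XtW <- t(X * w)
    XtWX_inv <- solve(XtW %*% X)
    B <- XtWX_inv %*% XtW %*% D[, keep, drop = FALSE]   # p x m coefficients
    R <- D[, keep, drop = FALSE] - X %*% B
    rss <- colSums(w * R^2)
    sigma2 <- rss / (nrow(X) - p_mod)
    beta <- B[2L, ]
    se <- sqrt(sigma2 * XtWX_inv[2L, 2L])
  } else {
    for (i in seq_along(keep)) {
      d <- D[, keep[i]]
      cc <- !is.na(d)
      fit <- stats::lm.wfit(X[cc, , drop = FALSE], d[cc], w[cc])
      rss <- sum(w[cc] * fit$residuals^2)
      df <- sum(cc) - p_mod
      if (df <= 0) next
      Rinv <- chol2inv(fit$qr$qr[seq_len(p_mod), , drop = FALSE])
      beta[i] <- fit$coefficients[2L]
      se[i] <- sqrt(rss / df * Rinv[2L, 2L])
    }
  }

  ok <- is.finite(beta) & is.finite(se) & se > 0
  keep <- keep[ok]; beta <- beta[ok]; se <- se[ok]
  if (!length(keep)) stop("all variants removed by the MAF/N filters")

  z <- beta / se
  lambda <- NA_real_
  if (config$genomic_control) {
    lambda <- stats::median(z^2) / stats::qchisq(0.5, df = 1)
    se <- se * sqrt(lambda)
    z <- beta / se
  }

  out <- data.frame(
    CHR = cohort$variants$chrom[keep],
    POS = cohort$variants$pos[keep],
    A1 = cohort$variants$alt[keep],
    A2 = cohort$variants$ref[keep],
    BETA = beta, SE = se, Z = z,
    P = 2 * stats::pnorm(-abs(z)),
    N = n_used[keep],
    MAF = maf[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "lambda") <- lambda
  out
}

scan_covariates <- function(cohort, covariates) {
  if (is.matrix(covariates)) {
    if (nrow(covariates) != length(cohort$individual_id))
      stop("covariate matrix must have one row per individual")
    return(covariates)
  }
  switch(covariates,
    ancestry = {
      A <- cohort$ancestry
      if (ncol(A) < 2L) NULL else A[, -1L, drop = FALSE]
    },
    none = NULL,
    stop("covariates must be 'ancestry', 'none', or a matrix")
  )
}
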