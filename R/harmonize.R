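#' Harmonize two summary-statistic tables onto shared variants and alleles
#'
#' Variants are matched on chromosome and position. Where the second
#' table's alleles are swapped relative to the first (A1/A2 exchanged) its
#' Z (and BETA, if present) is sign-flipped. Strand-ambiguous palindromic
#' pairs (A/T or C/G) with minor-allele frequency above `ambiguous_maf`
#' are dropped, as are allele mismatches and unmatched positions.
#'
#' @param a reference table (CHR, POS, A1, A2, Z, ...; the selection track
#'   by convention).
#' @param b table to align onto `a`.
#' @param ambiguous_maf MAF threshold above which palindromic variants are
#'   considered unresolvable (default 0.4). The MAF column of `a` is used
#'   if present, else `b`'s; palindromic variants without any MAF are kept.
#' @return object of class `harmonized_pair`: list with aligned `a` and
#'   `b` (same variant order), and counts `n_flipped`,
#'   `n_dropped_ambiguous`, `n_dropped_mismatch`, `n_unmatched_a`,
#'   `n_unmatched_b`.
#' @export
harmonize_sumstats <- function(a, b, ambiguous_maf = 0.4) {
  key_a <- variant_key(a$CHR, a$POS)
  key_b <- variant_key(b$CHR, b$POS)
  for (nm in list(c("a", "first"), c("b", "second"))) {
    k <- if (nm[1] == "a") key_a else key_b
    if (anyDuplicated(k))
      stop("duplicate variant keys in ", nm[2], " table: ",
           paste(unique(k[duplicated(k)]), collapse = ", "))
  }

  ib <- match(key_a, key_b)
  matched <- !is.na(ib)
  n_unmatched_a <- sum(!matched)
  n_unmatched_b <- nrow(b) - sum(matched)

  ia <- which(matched)
  ib <- ib[matched]
  A1a <- toupper(a$A1[ia]); A2a <- toupper(a$A2[ia])
  A1b <- toupper(b$A1[ib]); A2b <- toupper(b$A2[ib])

  same <- A1a == A1b & A2a == A2b
  swap <- A1a == A2b & A2a == A1b & !same
  mismatch <- !(same | swap)

  pair <- paste(pmin(A1a, A2a), pmax(A1a, A2a))
  palindromic <- pair %in% c("A T", "C G")
  maf <- rep(NA_real_, length(ia))
  if ("MAF" %in% names(a)) maf <- a$MAF[ia]
  if (anyNA(maf) && "MAF" %in% names(b)) {
    fill <- is.na(maf)
    if ("MAF" %in% names(b)) maf[fill] <- b$MAF[ib][fill]
  }
  ambiguous <- palindromic & !is.na(maf) & maf > ambiguous_maf

  keep <- !mismatch & !ambiguous
  ia <- ia[keep]; ib <- ib[keep]; swap <- swap[keep]

  a_out <- a[ia, , drop = FALSE]
  b_out <- b[ib, , drop = FALSE]
  if (any(swap)) {
    tmp <- b_out$A1[swap]
    b_out$A1[swap] <- b_out$A2[swap]
    b_out$A2[swap] <- tmp
    b_out$Z[swap] <- -b_out$Z[swap]
    if ("BETA" %in% names(b_out)) b_out$BETA[swap] <- -b_out$BETA[swap]
  }
  rownames(a_out) <- rownames(b_out) <- NULL

  structure(list(a = a_out, b = b_out,
                 n_flipped = sum(swap),
                 n_dropped_ambiguous = sum(ambiguous),
                 n_dropped_mismatch = sum(mismatch),
                 n_unmatched_a = n_unmatched_a,
                 n_unmatched_b = n_unmatched_b),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf(paste0("harmonized_pair: %d variants aligned ",
                     "(%d flipped; dropped: %d ambiguous, %d mismatched; ",
                     "unmatched: %d/%d)\n"),
              nrow(x$a), x$n_flipped, x$n_dropped_ambiguous,
              x$n_dropped_mismatch, x$n_unmatched_a, x$n_unmatched_b))
  invisible(x)
}
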