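#' Construct an ancient-cohort object
#'
#' Container for a dated cohort: individual identifiers, radiocarbon-scale
#' dates in years before present (positive = older), an individuals-by-
#' components ancestry matrix (rows on the simplex), an individuals-by-
#' variants dosage matrix in \{0, 1, 2\} (NA = missing; pseudo-haploid
#' individuals carry only \{0, 2, NA\}), a per-individual pseudo-haploid
#' flag, and a variant table (chrom, pos, ref, alt).
#'
#' @param individual_id character vector.
#' @param date_bp non-negative numeric dates, years before present.
#' @param ancestry matrix (individuals x components), rows summing to 1.
#' @param dosage matrix (individuals x variants) with entries in
#'   \{0, 1, 2, NA\}.
#' @param pseudohaploid logical per individual.
#' @param variants data frame with columns chrom, pos, ref, alt.
#' @return object of class `ancient_cohort`.
#' @export
ancient_cohort <- function(individual_id, date_bp, ancestry, dosage,
                           pseudohaploid, variants) {
  n <- length(individual_id)
  if (length(date_bp) != n || nrow(ancestry) != n || nrow(dosage) != n ||
      length(pseudohaploid) != n)
    stop("all per-individual fields must have the same length")
  if (any(date_bp < 0)) stop("date_bp must be non-negative")
  if (any(abs(rowSums(ancestry) - 1) > 1e-9))
    stop("ancestry rows must sum to 1")
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stop("dosages must be 0, 1, 2 or NA")
  ph <- dosage[pseudohaploid, , drop = FALSE]
  if (any(ph == 1, na.rm = TRUE))
    stop("pseudo-haploid individuals may only carry dosages {0, 2, NA}")
  if (nrow(variants) != ncol(dosage))
    stop("variant table must have one row per dosage column")
  structure(list(individual_id = individual_id, date_bp = date_bp,
                 ancestry = ancestry, dosage = dosage,
                 pseudohaploid = pseudohaploid, variants = variants),
            class = "ancient_cohort")
}

#' @export
print.ancient_cohort <- function(x, ...) {
  cat(sprintf("ancient_cohort: %d individuals, %d variants, dates %0.f-%0.f BP\n",
              length(x$individual_id), ncol(x$dosage),
              min(x$date_bp), max(x$date_bp)))
  cat(sprintf("  pseudo-haploid: %d; missing dosages: %.2f%%\n",
              sum(x$pseudohaploid), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Sample a dated cohort from simulated trajectories
#'
#' Individuals receive dates uniform over the simulated time depth; their
#' ancestry is drawn from a Dirichlet centred on the admixture-schedule
#' proportions at their date; diploid dosages are binomial draws from the
#' ancestry-mixed allele frequency at their date. Missingness and
#' pseudo-haploid masking (dosage = 2 x a single sampled allele) are then
#' applied at the configured rates. The accompanying truth table records
#' the per-variant selection coefficient, block assignment, component
#' ancestral frequencies, and a standardized selection-effect column used
#' by the summary-statistic generators.
#'
#' @param traj a [simulate_trajectories()] result.
#' @param config simulation configuration; defaults to the one inside
#'   `traj`.
#' @param seed seed for the cohort-sampling stream (distinct by default
#'   from the trajectory seed).
#' @return list with elements `cohort` ([ancient_cohort]) and `truth`
#'   (data frame).
#' @export
sample_cohort <- function(traj, config = traj$config,
                          seed = config$seed + 1L) {
  stopifnot(inherits(traj, "wf_trajectories"))
  set.seed(seed)
  n <- config$n_individuals
  V <- config$n_variants
  K <- config$n_ancestries
  G <- config$generations
  ypg <- config$years_per_generation
  depth <- config$depth_years

  date_bp <- stats::runif(n, 0, depth)
  gen_idx <- pmin(G, pmax(0, round((depth - date_bp) / ypg))) + 1L

  base_prop <- schedule_proportions(config$admixture_schedule, date_bp, K)
  conc <- config$ancestry_concentration
  if (is.finite(conc)) {
    g <- matrix(stats::rgamma(n * K, shape = conc * base_prop), n, K)
    zero <- rowSums(g) == 0
    g[zero, ] <- base_prop[zero, , drop = FALSE]  # degenerate shape guard
    ancestry <- g / rowSums(g)
  } else {
    ancestry <- base_prop
  }

  pseudo <- stats::runif(n) < config$pseudohaploid_rate
  dosage <- matrix(NA_real_, n, V)
  for (i in seq_len(n)) {
    q <- as.vector(matrix(traj$freq[gen_idx[i], , ], ncol = K) %*%
                     ancestry[i, ])
    q[q < 0] <- 0; q[q > 1] <- 1
    dosage[i, ] <- if (pseudo[i]) 2 * stats::rbinom(V, 1L, q)
                   else stats::rbinom(V, 2L, q)
  }
  if (config$missing_rate > 0) {
    dosage[matrix(stats::runif(n * V) < config$missing_rate, n, V)] <- NA
  }
  all_missing <- colSums(!is.na(dosage)) == 0
  if (any(all_missing))
    stop("all genotypes missing at variant(s): ",
         paste(which(all_missing), collapse = ", "))

  variants <- data.frame(
    chrom = 1L,
    pos = seq_len(V) * 10000L,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE
  )
  cohort <- ancient_cohort(
    individual_id = sprintf("IND%04d", seq_len(n)),
    date_bp = date_bp, ancestry = ancestry, dosage = dosage,
    pseudohaploid = pseudo, variants = variants
  )

  s <- traj$s
  sel_effect <- if (any(s != 0)) s / sqrt(sum(s^2)) * sqrt(config$h2_sel)
                else numeric(V)
  truth <- cbind(
    variants,
    data.frame(block_id = rep(seq_len(config$n_blocks),
                              each = config$variants_per_block)[seq_len(V)],
               true_s = s, sel_effect = sel_effect),
    stats::setNames(as.data.frame(traj$p0),
                    paste0("anc_freq", seq_len(K)))
  )
  attr(truth, "h2_sel") <- if (any(s != 0)) config$h2_sel else 0
  list(cohort = cohort, truth = truth)
}
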