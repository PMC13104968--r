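#' Configuration for the synthetic ancient-cohort generator
#'
#' Bundles every knob of the forward simulator: cohort and variant counts,
#' LD-block layout, time depth, effective population size, the selected
#' fraction and selection-coefficient range, the admixture schedule that
#' induces population-structure confounding, and the missingness /
#' pseudo-haploid calling rates typical of ancient DNA.
#'
#' The default time depth is 400 generations at 25 years per generation,
#' i.e. a 10,000-year transect. The default admixture schedule moves through
#' three ancestral components (hunter-gatherer-like, early-farmer-like,
#' steppe-like) so that naive frequency-on-date regressions are confounded
#' unless ancestry covariates are included.
#'
#' @param seed integer seed controlling every random draw downstream.
#' @param n_individuals cohort size.
#' @param n_variants number of variants (rounded up to fill LD blocks).
#' @param n_blocks number of LD blocks.
#' @param variants_per_block variants per block; default `n_variants / n_blocks`.
#' @param generations forward-simulation length in generations.
#' @param pop_size effective diploid population size (>= 10).
#' @param frac_selected proportion of variants given a nonzero selection
#'   coefficient.
#' @param s_range interval of per-generation additive selection coefficient
#'   magnitudes (sign is randomized per variant); must sit inside (-0.5, 0.5).
#' @param n_ancestries number of ancestral components.
#' @param admixture_schedule data frame with columns `age_max`, `age_min`
#'   (years BP, piecewise-constant intervals) and one proportion column per
#'   ancestry; rows must be simplexes. `NULL` installs the default
#'   three-component schedule (or uniform proportions otherwise).
#' @param missing_rate per-genotype missingness probability.
#' @param pseudohaploid_rate probability an individual is pseudo-haploid
#'   (dosages restricted to \{0, 2\}).
#' @param years_per_generation calendar years per generation.
#' @param fst Balding-Nichols divergence of component allele frequencies
#'   from the shared ancestral frequency (0 = identical components).
#' @param ancestry_concentration Dirichlet concentration of individual
#'   ancestry around the schedule proportions (`Inf` = exact proportions).
#' @param h2_sel total standardized selection-effect scale recorded in the
#'   truth table (used by the summary-statistic generators).
#' @param p0 optional fixed ancestral allele frequency (scalar or
#'   per-variant vector); default draws Uniform(0.05, 0.95).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 500L,
                       n_variants = 1000L,
                       n_blocks = 20L,
                       variants_per_block = NULL,
                       generations = 400L,
                       pop_size = 10000L,
                       frac_selected = 0.1,
                       s_range = c(0.005, 0.02),
                       n_ancestries = 3L,
                       admixture_schedule = NULL,
                       missing_rate = 0.05,
                       pseudohaploid_rate = 0.3,
                       years_per_generation = 25,
                       fst = 0.1,
                       ancestry_concentration = 100,
                       h2_sel = 0.5,
                       p0 = NULL) {
  if (is.null(variants_per_block))
    variants_per_block <- as.integer(ceiling(n_variants / n_blocks))
  n_variants <- as.integer(n_blocks * variants_per_block)

  assert_prob(frac_selected, "frac_selected")
  assert_prob(missing_rate, "missing_rate")
  assert_prob(pseudohaploid_rate, "pseudohaploid_rate")
  assert_prob(fst, "fst")
  if (length(s_range) != 2L || any(abs(s_range) >= 0.5))
    stop("`s_range` must be an interval within (-0.5, 0.5)")
  if (n_ancestries < 1L) stop("need at least one ancestry component")
  if (!is.null(p0)) assert_prob(p0, "p0")

  depth_years <- generations * years_per_generation
  if (is.null(admixture_schedule))
    admixture_schedule <- default_admixture_schedule(n_ancestries, depth_years)
  validate_admixture_schedule(admixture_schedule, n_ancestries)

  cfg <- list(
    seed = as.integer(seed), n_individuals = as.integer(n_individuals),
    n_variants = n_variants, n_blocks = as.integer(n_blocks),
    variants_per_block = variants_per_block,
    generations = as.integer(generations), pop_size = pop_size,
    frac_selected = frac_selected, s_range = s_range,
    n_ancestries = as.integer(n_ancestries),
    admixture_schedule = admixture_schedule,
    missing_rate = missing_rate, pseudohaploid_rate = pseudohaploid_rate,
    years_per_generation = years_per_generation,
    depth_years = depth_years,
    fst = fst, ancestry_concentration = ancestry_concentration,
    h2_sel = h2_sel, p0 = p0
  )
  class(cfg) <- "sim_config"
  cfg
}

# Three-component schedule loosely tracking the West Eurasian transect:
# a hunter-gatherer-only deep past, a farmer-dominated middle interval, and
# a steppe-admixed recent interval. For other component counts the schedule
# is a single interval of uniform proportions.
default_admixture_schedule <- function(k, depth_years) {
  if (k == 3L) {
    sched <- data.frame(
      age_max = c(depth_years, 0.85 * depth_years, 0.50 * depth_years),
      age_min = c(0.85 * depth_years, 0.50 * depth_years, 0),
      anc1 = c(1.00, 0.20, 0.15),
      anc2 = c(0.00, 0.80, 0.40),
      anc3 = c(0.00, 0.00, 0.45)
    )
  } else {
    props <- matrix(1 / k, nrow = 1, ncol = k,
                    dimnames = list(NULL, paste0("anc", seq_len(k))))
    sched <- cbind(data.frame(age_max = depth_years, age_min = 0),
                   as.data.frame(props))
  }
  sched
}

validate_admixture_schedule <- function(sched, k) {
  pcols <- paste0("anc", seq_len(k))
  if (!all(c("age_max", "age_min", pcols) %in% names(sched)))
    stop("admixture schedule needs columns age_max, age_min, anc1..anc", k)
  pm <- as.matrix(sched[, pcols, drop = FALSE])
  assert_prob(pm, "ancestry proportions")
  if (any(abs(rowSums(pm) - 1) > 1e-9))
    stop("ancestry proportions must sum to 1 in every schedule interval")
  invisible(sched)
}

# Piecewise-constant lookup of ancestry proportions at a date (years BP).
schedule_proportions <- function(sched, date_bp, k) {
  pcols <- paste0("anc", seq_len(k))
  pm <- as.matrix(sched[, pcols, drop = FALSE])
  out <- matrix(NA_real_, length(date_bp), k)
  for (r in seq_len(nrow(sched))) {
    inside <- date_bp <= sched$age_max[r] & date_bp >= sched$age_min[r]
    out[inside & is.na(out[, 1L]), ] <-
      matrix(pm[r, ], sum(inside & is.na(out[, 1L])), k, byrow = TRUE)
  }
  if (anyNA(out)) stop("admixture schedule does not cover all sampled dates")
  out
}
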