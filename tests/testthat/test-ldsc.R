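test_that("a pure-null track gives zero slope and unit intercept", {
  ld <- make_ld_reference(100, 25)
  set.seed(1)
  ss <- data.frame(CHR = 1L, POS = ld$variants$pos, A1 = "G", A2 = "A",
                   Z = stats::rnorm(ld$M), N = 5e4)
  h <- estimate_h2(ss, ld, n_blocks = 50)
  expect_lt(abs(h$h2), 2 * h$se)
  se_int <- paleoimmune:::jackknife_se(h$loo_intercept)
  expect_lt(abs(h$intercept - 1), 2 * se_int)
})

test_that("h2 and rg round-trip the generator's targets", {
  ld <- make_ld_reference(200, 25)
  truth <- simulate_truth_effects(ld, h2_sel = 0.5, seed = 2)
  sel <- simulate_selection_zscores(truth, ld, 1e5, seed = 3)
  h <- estimate_h2(sel, ld, n_blocks = 100)
  expect_lt(abs(h$h2 - 0.5), 2 * h$se)

  gw5 <- simulate_gwas_sumstats(truth, ld, 1e5, rg_target = 0.5, seed = 4)
  r5 <- estimate_rg(sel, gw5, ld, n_blocks = 100)
  expect_lt(abs(r5$rg - 0.5), 2 * r5$se_rg)

  # 3-SE Monte-Carlo slack at this reduced scale (5k variants); the
  # full-scale 2-SE recovery check lives in the acceptance suite
  gw0 <- simulate_gwas_sumstats(truth, ld, 1e5, rg_target = 0, seed = 5)
  r0 <- estimate_rg(sel, gw0, ld, n_blocks = 100)
  expect_lt(abs(r0$rg), 3 * r0$se_rg)

  # identical tracks are perfectly correlated
  rself <- estimate_rg(sel, sel, ld, n_blocks = 100)
  expect_lt(abs(rself$rg - 1), 2 * max(rself$se_rg, 1e-3))
})

test_that("doubling the LD scores halves the slope with frozen weights", {
  ld <- make_ld_reference(50, 20)
  truth <- simulate_truth_effects(ld, h2_sel = 0.4, seed = 6)
  ss <- simulate_selection_zscores(truth, ld, 5e4, seed = 7)
  h1 <- estimate_h2(ss, ld, n_blocks = 25)
  ld2 <- ld
  ld2$variants$ld_score <- 2 * ld$variants$ld_score
  h2 <- estimate_h2(ss, ld2, n_blocks = 25, weights = h1$weights)
  h1b <- estimate_h2(ss, ld, n_blocks = 25, weights = h1$weights)
  expect_equal(h2$h2, h1b$h2 / 2, tolerance = 1e-10)
})

test_that("rg is symmetric and scale-consistent", {
  ld <- make_ld_reference(100, 20)
  truth <- simulate_truth_effects(ld, h2_sel = 0.5, seed = 8)
  a <- simulate_selection_zscores(truth, ld, 8e4, seed = 9)
  b <- simulate_gwas_sumstats(truth, ld, 6e4, rg_target = 0.4, seed = 10)
  r_ab <- estimate_rg(a, b, ld, n_blocks = 50)
  r_ba <- estimate_rg(b, a, ld, n_blocks = 50)
  expect_equal(r_ab$rg, r_ba$rg, tolerance = 1e-10)

  a2 <- transform(a, Z = 2 * Z, N = 4 * N)
  r_scaled <- estimate_rg(a2, b, ld, n_blocks = 50)
  expect_equal(r_scaled$rg, r_ab$rg, tolerance = 1e-6)

  b_bad <- b[-1, ]
  expect_error(estimate_rg(a, b_bad, ld), "harmonize")
})

test_that("GLS meta-analysis reduces to IVW and matches the hand formula", {
  est <- c(0.2, -0.1, 0.05)
  v <- c(0.01, 0.04, 0.02)
  m <- meta_gls(est, Sigma = diag(v))
  ivw <- sum(est / v) / sum(1 / v)
  expect_equal(m$estimate, ivw, tolerance = 1e-14)
  expect_equal(m$se, 1 / sqrt(sum(1 / v)), tolerance = 1e-14)

  # all estimates equal -> pooled equals that value under any valid Sigma
  S <- matrix(c(1, 0.5, 0.5, 2), 2)
  expect_equal(meta_gls(c(0.3, 0.3), Sigma = S)$estimate, 0.3)

  # hand-evaluated GLS: Sigma = [[1, .5], [.5, 2]], r = (0.1, 0.3)
  m2 <- meta_gls(c(0.1, 0.3), Sigma = S)
  expect_equal(m2$estimate, 0.15, tolerance = 1e-10)
  expect_equal(m2$se, 0.9354143, tolerance = 1e-6)
  expect_equal(m2$p, stats::pnorm(0.15 / 0.9354143), tolerance = 1e-6)
})

test_that("meta_gls builds Sigma from shared jackknife pseudovalues", {
  set.seed(11)
  B <- 40
  loo <- rbind(0.2 + stats::rnorm(B, sd = 0.002),
               -0.1 + stats::rnorm(B, sd = 0.003))
  est <- rowMeans(loo)
  m <- meta_gls(est, loo = loo)
  pseudo <- B * est - (B - 1) * loo
  expect_equal(m$Sigma, stats::cov(t(pseudo)) / B, tolerance = 1e-12)
  expect_error(meta_gls(est, loo = loo[, 1, drop = FALSE]),
               "inconsistent block counts")
  expect_error(meta_gls(c(0.1, 0.2, 0.3), loo = loo), "one row per")

  # near-singular Sigma triggers the ridge and still returns finite output
  S <- matrix(c(1, 1, 1, 1 + 1e-12), 2)
  mr <- meta_gls(c(0.1, 0.2), Sigma = S)
  expect_true(is.finite(mr$estimate) && is.finite(mr$se))
  expect_gt(mr$condition_number, 1e6)
})

test_that("signal partitioning recovers shares and swaps with its complement", {
  ld <- make_ld_reference(200, 25)
  truth <- simulate_truth_effects(ld, h2_sel = 0.5, seed = 12)
  ss <- simulate_selection_zscores(truth, ld, 1e5, seed = 13)
  set.seed(14)
  ann <- rep(FALSE, ld$M); ann[sample.int(ld$M, 1000)] <- TRUE
  p1 <- partition_signal(ss, ld, ann, n_blocks = 50)
  p2 <- partition_signal(ss, ld, !ann, n_blocks = 50)
  expect_equal(p1$proportion + p2$proportion, 1, tolerance = 1e-8)
  expect_lt(abs(p1$proportion - 0.2), 2 * p1$se)
  expect_lt(abs(p1$enrichment - 1), 2 * p1$se / 0.2)

  # all signal inside the annotation
  truth_in <- truth
  truth_in$sel_effect[!ann] <- 0
  attr(truth_in, "h2_sel") <- sum(truth_in$sel_effect^2)
  ss_in <- simulate_selection_zscores(truth_in, ld, 1e5, seed = 15)
  p_in <- partition_signal(ss_in, ld, ann, n_blocks = 50)
  expect_lt(abs(p_in$proportion - 1), 3 * p_in$se)  # reduced-scale slack

  expect_error(partition_signal(ss, ld, rep(TRUE, ld$M)), "not all")
  expect_error(partition_signal(ss, ld, rep(FALSE, ld$M)), "non-empty")

  # r = 0 makes annotation scores collinear with the intercept pair
  ld0 <- make_ld_reference(20, 10, r = 0)
  ss0 <- data.frame(CHR = 1L, POS = ld0$variants$pos, A1 = "G", A2 = "A",
                    Z = stats::rnorm(ld0$M), N = 1e4)
  ann0 <- rep(c(TRUE, FALSE), length.out = ld0$M)
  expect_error(partition_signal(ss0, ld0, ann0, n_blocks = 10),
               "collinear")
})

test_that("the block jackknife matches the analytic SE on iid data", {
  ratio <- vapply(1:10, function(s) {
    set.seed(s)
    x <- stats::rnorm(5000)
    bj <- block_jackknife(x, n_blocks = 100)
    bj$se / (stats::sd(x) / sqrt(length(x)))
  }, 0)
  expect_lt(abs(mean(ratio) - 1), 0.20)
})
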