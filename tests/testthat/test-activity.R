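mk_track <- function(pos, z, n = 1e4, chrom = 1L) {
  data.frame(CHR = chrom, POS = pos, A1 = "G", A2 = "A", Z = z, N = n,
             stringsAsFactors = FALSE)
}

test_that("gene covariance matches hand arithmetic and its symmetries", {
  pos <- 1:6 * 1000
  sel <- mk_track(pos, c(4, -5, 3.5, 0.5, 6, -3.5), n = 2e4)
  pq <- mk_track(pos, c(3.2, -4, 1, 5, 3.1, 4), n = 1e4)
  gc <- gene_covariance(sel, pq, z_min = 3)
  # qualifying by hand: |Zsel| > 3 & |Zpq| > 3 -> variants 1, 2, 5, 6
  hand <- mean(c(4 * 3.2, (-5) * (-4), 6 * 3.1, (-3.5) * 4) /
               sqrt(2e4 * 1e4))
  expect_identical(gc$n_qualifying, 4L)
  expect_equal(gc$covariance, hand, tolerance = 1e-12)

  # self-covariance is positive; pqtl negation flips the sign exactly
  self <- gene_covariance(sel, sel)
  expect_gt(self$covariance, 0)
  neg <- gene_covariance(sel, transform(pq, Z = -Z))
  expect_equal(neg$covariance, -gc$covariance, tolerance = 1e-12)

  none <- gene_covariance(sel, mk_track(pos, rep(0.1, 6)))
  expect_false(none$qualified)
})

activity_fixture <- function(coupling_value, seed = 50, n_genes = 12,
                             noise = TRUE) {
  ld <- make_ld_reference(100, 25)
  truth <- simulate_truth_effects(ld, h2_sel = 0.5, seed = seed)
  sel <- simulate_selection_zscores(truth, ld, 1e5, seed = seed + 1,
                                    noise = noise)
  genes <- make_gene_map(ld, n_genes)
  coup <- stats::setNames(rep(coupling_value, n_genes), genes$gene_id)
  pq <- simulate_pqtl_tables(truth, ld, genes, 5e4, coup, seed = seed + 2,
                             h2_cis = if (noise) 0.2 else 0, noise = noise)
  list(sel = sel, pq = pq, genes = genes)
}

test_that("the pathway statistic is exactly antisymmetric in regulator signs", {
  fx <- activity_fixture(0.4, seed = 60)
  signs <- stats::setNames(c(1, 1, -1, 1, -1, 1), fx$genes$gene_id[1:6])
  pw <- list(id = "P", signs = signs)
  pw_flip <- list(id = "P", signs = -signs)
  a <- pathway_activity(fx$sel, fx$pq, pw, n_blocks = 25)
  b <- pathway_activity(fx$sel, fx$pq, pw_flip, n_blocks = 25)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_true(a$direction != b$direction)

  # negating the whole pQTL track also flips the statistic exactly
  pq_neg <- lapply(fx$pq, function(x) transform(x, Z = -Z))
  c_ <- pathway_activity(fx$sel, pq_neg, pw, n_blocks = 25)
  expect_equal(c_$statistic, -a$statistic, tolerance = 1e-12)
})

test_that("positive coupling on positive regulators infers increased activity", {
  fx <- activity_fixture(0.6, seed = 70)
  pw <- list(id = "UP", signs = stats::setNames(rep(1, 8),
                                                fx$genes$gene_id[1:8]))
  res <- pathway_activity(fx$sel, fx$pq, pw, n_blocks = 25)
  expect_identical(res$direction, "increased")
  expect_gt(res$z, 3)

  # paired positive/negative regulator sets of the same process concur:
  # negative regulators of an upregulated process are suppressed, i.e.
  # couple negatively, and the sign convention recovers "increased"
  fx_neg <- activity_fixture(-0.6, seed = 70)
  pw_neg <- list(id = "UPneg",
                 signs = stats::setNames(rep(-1, 8),
                                         fx_neg$genes$gene_id[1:8]))
  res_neg <- pathway_activity(fx_neg$sel, fx_neg$pq, pw_neg, n_blocks = 25)
  expect_identical(res_neg$direction, "increased")
})

test_that("the drop rule is idempotent and reasons are reported", {
  fx <- activity_fixture(0.5, seed = 80)
  # one gene with a pQTL track that never qualifies
  pos <- fx$sel$POS
  fx$pq$GENE_FLAT <- mk_track(pos, rep(0, length(pos)), n = 5e4)
  signs <- stats::setNames(c(1, 1, 1, 1), c(fx$genes$gene_id[1:3],
                                            "GENE_FLAT"))
  res <- pathway_activity(fx$sel, fx$pq, list(id = "P", signs = signs),
                          n_blocks = 25)
  expect_identical(unname(res$dropped["GENE_FLAT"]),
                   "no qualifying variants")

  # re-running on the retained genes drops nothing further
  res2 <- pathway_activity(fx$sel, fx$pq,
                           list(id = "P", signs = signs[res$genes_used]),
                           n_blocks = 25)
  expect_identical(sort(res2$genes_used), sort(res$genes_used))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)

  all_flat <- list(id = "P", signs = c(GENE_FLAT = 1))
  expect_error(pathway_activity(fx$sel, fx$pq, all_flat),
               "all genes dropped")
})

test_that("the gene filter gates pathway membership", {
  fx <- activity_fixture(0.5, seed = 90)
  signs <- stats::setNames(rep(1, 6), fx$genes$gene_id[1:6])
  res <- pathway_activity(fx$sel, fx$pq, list(id = "P", signs = signs),
                          n_blocks = 25,
                          gene_filter = fx$genes$gene_id[1:3])
  expect_setequal(res$genes_used, fx$genes$gene_id[1:3])
  expect_true(all(res$dropped[fx$genes$gene_id[4:6]] ==
                  "failed gene filter"))
})

test_that("jackknife SE approaches the analytic SE on an unstructured track", {
  # independent variants (r = 0): contributions are i.i.d. products
  ratio <- vapply(1:10, function(s) {
    ld <- make_ld_reference(400, 1, r = 0)
    truth <- simulate_truth_effects(ld, h2_sel = 0.9, seed = s)
    sel <- simulate_selection_zscores(truth, ld, 3e5, seed = s + 100)
    pq <- simulate_pqtl_tables(truth, ld, make_gene_map(ld, 1), 3e5,
                               stats::setNames(1, "GENE001"),
                               seed = s + 200, h2_cis = 0)
    gc <- gene_covariance(sel, pq$GENE001)
    pw <- list(id = "P", signs = c(GENE001 = 1))
    res <- pathway_activity(sel, pq, pw, n_blocks = 50)
    analytic <- stats::sd(gc$contrib) / sqrt(gc$n_qualifying)
    res$se / analytic
  }, 0)
  expect_lt(abs(mean(ratio) - 1), 0.25)
})

test_that("activation summary tabulates directions and reuses the odds ratio", {
  res <- data.frame(
    pathway = sprintf("P%02d", 1:74),
    direction = rep(c("increased", "decreased", "increased", "decreased"),
                    c(33, 2, 22, 17)),
    immune = rep(c(TRUE, FALSE), c(35, 39)),
    q = 0.01
  )
  s <- activation_summary(res, B = 199, seed = 3)
  expect_identical(s$table["increased", "immune"], 33L)
  expect_identical(s$odds_ratio, 12.75)
  expect_lt(s$p_permutation, 0.05)

  none <- transform(res, q = 0.5)
  s0 <- activation_summary(none)
  expect_identical(s0$n_significant, 0L)
  expect_true(is.na(s0$odds_ratio))

  all_inc <- transform(res, direction = "increased")
  s1 <- activation_summary(all_inc, B = 99, seed = 1)
  expect_true(s1$flagged)  # zero margin: odds ratio undefined
})
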