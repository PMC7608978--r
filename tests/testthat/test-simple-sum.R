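test_that("p-values map to upper-tail chi-square(1) quantiles", {
  expect_equal(pvalues_to_chisq(1), 0)
  expect_equal(pvalues_to_chisq(0.05), 3.8415, tolerance = 1e-4)
  expect_equal(pvalues_to_chisq(0.3173105), 1.000, tolerance = 1e-3)
  expect_error(pvalues_to_chisq(0), class = "sscoloc_domain_error")
  expect_error(pvalues_to_chisq(1.1), class = "sscoloc_domain_error")
})

test_that("quadratic-form tail matches closed forms", {
  # two unit eigenvalues: chi-square(2), tail = exp(-s/2)
  s <- stats::qchisq(0.95, 2)
  expect_equal(quadform_tail_prob(s, c(1, 1)), exp(-s / 2), tolerance = 1e-6)
  expect_equal(quadform_tail_prob(3.841459, 1), 0.05, tolerance = 1e-4)
  expect_equal(quadform_tail_prob(0, c(1, 2)), 1)
  expect_error(quadform_tail_prob(1, c(-1, 2)), class = "sscoloc_domain_error")
  expect_error(quadform_tail_prob(1, c(0, 0)), class = "sscoloc_degenerate_error")
  # distinct eigenvalues against a frozen-seed Monte-Carlo oracle
  lam <- c(2, 1, 0.5); s <- 10
  set.seed(1234)
  draws <- colSums(lam * matrix(stats::rchisq(3 * 2e5, df = 1), nrow = 3))
  phat <- mean(draws > s)
  se <- sqrt(phat * (1 - phat) / 2e5)
  expect_lt(abs(quadform_tail_prob(s, lam) - phat), 3 * se)
})

test_that("stage 1 reduces to the chi-square tail and is uniform under the null", {
  expect_equal(stage1_test(3.841459, matrix(1)), 0.05, tolerance = 1e-4)
  expect_equal(stage1_test(rep(0, 4), diag(4)), 1)
  set.seed(55)
  pvals <- replicate(300, {
    T <- stats::rchisq(20, df = 1)
    stage1_test(T, diag(20))
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("noncentrality estimate is mean evidence above its null expectation", {
  expect_equal(estimate_noncentrality(rep(1, 10)), 0)
  expect_equal(estimate_noncentrality(c(5, 3, 4)), 3)
  expect_equal(estimate_noncentrality(c(0.1, 0.2)), 0)  # clamped at zero
  set.seed(9)
  T <- stats::rchisq(1000, df = 1, ncp = 4)
  expect_gt(estimate_noncentrality(T), 3.5)
  expect_lt(estimate_noncentrality(T), 4.5)
})

test_that("stage-2 statistic has null mean 0 and sd 1 under its own model", {
  set.seed(77)
  n <- 30
  w <- ss_weights(stats::runif(n))  # one fixed draw of GWAS weights
  zs <- replicate(1e4, {
    T <- stats::rchisq(n, df = 1)
    ss_stage2_test(T, w, diag(n), delta = 0)$z
  })
  expect_lt(abs(mean(zs)), 0.05)
  expect_lt(abs(stats::sd(zs) - 1), 0.05)
})

test_that("degenerate weights fail rather than producing a p-value", {
  n <- 10
  T <- stats::rchisq(n, df = 1)
  res <- ss_stage2_test(T, list(g = rep(2, n), c = rep(0, n)), diag(n), 0)
  expect_false(res$ok)
})

test_that("the statistic is invariant to SNP order, centering and weight scale", {
  set.seed(5)
  n <- 25
  R <- 0.7^abs(outer(1:n, 1:n, "-"))
  T <- stats::rchisq(n, df = 1, ncp = 2)
  p_gwas <- stats::runif(n)
  w <- ss_weights(p_gwas)
  delta <- estimate_noncentrality(T)
  z0 <- ss_stage2_test(T, w, R, delta)$z

  perm <- sample(n)
  zp <- ss_stage2_test(T[perm], list(g = w$g[perm], c = w$c[perm]),
                       R[perm, perm], delta)$z
  expect_equal(zp, z0, tolerance = 1e-12)

  # adding a constant to all -log10 p leaves the centered weights unchanged
  w_shift <- ss_weights(p_gwas / 10)  # shifts g by log10(10) = 1
  expect_equal(w_shift$c, w$c, tolerance = 1e-12)

  w_scaled <- list(g = 3 * w$g, c = 3 * w$c)
  expect_equal(ss_stage2_test(T, w_scaled, R, delta)$z, z0, tolerance = 1e-12)
})

test_that("raising evidence at the top-weighted SNP never lowers the statistic", {
  set.seed(6)
  n <- 15
  R <- 0.5^abs(outer(1:n, 1:n, "-"))
  T <- stats::rchisq(n, df = 1)
  w <- ss_weights(stats::runif(n))
  jmax <- which.max(w$c)
  delta <- estimate_noncentrality(T)  # held fixed so only the numerator moves
  zs <- vapply(seq(0, 20, by = 2), function(add) {
    T2 <- T; T2[jmax] <- T2[jmax] + add
    ss_stage2_test(T2, w, R, delta)$z
  }, numeric(1))
  expect_true(all(diff(zs) >= -1e-12))
})

test_that("run_simple_sum encodes its failure modes as sentinels", {
  cfg <- scenario_config("C", seed = 1)
  sim <- simulate_summary_stats(cfg, with_genotypes = FALSE)

  # empty secondary in region -> -1 (no data)
  empty <- make_ds(pos = 1:6, p = rep(0.5, 6))
  res1 <- run_simple_sum(sim$primary, empty, sim$ld, sim$region)
  expect_equal(res1$status, "NO_DATA")
  expect_equal(res1$sentinel, -1L)

  # stage-1 gate at alpha/m is the -2 condition, whatever the draw
  for (seed in 1:8) {
    simA <- simulate_summary_stats(scenario_config("A", seed = seed),
                                   with_genotypes = FALSE)
    res <- run_simple_sum(simA$primary, simA$collection$entries[[1]], simA$ld,
                          simA$region, alpha = 0.05, m = 49)
    if (res$status %in% c("NOT_SIGNIFICANT", "OK")) {
      expect_equal(res$status == "NOT_SIGNIFICANT", res$stage1_p > 0.05 / 49)
    }
    if (res$status == "NOT_SIGNIFICANT") expect_equal(res$sentinel, -2L)
  }

  # fewer than min_snps harmonized SNPs with a passing stage 1 -> -3
  cfg4 <- scenario_config("C", n_snps = 4, seed = 2, effect_size = 8)
  sim4 <- simulate_summary_stats(cfg4, with_genotypes = FALSE)
  res3 <- run_simple_sum(sim4$primary, sim4$collection$entries[[1]], sim4$ld,
                         sim4$region)
  expect_equal(res3$status, "FAILED")
  expect_equal(res3$sentinel, -3L)

  # colocalized locus -> OK with small p
  resC <- run_simple_sum(sim$primary, sim$collection$entries[[1]], sim$ld,
                         sim$region)
  expect_equal(resC$status, "OK")
  expect_lt(resC$ss_p, 0.05)
  expect_equal(resC$neglog10_ss_p, -log10(resC$ss_p))
})
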