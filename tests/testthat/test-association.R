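test_that("depth normalization preserves zeros and common-scale invariance", {
  obs <- matrix(c(0, 4, 8, 2), 2, 2, dimnames = list(NULL, c("D1", "D2")))
  depth <- c(D1 = 2e6, D2 = 1e6)
  norm <- normalize_counts(obs, depth)
  expect_equal(unname(norm[1, 1]), 0)
  expect_equal(unname(norm[2, 1]), 2)
  expect_equal(unname(norm[1, 2]), 8)
  # scaling all depths by a constant rescales counts but not test results
  norm2 <- normalize_counts(obs, depth * 3)
  g <- c(D1 = 0L, D2 = 2L)
  t1 <- genotype_trend_test(norm[2, ], g)
  t2 <- genotype_trend_test(norm2[2, ], g)
  expect_equal(t1$p_geno, t2$p_geno, tolerance = 1e-9)
})

test_that("expected counts are distance-stratum means with scale equivariance", {
  loops <- tibble::tibble(chrom = "chr1",
                          b1_start = seq(0L, by = 100000L, length.out = 24L),
                          b2_start = seq(0L, by = 100000L, length.out = 24L) +
                            50000L,
                          resolution = 5000L)
  donors <- c("D1", "D2")
  obs <- matrix(2, 24, 2, dimnames = list(NULL, donors))
  profs <- contact_profiles(loops, obs, NULL,
                            matrix(TRUE, 24, 2, dimnames = list(NULL, donors)))
  est <- estimate_expected_counts(profs)
  expect_equal(unname(est$expected), matrix(2, 24, 2))  # stratum mean
  profs2 <- profs
  profs2$observed <- profs$observed * 2
  est2 <- estimate_expected_counts(profs2)
  expect_equal(est2$expected, est$expected * 2)
  expect_equal(contact_ratios(est2), contact_ratios(est))
  expect_true(all(est$expected > 0))
})

test_that("expected counts track a simulated power-law decay", {
  # constant baseline so the generating expected depends on distance only
  cfg <- sim_config(n_loops = 300, n_effects = 0, seed = 31,
                    baseline_range = c(20, 20))
  ds <- simulate_dataset(cfg, emit_read_pairs = FALSE)
  profs <- ds$profiles
  profs$expected <- NULL
  est <- estimate_expected_counts(profs)
  # Monte-Carlo oracle: within each donor x stratum, the estimate (the
  # stratum mean of observed) should sit within 3 SE of the stratum mean of
  # the generating expected counts
  stratum <- floor(log10(profs$loops$distance) * 8)
  checked <- 0L
  for (d in ds$profiles$donors[1:5]) {
    for (s in unique(stratum)) {
      rows <- stratum == s
      if (sum(rows) < 10) next
      obs <- ds$profiles$observed[rows, d]
      se <- sd(obs) / sqrt(length(obs))
      expect_lt(abs(est$expected[rows, d][1] -
                      mean(ds$profiles$expected[rows, d])), 3.5 * se)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5L)
})

test_that("genotype trend test matches a normal-equations oracle and edge cases", {
  set.seed(77)
  norm <- 2^rnorm(8, 5, 1) - 1
  g <- c(0, 0, 1, 1, 1, 2, 2, 2)
  names(norm) <- names(g) <- paste0("D", 1:8)
  fit <- genotype_trend_test(norm, g)
  oracle <- ols_oracle(log2(norm + 1), cbind(1, g))
  expect_equal(fit$slope, unname(oracle$beta[2]), tolerance = 1e-10)
  expect_equal(fit$p_geno, unname(oracle$p[2]), tolerance = 1e-10)

  # zero-residual increasing counts: p -> 0
  counts <- c(1, 1, 3, 3, 7, 7)
  names(counts) <- paste0("D", 1:6)
  g2 <- stats::setNames(c(0, 0, 1, 1, 2, 2), names(counts))
  fit2 <- genotype_trend_test(counts, g2)
  expect_lt(fit2$p_geno, 1e-12)
  expect_gt(fit2$slope, 0)

  # constant response
  fit3 <- genotype_trend_test(stats::setNames(rep(4, 6), names(counts)), g2)
  expect_equal(fit3$p_geno, 1)
  expect_equal(fit3$slope, 0)

  # single dosage level is untestable
  fit4 <- genotype_trend_test(counts, stats::setNames(rep(1, 6), names(counts)))
  expect_false(fit4$testable)

  # missing genotypes are excluded
  g5 <- g2; g5[1] <- NA
  fit5 <- genotype_trend_test(counts, g5)
  expect_equal(fit5$n_used, 5L)
})

test_that("trend test is invariant to donor relabeling", {
  set.seed(88)
  norm <- stats::setNames(2^rnorm(12, 5, 1), paste0("D", 1:12))
  g <- stats::setNames(sample(0:2, 12, replace = TRUE), names(norm))
  perm <- sample(names(norm))
  f1 <- genotype_trend_test(norm, g)
  f2 <- genotype_trend_test(norm[perm], g[perm])
  expect_equal(f1$p_geno, f2$p_geno, tolerance = 1e-12)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
})

test_that("paired allele t-test matches the closed-form Student tail", {
  # symmetric diffs with direction +: t = 0 -> p = 0.5
  r <- c(2, 3); a <- c(3, 2)  # diffs +1, -1
  fit <- allele_paired_ttest(r, a, direction = 1, min_donors = 2)
  expect_equal(fit$p_as, 0.5)

  # diffs (3,3,5): closed form with df = 2
  r2 <- c(0, 0, 0); a2 <- c(3, 3, 5)
  fit2 <- allele_paired_ttest(r2, a2, direction = 1)
  expect_equal(fit2$p_as, paired_t_oracle(c(3, 3, 5), 1), tolerance = 1e-12)
  # opposite direction is the complementary tail
  fit2m <- allele_paired_ttest(r2, a2, direction = -1)
  expect_equal(fit2m$p_as, 1 - fit2$p_as, tolerance = 1e-12)

  # all diffs zero -> p = 1 (no usable direction)
  fit3 <- allele_paired_ttest(c(2, 2, 2), c(2, 2, 2), direction = 1)
  expect_equal(fit3$p_as, 1)

  # zero variance, nonzero mean in the tested direction -> p = 0
  fit4 <- allele_paired_ttest(c(1, 1, 1), c(4, 4, 4), direction = 1)
  expect_equal(fit4$p_as, 0)
  fit4m <- allele_paired_ttest(c(1, 1, 1), c(4, 4, 4), direction = -1)
  expect_equal(fit4m$p_as, 1)

  # fewer than 3 usable donors -> missing
  fit5 <- allele_paired_ttest(c(3, 0), c(1, 0), direction = 1)
  expect_true(is.na(fit5$p_as))
})

test_that("BH matches the brute-force step-up and Fisher combination behaves", {
  # worked case: equally spaced p-values collapse to the largest ratio
  recs <- tibble::tibble(p_geno = c(0.01, 0.02, 0.03, 0.04),
                         p_as = NA_real_)
  out <- combine_and_fdr(recs)
  expect_equal(out$fdr_pop, rep(0.04, 4))
  expect_equal(out$p_comb, out$p_geno)  # missing p_as -> fallback

  # single pair
  one <- combine_and_fdr(tibble::tibble(p_geno = 0.03, p_as = NA_real_))
  expect_equal(one$fdr_def, 0.03)

  # random p-vectors vs the oracle
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    got <- combine_and_fdr(tibble::tibble(p_geno = p, p_as = NA_real_))
    expect_equal(got$fdr_pop, bh_oracle(p), tolerance = 1e-12)
  }

  # Fisher combination is monotone non-increasing in each component
  grid <- expand.grid(pg = c(0.9, 0.5, 0.1, 0.01), pa = c(0.9, 0.5, 0.1, 0.01))
  pc <- combine_and_fdr(tibble::tibble(p_geno = grid$pg, p_as = grid$pa))$p_comb
  m <- matrix(pc, 4, 4)
  expect_true(all(diff(m) <= 1e-12))       # decreasing in p_geno
  expect_true(all(t(diff(t(m))) <= 1e-12)) # decreasing in p_as

  # empty input -> empty output
  expect_equal(nrow(combine_and_fdr(tibble::tibble(p_geno = numeric(),
                                                   p_as = numeric()))), 0L)
})
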