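ratio_profiles <- function(ratio, loops_df = NULL) {
  # profiles whose obs/exp equals `ratio` exactly (expected = 1)
  n <- nrow(ratio)
  if (is.null(loops_df)) {
    loops_df <- tibble::tibble(
      chrom = "chr1",
      b1_start = seq(0L, by = 100000L, length.out = n),
      b2_start = seq(0L, by = 100000L, length.out = n) + 50000L,
      resolution = 5000L)
  }
  contact_profiles(loops_df, ratio,
                   matrix(1, n, ncol(ratio), dimnames = dimnames(ratio)),
                   matrix(TRUE, n, ncol(ratio), dimnames = dimnames(ratio)))
}

ratio_panel <- function(dosage_vec) {
  donors <- names(dosage_vec)
  genotype_panel(
    tibble::tibble(snp_id = "rs1", chrom = "chr1", pos = 1000L,
                   ref = "A", alt = "G"),
    matrix(dosage_vec, 1, dimnames = list("rs1", donors)),
    tibble::tibble(donor = donors, depth = 1e6))
}

test_that("pooled regression: zero-residual and oracle agreement", {
  donors <- paste0("D", 1:10)
  dos <- stats::setNames(rep(c(0L, 1L, 2L), length.out = 10), donors)
  ratio <- rbind(1 + 0.5 * dos, 1 + 0.5 * dos)
  colnames(ratio) <- donors
  profs <- ratio_profiles(ratio)
  panel <- ratio_panel(dos)
  fit <- pooled_genotype_regression("rs1", profs$loops$loop_id, profs, panel)
  expect_lt(fit$p_pool, 1e-12)
  expect_true(all(fit$loop_signs == 1L))

  set.seed(41)
  ratio2 <- matrix(rnorm(30, 2, 0.3), 3, 10, dimnames = list(NULL, donors))
  profs2 <- ratio_profiles(ratio2)
  fit2 <- pooled_genotype_regression("rs1", profs2$loops$loop_id, profs2, panel)
  y <- as.vector(t(ratio2))
  x <- rep(as.numeric(dos), times = 3)
  oracle <- ols_oracle(y, cbind(1, x))
  expect_equal(fit2$p_pool, unname(oracle$p[2]), tolerance = 1e-10)
  expect_equal(fit2$slope, unname(oracle$beta[2]), tolerance = 1e-10)

  # constant ratios -> p = 1
  profs3 <- ratio_profiles(matrix(2, 2, 10, dimnames = list(NULL, donors)))
  fit3 <- pooled_genotype_regression("rs1", profs3$loops$loop_id, profs3, panel)
  expect_equal(fit3$p_pool, 1)
})

test_that("multi-loop labeling requires concordant signs and a strong pool", {
  donors <- paste0("D", 1:12)
  dos <- stats::setNames(rep(0:2, each = 4), donors)
  up <- 1 + 0.5 * as.numeric(dos)
  set.seed(42)
  noise <- function() rnorm(12, 0, 0.01)
  concordant <- rbind(up + noise(), up + noise(), up + noise())
  colnames(concordant) <- donors
  profs <- ratio_profiles(concordant)
  panel <- ratio_panel(dos)
  expect_true(label_multiloop("rs1", profs$loops$loop_id, profs, panel))

  # one loop trending the other way blocks the label regardless of p
  mixed <- rbind(up + noise(), 3 - up + noise())
  colnames(mixed) <- donors
  profs2 <- ratio_profiles(mixed)
  expect_false(label_multiloop("rs1", profs2$loops$loop_id, profs2, panel))

  # weak pooled significance fails the alpha rule
  weak <- rbind(1 + 0.02 * as.numeric(dos) + rnorm(12, 0, 0.3),
                1 + 0.02 * as.numeric(dos) + rnorm(12, 0, 0.3))
  colnames(weak) <- donors
  profs3 <- ratio_profiles(weak)
  expect_false(label_multiloop("rs1", profs3$loops$loop_id, profs3, panel))
  # a single loop can never be multi-loop
  expect_false(label_multiloop("rs1", profs$loops$loop_id[1], profs, panel))
})

test_that("component growth: isolated seeds, both-ends rule, finalization", {
  res <- 5000L
  loops <- tibble::tibble(
    chrom = "chr1",
    b1_start = c(100000L, 105000L, 300000L, 102000L %/% res * res),
    b2_start = c(200000L, 205000L, 400000L, 500000L),
    resolution = res)
  loops$loop_id <- loop_key(loops$chrom, loops$b1_start, loops$b2_start)
  # loop 4 shares the b1 neighborhood but its b2 is far: must not be added
  region <- grow_component(loops$loop_id[1], loops, slack_t = 10000)
  expect_setequal(region$loop_ids, loops$loop_id[1:2])
  expect_equal(region$r1s, 100000L)
  expect_equal(region$r1e, 105000L)
  expect_true(region$disjoint)
  expect_equal(region$A, c(100000L, 110000L))

  # single isolated loop is its own fixpoint
  lone <- grow_component(loops$loop_id[3], loops, slack_t = 10000)
  expect_equal(lone$loop_ids, loops$loop_id[3])
  expect_equal(lone$A, c(300000L, 305000L))
  expect_equal(lone$B, c(400000L, 405000L))

  expect_error(grow_component("chr1:1-2", loops), "not among")
})

test_that("growth equals the randomized single-addition closure oracle", {
  for (seed in 1:60) {
    inst <- random_loop_instance(n = sample(5:50, 1), seed = seed)
    seed_loop <- inst$loop_id[sample(nrow(inst), 1)]
    got <- grow_component(seed_loop, inst, slack_t = 10000)
    want <- grow_oracle(seed_loop, inst, slack_t = 10000,
                        order_seed = seed + 1)
    expect_equal(sort(got$loop_ids), want$loop_ids)
    expect_equal(got[c("r1s", "r1e", "r2s", "r2e", "disjoint")],
                 want[c("r1s", "r1e", "r2s", "r2e", "disjoint")])
  }
})

test_that("any seed inside a component yields the same finalized region", {
  for (seed in 61:90) {
    inst <- random_cluster_instance(n_clusters = sample(2:6, 1), seed = seed)
    first <- grow_component(inst$loop_id[1], inst, slack_t = 10000)
    for (other in first$loop_ids) {
      again <- grow_component(other, inst, slack_t = 10000)
      expect_setequal(again$loop_ids, first$loop_ids)
      expect_equal(again$A, first$A)
      expect_equal(again$B, first$B)
    }
  }
})

test_that("genotype-aggregated maps: single-cell values and donor symmetry", {
  donors <- paste0("D", 1:6)
  dos <- stats::setNames(c(0L, 0L, 1L, 1L, 2L, 2L), donors)
  ratio <- matrix(c(1, 1, 2, 2, 4, 4), 1, 6, dimnames = list(NULL, donors))
  profs <- ratio_profiles(ratio)
  panel <- ratio_panel(dos)
  region <- grow_component(profs$loops$loop_id[1], profs$loops)
  maps <- aggregate_genotype_maps("rs1", region, profs, panel)
  expect_equal(unname(maps$y), c(0, 1, 2))  # log2 of (1, 2, 4)

  # permuting donors within genotype classes leaves the maps unchanged
  perm <- c("D2", "D1", "D4", "D3", "D6", "D5")
  profs_perm <- ratio_profiles(ratio[, perm, drop = FALSE])
  panel_perm <- ratio_panel(dos[perm])
  maps_perm <- aggregate_genotype_maps("rs1", region, profs_perm, panel_perm)
  expect_equal(maps_perm$y, maps$y)

  # zero-contact cells are excluded per class, not treated as zero
  ratio0 <- ratio; ratio0[1, c("D1", "D2")] <- 0
  profs0 <- ratio_profiles(ratio0)
  maps0 <- aggregate_genotype_maps("rs1", region, profs0, panel)
  expect_true(is.na(maps0$y[["ref"]]))
})

test_that("95th percentile of a 20-cell map matches a sort-based oracle", {
  set.seed(7)
  donors <- paste0("D", 1:6)
  dos <- stats::setNames(c(0L, 0L, 1L, 1L, 2L, 2L), donors)
  res <- 5000L
  loops_df <- tibble::tibble(
    chrom = "chr1",
    b1_start = rep(seq(100000L, by = res, length.out = 5), 4),
    b2_start = rep(seq(400000L, by = res, length.out = 4), each = 5),
    resolution = res)
  ratio <- matrix(runif(20 * 6, 0.5, 4), 20, 6,
                  dimnames = list(NULL, donors))
  profs <- ratio_profiles(ratio, loops_df)
  panel <- ratio_panel(dos)
  region <- grow_component(profs$loops$loop_id[1], profs$loops)
  maps <- aggregate_genotype_maps("rs1", region, profs, panel)
  # oracle: type-7 interpolation done by hand on the sorted values
  vals <- sort(log2(rowMeans(ratio[, 1:2])))
  h <- (length(vals) - 1) * 0.95 + 1
  want <- vals[floor(h)] + (h - floor(h)) * (vals[ceiling(h)] - vals[floor(h)])
  expect_equal(unname(maps$y[["ref"]]), want, tolerance = 1e-12)
})

test_that("percentile-step criterion around the 0.1 threshold", {
  expect_true(percentile_step_test(c(0.00, 0.15, 0.32))$pass)
  expect_equal(percentile_step_test(c(0.00, 0.15, 0.32))$orientation,
               "increasing")
  expect_false(percentile_step_test(c(0.00, 0.05, 0.40))$pass)
  expect_true(percentile_step_test(c(0.50, 0.35, 0.20))$pass)
  expect_equal(percentile_step_test(c(0.50, 0.35, 0.20))$orientation,
               "decreasing")
  expect_true(percentile_step_test(c(0, 0.1, 0.2))$pass)   # steps == thr
  expect_false(percentile_step_test(c(0, 0.2, 0.1))$pass)  # non-monotone
  expect_false(percentile_step_test(c(0, NA, 0.4))$pass)   # undefined map
  expect_true(percentile_step_test(c(0, 0.05, 0.12), thr = 0.05)$pass)
})

test_that("connectivity calls satisfy each criterion individually", {
  cfg <- sim_config(n_loops = 15, n_effects = 3, n_region_loci = 2,
                    region_effect = 2, seed = 51)
  ds <- simulate_dataset(cfg, emit_read_pairs = FALSE)
  fit <- map_iqtls(ds$profiles, ds$panel, allele_records = ds$allele_records)
  conn <- call_connectivity_qtls(iqtl_calls(fit), fit$profiles, ds$panel)
  expect_true(all(!conn$called |
                    (conn$p_pool < 1e-5 & conn$bonferroni_p < 0.005)))
  for (i in which(conn$called)) {
    expect_true(percentile_step_test(
      c(conn$y_ref[i], conn$y_het[i], conn$y_alt[i]))$pass)
  }
  # identical (snp, region) pairs are evaluated once
  expect_equal(anyDuplicated(conn[, c("snp_id", "chrom", "r1s", "r1e",
                                      "r2s", "r2e")]), 0L)
  # conjunction: p_pool = tiny but flat maps must not be called
  expect_true(all(conn$called == (conn$p_pool < 1e-5 &
                                    conn$bonferroni_p < 0.005 &
                                    !is.na(conn$orientation))))
})
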