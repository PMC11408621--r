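# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately takes a different route than the package code.

# Brute-force Benjamini-Hochberg step-up: for each p_i, the q-value is the
# smallest over all j with p_(j) >= p_i of min(1, p_(j) * n / j).
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    ranks_ge <- which(p[ord] >= p[i])
    q[i] <- min(1, min(p[ord][ranks_ge] * n / ranks_ge))
  }
  q
}

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# support of cell `a` given fixed margins.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # set size
  n2 <- c + d         # control size
  k <- a + c          # annotated total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form one-sided paired-t tail.
paired_t_oracle <- function(diffs, direction) {
  n <- length(diffs)
  tt <- mean(diffs) / (sd(diffs) / sqrt(n))
  if (direction >= 0) stats::pt(tt, n - 1, lower.tail = FALSE)
  else stats::pt(tt, n - 1, lower.tail = TRUE)
}

# Least squares via the normal equations, with the standard t-based p-value
# for the slope.
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(beta = drop(beta),
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

# Naive double-loop allele counting, mirroring the stated filters verbatim.
naive_count_oracle <- function(read_pairs, pairs, panel, w = 5000,
                               min_mapq = 10, dist_range = c(1e4, 3e6)) {
  dosage <- panel$dosage
  res <- pairs$resolution[1]
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    opp <- if (p$side == "1") p$b2_start
      else if (p$side == "2") p$b1_start
      else if (abs(p$pos - p$b1_start) >= abs(p$pos - p$b2_start)) p$b1_start
      else p$b2_start
    for (d in colnames(dosage)) {
      if (is.na(dosage[p$snp_id, d]) || dosage[p$snp_id, d] != 1L) next
      refc <- altc <- 0L
      for (j in seq_len(nrow(read_pairs))) {
        r <- read_pairs[j, ]
        if (r$donor != d || r$chrom != p$chrom) next
        if (is.na(r$tag_pos) || r$tag_pos != p$pos) next
        if (r$mapq1 < min_mapq || r$mapq2 < min_mapq) next
        span <- abs(r$pos2 - r$pos1)
        if (span < dist_range[1] || span > dist_range[2]) next
        other <- if (abs(r$pos1 - r$tag_pos) <= abs(r$pos2 - r$tag_pos))
          r$pos2 else r$pos1
        if (other < opp - w || other >= opp + res + w) next
        if (r$tag_base == p$ref) refc <- refc + 1L
        else if (r$tag_base == p$alt) altc <- altc + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        snp_id = p$snp_id, loop_id = p$loop_id, donor = d,
        ref_reads = refc, alt_reads = altc)
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), snp_id, loop_id, donor)
}

# Randomized single-addition component growth + finalization; independent of
# the package's batch fixpoint.
grow_oracle <- function(seed_loop_id, sig_loops, slack_t = 10000,
                        order_seed = 1) {
  df <- as.data.frame(sig_loops)
  seed <- match(seed_loop_id, df$loop_id)
  same <- df$chrom == df$chrom[seed]
  in_s <- seq_len(nrow(df)) == seed
  set.seed(order_seed)
  repeat {
    r1s <- min(df$b1_start[in_s]); r1e <- max(df$b1_start[in_s])
    r2s <- min(df$b2_start[in_s]); r2e <- max(df$b2_start[in_s])
    cand <- which(same & !in_s &
                    df$b1_start >= r1s - slack_t & df$b1_start <= r1e + slack_t &
                    df$b2_start >= r2s - slack_t & df$b2_start <= r2e + slack_t)
    if (!length(cand)) break
    # one loop at a time, random order (sample.int avoids the scalar trap)
    in_s[cand[sample.int(length(cand), 1L)]] <- TRUE
  }
  disjoint <- r1e < r2s
  final <- if (disjoint) {
    same & df$b1_start >= r1s & df$b1_start <= r1e &
      df$b2_start >= r2s & df$b2_start <= r2e
  } else {
    same & df$b1_start >= r1s & df$b2_start <= r2e
  }
  list(loop_ids = sort(df$loop_id[final]),
       r1s = r1s, r1e = r1e, r2s = r2s, r2e = r2e, disjoint = disjoint)
}

# Random loop instance on the 5 kb grid, dense enough to form multi-loop
# components under the 10 kb slack.
random_loop_instance <- function(n, seed) {
  set.seed(seed)
  res <- 5000L
  repeat {
    b1 <- sample(seq(0L, 60L) * res, n, replace = TRUE)
    b2 <- b1 + sample(seq(4L, 30L) * res, n, replace = TRUE)
    df <- unique(data.frame(chrom = "chr1", b1_start = b1, b2_start = b2))
    if (nrow(df) >= 2L) break
  }
  df$resolution <- res
  df$loop_id <- loop_key(df$chrom, df$b1_start, df$b2_start)
  tibble::as_tibble(df)
}

# Random instance shaped like realistic loop calls: tight anchor clusters
# (pairwise within the 10 kb slack) separated by much more than the slack.
# On such instances component growth is seed-invariant; on arbitrarily
# dense instances the extrema-based growth is not (see the methods
# vignette for a three-loop counterexample).
random_cluster_instance <- function(n_clusters, seed) {
  set.seed(seed)
  res <- 5000L
  rows <- lapply(seq_len(n_clusters), function(k) {
    b1c <- 1000000L + (k - 1L) * 200000L
    b2c <- b1c + 50000L + sample(0:10, 1) * res
    m <- sample(1:6, 1)
    data.frame(
      chrom = "chr1",
      b1_start = b1c + sample(0:2, m, replace = TRUE) * res,
      b2_start = b2c + sample(0:2, m, replace = TRUE) * res)
  })
  df <- unique(do.call(rbind, rows))
  df$resolution <- res
  df$loop_id <- loop_key(df$chrom, df$b1_start, df$b2_start)
  tibble::as_tibble(df)
}

# One-row cascade record realizing a chosen clause combination.
make_cascade_record <- function(fdr_def_ok, presence, pop_sig, as_sig, aux) {
  rec <- tibble::tibble(
    fdr_def = if (fdr_def_ok) 0.01 else 0.10,
    fdr_pop = if (pop_sig) 0.01 else 0.20,
    p_as = if (as_sig) 0.01 else 0.30,
    n_g0 = if (presence) 5L else 1L, n_g1 = 15L,
    n_g2 = if (presence) 10L else 14L
  )
  # genotype direction: ascending normalized means
  norm <- c(1, 2, 3)
  raw <- if (pop_sig && !as_sig && !aux) c(1, 3, 2) else c(10, 20, 30)
  for (g in 0:2) {
    rec[[paste0("mean_raw_g", g)]] <- raw[g + 1]
    rec[[paste0("median_raw_g", g)]] <- raw[g + 1]
    rec[[paste0("mean_norm_g", g)]] <- norm[g + 1]
    rec[[paste0("median_norm_g", g)]] <- norm[g + 1]
  }
  # allelic direction: concordant (alt > ref) unless the AS branch is active
  # and aux demands discordance
  if (!pop_sig && as_sig && !aux) {
    rec$allele_ref_mean <- 8; rec$allele_alt_mean <- 4
  } else {
    rec$allele_ref_mean <- 4; rec$allele_alt_mean <- 8
  }
  rec
}

# The documented decision, written independently of the package cascade.
cascade_expected <- function(fdr_def_ok, presence, pop_sig, as_sig, aux) {
  if (!fdr_def_ok || !presence) return(FALSE)
  if (pop_sig && as_sig) return(TRUE)
  if (pop_sig && !as_sig) return(aux)    # monotone-trend clause
  if (!pop_sig && as_sig) return(aux)    # allele-concordance clause
  FALSE
}

# Small deterministic dataset reused by several files.
tiny_dataset <- function(seed = 42, ...) {
  cfg <- sim_config(n_loops = 30, n_effects = 4, n_donors = 24,
                    seed = seed, ...)
  simulate_dataset(cfg)
}
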