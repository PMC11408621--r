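#' Pooled genotype regression over a set of loops
#'
#' Stacks per-donor obs/exp contact ratios over all supplied loops and fits
#' one least-squares line against the SNP's alternate-allele dosage; the
#' p-value is the F-test for the dosage term. Per-loop slope signs come
#' from per-loop fits and feed the direction-concordance rule.
#'
#' @param snp_id SNP identifier in `panel`.
#' @param loop_ids Loop keys present in `profiles`.
#' @param profiles A [contact_profiles()] with expected counts.
#' @param panel A [genotype_panel()].
#' @return List: `p_pool`, `slope`, `n_obs`, `loop_signs` (named integer
#'   vector of per-loop slope signs).
#' @export
pooled_genotype_regression <- function(snp_id, loop_ids, profiles, panel) {
  ratios <- contact_ratios(profiles)[loop_ids, , drop = FALSE]
  dosage <- panel$dosage[snp_id, profiles$donors]
  keep <- !is.na(dosage)
  r <- ratios[, keep, drop = FALSE]
  g <- as.numeric(dosage[keep])
  y <- as.vector(t(r))            # loop-major stacking, donors fastest
  x <- rep(g, times = nrow(r))
  if (stats::var(y) < 1e-24 || length(unique(x)) < 2L) {
    return(list(p_pool = 1, slope = 0, n_obs = length(y),
                loop_signs = setNames(rep(0L, length(loop_ids)), loop_ids)))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- if (sm$sigma^2 < 1e-24) {
    if (abs(coef(fit)[["x"]]) > 0) 0 else 1
  } else {
    sm$coefficients["x", "Pr(>|t|)"]
  }
  signs <- vapply(seq_len(nrow(r)), function(i) {
    yi <- r[i, ]
    if (stats::var(yi) < 1e-24) return(0L)
    as.integer(sign(coef(lm(yi ~ g))[["g"]]))
  }, integer(1))
  list(p_pool = unname(p), slope = unname(coef(fit)[["x"]]),
       n_obs = length(y), loop_signs = setNames(signs, loop_ids))
}

#' Label a multi-loop iQTL
#'
#' An iQTL associated with more than one loop is labeled multi-loop when
#' every per-loop genotype slope has the same nonzero sign and the pooled
#' regression over all its loops is significant.
#'
#' @param snp_id SNP identifier.
#' @param loop_ids The (> 1) loops the SNP is an accepted iQTL for.
#' @param profiles,panel See [pooled_genotype_regression()].
#' @param alpha Pooled regression significance threshold (default 1e-5).
#' @return Logical.
#' @export
label_multiloop <- function(snp_id, loop_ids, profiles, panel, alpha = 1e-5) {
  if (length(loop_ids) < 2L) return(FALSE)
  fit <- pooled_genotype_regression(snp_id, loop_ids, profiles, panel)
  signs <- fit$loop_signs
  all(signs != 0L) && length(unique(signs)) == 1L && fit$p_pool < alpha
}

#' Grow a connected loop component from a seed loop
#'
#' Iterative closure over spatial adjacency: starting from the seed loop,
#' any loop whose b1 lies within `[r1s - t, r1e + t]` and whose b2 lies
#' within `[r2s - t, r2e + t]` (closed bounds on bin-start coordinates,
#' extrema over the current set) is added, extrema are updated, and the
#' procedure stops at a fixpoint. The final set is then re-derived from the
#' extremal segments `A = [r1s, r1e]` and `B = [r2s, r2e]`: when disjoint
#' (`r1e < r2s`), all significant loops with b1 in A and b2 in B; when
#' overlapping, all significant loops with both ends inside the complete
#' span `[r1s, r2e]`.
#'
#' @param seed_loop_id Loop key of the seed (must be in `sig_loops`).
#' @param sig_loops Tibble of loops significant in at least one donor
#'   (columns `loop_id`, `chrom`, `b1_start`, `b2_start`, `resolution`),
#'   same chromosome as the seed.
#' @param slack_t Adjacency slack in bp (default 10000 = two 5 kb bins).
#' @return A `component_region`: list with `loop_ids` (the finalized set S),
#'   `r1s`, `r1e`, `r2s`, `r2e`, `disjoint`, `A`, `B` (half-open segment
#'   bounds in bp), `chrom`, `resolution`.
#' @export
grow_component <- function(seed_loop_id, sig_loops, slack_t = 10000) {
  sig_loops <- as_tibble(sig_loops)
  seed <- match(seed_loop_id, sig_loops$loop_id)
  if (is.na(seed)) abort("seed loop is not among the significant loops")
  chrom <- sig_loops$chrom[seed]
  same <- sig_loops$chrom == chrom
  b1 <- sig_loops$b1_start
  b2 <- sig_loops$b2_start
  in_s <- rep(FALSE, nrow(sig_loops))
  in_s[seed] <- TRUE
  repeat {
    r1s <- min(b1[in_s]); r1e <- max(b1[in_s])
    r2s <- min(b2[in_s]); r2e <- max(b2[in_s])
    add <- same & !in_s &
      b1 >= r1s - slack_t & b1 <= r1e + slack_t &
      b2 >= r2s - slack_t & b2 <= r2e + slack_t
    if (!any(add)) break
    in_s <- in_s | add
  }
  res <- sig_loops$resolution[seed]
  disjoint <- r1e < r2s
  final <- if (disjoint) {
    same & b1 >= r1s & b1 <= r1e & b2 >= r2s & b2 <= r2e
  } else {
    same & b1 >= r1s & b2 <= r2e
  }
  structure(
    list(
      seed_loop_id = seed_loop_id,
      loop_ids = sig_loops$loop_id[final],
      r1s = r1s, r1e = r1e, r2s = r2s, r2e = r2e,
      disjoint = disjoint,
      A = c(r1s, r1e + res), B = c(r2s, r2e + res),
      chrom = chrom, resolution = res
    ),
    class = "component_region"
  )
}

#' @export
print.component_region <- function(x, ...) {
  cat(sprintf(
    "<component_region> %s: %d loop(s), A=[%d,%d) B=[%d,%d) (%s)\n",
    x$chrom, length(x$loop_ids), x$A[1], x$A[2], x$B[1], x$B[2],
    if (x$disjoint) "disjoint" else "overlapping"))
  invisible(x)
}

#' Genotype-aggregated contact maps for a component region
#'
#' Uses every contact of the region with a positive count (significant or
#' not): bin pairs with one end in segment A and the other in B when the
#' segments are disjoint, or all bin pairs inside the complete span
#' otherwise. For each genotype class of the SNP, a cell's value is the
#' mean obs/exp ratio across donors of that class having a positive contact
#' there; cells with no such donor are marked empty (`NA`) and excluded
#' from the percentile. `y_ref`, `y_het`, `y_alt` are the 95th percentiles
#' of the log2-transformed maps over non-empty cells.
#'
#' @param snp_id SNP identifier.
#' @param region A [grow_component()] result.
#' @param profiles A [contact_profiles()] with expected counts (the raw
#'   contact inventory for the region).
#' @param panel A [genotype_panel()].
#' @return A `genotype_contact_map`: list with `cells` (tibble `loop_id`,
#'   `b1_start`, `b2_start`, `m_ref`, `m_het`, `m_alt`) and `y` (named
#'   vector of 95th percentiles, `NA` when a map has no non-empty cell).
#' @export
aggregate_genotype_maps <- function(snp_id, region, profiles, panel) {
  loops <- profiles$loops
  b1 <- loops$b1_start
  b2 <- loops$b2_start
  keep <- loops$chrom == region$chrom &
    if (region$disjoint) {
      b1 >= region$r1s & b1 <= region$r1e & b2 >= region$r2s & b2 <= region$r2e
    } else {
      b1 >= region$r1s & b2 <= region$r2e
    }
  cells <- loops[keep, c("loop_id", "b1_start", "b2_start")]
  ratios <- contact_ratios(profiles)[keep, , drop = FALSE]
  obs <- profiles$observed[keep, , drop = FALSE]
  dosage <- panel$dosage[snp_id, profiles$donors]
  class_mean <- function(g) {
    cols <- !is.na(dosage) & dosage == g
    vapply(seq_len(nrow(ratios)), function(i) {
      use <- cols & obs[i, ] > 0
      if (!any(use)) NA_real_ else mean(ratios[i, use])
    }, numeric(1))
  }
  cells$m_ref <- class_mean(0L)
  cells$m_het <- class_mean(1L)
  cells$m_alt <- class_mean(2L)
  pct <- function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) return(NA_real_)
    unname(quantile(log2(v), probs = 0.95, type = 7))
  }
  structure(
    list(snp_id = snp_id, cells = cells,
         y = c(ref = pct(cells$m_ref), het = pct(cells$m_het),
               alt = pct(cells$m_alt))),
    class = "genotype_contact_map"
  )
}

#' Percentile-step criterion on genotype-aggregated maps
#'
#' The region passes when the 95th-percentile summaries `(y_ref, y_het,
#' y_alt)` are monotone increasing or decreasing with every step at least
#' `thr` (default 0.1 on the log2 scale).
#'
#' @param y Named or plain numeric vector `(y_ref, y_het, y_alt)`, or a
#'   `genotype_contact_map`.
#' @param thr Minimum step (default 0.1).
#' @return List: `pass` (logical), `orientation` (`"increasing"`,
#'   `"decreasing"` or `NA`).
#' @export
percentile_step_test <- function(y, thr = 0.1) {
  if (inherits(y, "genotype_contact_map")) y <- y$y
  if (length(y) != 3L || anyNA(y)) {
    return(list(pass = FALSE, orientation = NA_character_))
  }
  d <- diff(y)
  if (all(d >= thr)) return(list(pass = TRUE, orientation = "increasing"))
  if (all(d <= -thr)) return(list(pass = TRUE, orientation = "decreasing"))
  list(pass = FALSE, orientation = NA_character_)
}

#' Call connectivity-QTLs from an iQTL call set
#'
#' For each accepted (SNP, loop) seed: grows the loop component, pools the
#' obs/exp ratios of its loops against the SNP dosage, and retains the
#' (SNP, region) when the pooled regression p-value is below `alpha`, its
#' Bonferroni adjustment (over all evaluated (SNP, region) pairs) is below
#' `bonf_alpha`, and the genotype-aggregated maps pass the percentile-step
#' criterion. Identical (SNP, region) pairs reached from different seeds
#' are evaluated once.
#'
#' @param iqtl_calls Tibble with `snp_id` and `loop_id` (accepted iQTLs).
#' @param profiles A [contact_profiles()] with expected counts.
#' @param panel A [genotype_panel()].
#' @param alpha Pooled-regression threshold (default 1e-5).
#' @param bonf_alpha Bonferroni-adjusted threshold (default 0.005).
#' @param thr Percentile-step threshold (default 0.1).
#' @param slack_t Component-growth slack in bp (default 10000).
#' @return Tibble, one row per evaluated (SNP, region): coordinates,
#'   `disjoint`, `n_loops`, `p_pool`, `bonferroni_p`, `y_ref`, `y_het`,
#'   `y_alt`, `orientation` and the final `called` flag.
#' @export
call_connectivity_qtls <- function(iqtl_calls, profiles, panel,
                                   alpha = 1e-5, bonf_alpha = 0.005,
                                   thr = 0.1, slack_t = 10000) {
  empty <- tibble(
    snp_id = character(), chrom = character(),
    r1s = integer(), r1e = integer(), r2s = integer(), r2e = integer(),
    disjoint = logical(), n_loops = integer(), p_pool = numeric(),
    bonferroni_p = numeric(), y_ref = numeric(), y_het = numeric(),
    y_alt = numeric(), orientation = character(), called = logical()
  )
  if (nrow(iqtl_calls) == 0L) return(empty)
  sig_any <- rowSums(profiles$significant) > 0
  sig_loops <- profiles$loops[sig_any, ]
  regions <- list()
  keys <- character()
  meta <- list()
  for (i in seq_len(nrow(iqtl_calls))) {
    seed <- iqtl_calls$loop_id[i]
    if (!seed %in% sig_loops$loop_id) next
    region <- grow_component(seed, sig_loops, slack_t = slack_t)
    key <- paste(iqtl_calls$snp_id[i], region$chrom, region$r1s,
                 region$r1e, region$r2s, region$r2e, sep = "|")
    if (key %in% keys) next
    keys <- c(keys, key)
    regions <- c(regions, list(region))
    meta <- c(meta, list(iqtl_calls$snp_id[i]))
  }
  if (!length(regions)) return(empty)
  n_tests <- length(regions)
  rows <- map(seq_along(regions), function(k) {
    region <- regions[[k]]
    snp <- meta[[k]]
    fit <- pooled_genotype_regression(snp, region$loop_ids, profiles, panel)
    maps <- aggregate_genotype_maps(snp, region, profiles, panel)
    step <- percentile_step_test(maps, thr = thr)
    bonf <- min(1, fit$p_pool * n_tests)
    tibble(
      snp_id = snp, chrom = region$chrom,
      r1s = region$r1s, r1e = region$r1e,
      r2s = region$r2s, r2e = region$r2e,
      disjoint = region$disjoint,
      n_loops = length(region$loop_ids),
      p_pool = fit$p_pool, bonferroni_p = bonf,
      y_ref = unname(maps$y["ref"]), y_het = unname(maps$y["het"]),
      y_alt = unname(maps$y["alt"]),
      orientation = step$orientation %na% NA_character_,
      called = fit$p_pool < alpha && bonf < bonf_alpha && step$pass
    )
  }) |> list_rbind()
  arrange(rows, .data$chrom, .data$r1s, .data$r2e, .data$snp_id)
}
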