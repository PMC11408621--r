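#' Flag SNPs overlapping annotation intervals
#'
#' Exact overlap (`slack = 0`) flags a SNP whose position lies inside a
#' 0-based half-open interval; a positive `slack` expands every interval by
#' that many bp on each side (5000 reproduces "within 5 kb" proximity
#' matching).
#'
#' @param snps Tibble with `chrom` and `pos` columns.
#' @param intervals Tibble with `chrom`, `start`, `end` (half-open), as from
#'   [read_bed_intervals()].
#' @param slack Expansion in bp on each side (default 0 = exact overlap).
#' @return `snps` with a logical `annotated` column appended.
#' @export
interval_overlap <- function(snps, intervals, slack = 0) {
  snps <- as_tibble(snps)
  if (nrow(intervals) == 0L) return(mutate(snps, annotated = FALSE))
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(start = snps$pos + 1L, width = 1L))
  # half-open [start - slack, end + slack) -> 1-based closed
  iv_gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start - slack + 1L,
                     end = intervals$end + slack))
  # suppress the disjoint-seqlevels notice when a chromosome appears on one
  # side only: that is an ordinary no-overlap case here
  hits <- suppressWarnings(GenomicRanges::countOverlaps(snp_gr, iv_gr)) > 0
  mutate(snps, annotated = as.logical(hits))
}

#' Loop-matched control SNP sampling
#'
#' Builds the resampling null for overlap enrichment: for every loop with
#' at least one associated iQTL, draws (without replacement, globally
#' across loops) as many control SNPs as that loop has iQTLs, from the
#' pool of SNPs overlapping or within `window` bp of either anchor bin and
#' not themselves iQTLs. When a loop's pool is too small, all available
#' SNPs are taken and the shortfall is recorded.
#'
#' @param iqtl_calls Tibble with `snp_id` and `loop_id` (the accepted call
#'   set; per-loop iQTL counts are taken from it).
#' @param all_snps Tibble of the SNP universe (`snp_id`, `chrom`, `pos`).
#' @param loops Tibble of loops (`loop_id`, `chrom`, `b1_start`,
#'   `b2_start`, `resolution`).
#' @param window Anchor neighborhood in bp (default 20000).
#' @param seed Integer seed; the draw is reproducible under it.
#' @return Tibble of control SNPs (`snp_id`, `chrom`, `pos`, `loop_id`)
#'   with a `shortfall` attribute (named per-loop deficit, empty when
#'   none).
#' @export
loop_matched_null_sample <- function(iqtl_calls, all_snps, loops,
                                     window = 20000, seed = 1) {
  iqtl_ids <- unique(iqtl_calls$snp_id)
  per_loop <- iqtl_calls |> count(.data$loop_id, name = "n_iqtl")
  loops_used <- loops |> inner_join(per_loop, by = "loop_id")
  pool_all <- all_snps |> filter(!.data$snp_id %in% iqtl_ids)
  with_sim_seed(seed, 0, {
    taken <- character()
    shortfall <- integer()
    out <- map(seq_len(nrow(loops_used)), function(i) {
      l <- loops_used[i, ]
      res <- l$resolution
      pool <- pool_all |>
        filter(.data$chrom == l$chrom,
               (.data$pos >= l$b1_start - window &
                  .data$pos < l$b1_start + res + window) |
                 (.data$pos >= l$b2_start - window &
                    .data$pos < l$b2_start + res + window),
               !.data$snp_id %in% taken)
      k <- l$n_iqtl
      if (nrow(pool) < k) {
        shortfall[[l$loop_id]] <<- k - nrow(pool)
        warn(sprintf("loop %s: control pool short by %d SNP(s)",
                     l$loop_id, k - nrow(pool)))
        k <- nrow(pool)
      }
      pick <- pool[sample.int(nrow(pool), k), ]
      taken <<- c(taken, pick$snp_id)
      mutate(pick, loop_id = l$loop_id)
    }) |> list_rbind()
    attr(out, "shortfall") <- shortfall
    out
  })
}

#' Fisher's exact enrichment test on a 2x2 overlap table
#'
#' The table counts in-set and control SNPs that are / are not annotated.
#' The p-value comes from the exact hypergeometric distribution (two-sided
#' by default); the odds ratio is the cross-product `(a*d)/(b*c)` with the
#' usual 0/Inf conventions for zero cells.
#'
#' @param table Numeric `c(a, b, c, d)` = (in-set annotated, in-set not,
#'   control annotated, control not), or a 2x2 matrix in row-major layout
#'   (rows = set/control, columns = annotated/not).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return One-row tibble: `odds_ratio`, `p_value`, `a`, `b`, `c`, `d` and
#'   the exact confidence bounds `conf_lo`, `conf_hi` (two-sided only).
#' @export
fisher_enrichment <- function(table, alternative = "two.sided") {
  if (is.matrix(table)) table <- as.vector(t(table))
  stopifnot(length(table) == 4L)
  if (any(table < 0)) abort("overlap table counts must be >= 0")
  if (sum(table) == 0) abort("all-zero overlap table")
  a <- table[1]; b <- table[2]; cc <- table[3]; d <- table[4]
  m <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
  ft <- fisher.test(m, alternative = alternative, conf.int = TRUE)
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * cc)
  }
  tibble(odds_ratio = or, p_value = ft$p.value,
         a = a, b = b, c = cc, d = d,
         conf_lo = if (!is.null(ft$conf.int)) ft$conf.int[1] else NA_real_,
         conf_hi = if (!is.null(ft$conf.int)) ft$conf.int[2] else NA_real_)
}

#' Overlap-enrichment report for an iQTL set against an annotation
#'
#' Convenience wrapper: flags overlap of the iQTL set and a loop-matched
#' control set with the annotation intervals and runs [fisher_enrichment()]
#' on the resulting 2x2 table.
#'
#' @param iqtl_snps Tibble of iQTL SNPs (`snp_id`, `chrom`, `pos`).
#' @param control_snps Tibble of control SNPs (same columns), e.g. from
#'   [loop_matched_null_sample()].
#' @param intervals Annotation intervals (see [interval_overlap()]).
#' @param slack Overlap slack in bp.
#' @param set_name,annotation Labels carried into the report row.
#' @return One-row tibble combining set sizes, the table, odds ratio and
#'   p-value.
#' @export
enrichment_report <- function(iqtl_snps, control_snps, intervals, slack = 0,
                              set_name = "iqtl", annotation = "annotation") {
  set_fl <- interval_overlap(iqtl_snps, intervals, slack = slack)$annotated
  ctl_fl <- interval_overlap(control_snps, intervals, slack = slack)$annotated
  tab <- c(sum(set_fl), sum(!set_fl), sum(ctl_fl), sum(!ctl_fl))
  fisher_enrichment(tab) |>
    mutate(set_name = set_name, annotation = annotation,
           n_set = length(set_fl), n_control = length(ctl_fl),
           .before = 1)
}
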