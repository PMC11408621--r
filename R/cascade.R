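#' Per-genotype trend summary for one SNP-loop pair
#'
#' Summarises raw and depth-normalized contact counts within the three
#' genotype classes (0 = reference homozygous, 1 = heterozygous,
#' 2 = alternate homozygous) plus mean allele reads over heterozygous
#' donors; these summaries feed the filtering cascade.
#'
#' @param raw,normalized Named per-donor raw and normalized counts.
#' @param dosage Named per-donor dosages; missing genotypes are excluded.
#' @param ref_reads,alt_reads Optional per-heterozygous-donor allele reads.
#' @return One-row tibble: `n_g0..n_g2`, `mean_raw_g*`, `median_raw_g*`,
#'   `mean_norm_g*`, `median_norm_g*`, `allele_ref_mean`, `allele_alt_mean`.
#' @export
trend_summary <- function(raw, normalized, dosage,
                          ref_reads = NULL, alt_reads = NULL) {
  keep <- !is.na(dosage)
  dosage <- dosage[keep]
  raw <- raw[keep]
  normalized <- normalized[keep]
  stat <- function(fun, x, g) {
    v <- if (any(dosage == g)) fun(x[dosage == g]) else NA_real_
    v
  }
  out <- tibble(
    n_g0 = sum(dosage == 0), n_g1 = sum(dosage == 1), n_g2 = sum(dosage == 2)
  )
  for (g in 0:2) {
    out[[paste0("mean_raw_g", g)]] <- stat(mean, raw, g)
    out[[paste0("median_raw_g", g)]] <- stat(median, raw, g)
    out[[paste0("mean_norm_g", g)]] <- stat(mean, normalized, g)
    out[[paste0("median_norm_g", g)]] <- stat(median, normalized, g)
  }
  has_allele <- !is.null(ref_reads) && length(ref_reads) > 0
  out$allele_ref_mean <- if (has_allele) mean(ref_reads) else NA_real_
  out$allele_alt_mean <- if (has_allele) mean(alt_reads) else NA_real_
  out
}

#' Cascade condition 1: all genotypes present in at least two donors
#'
#' @param trend A [trend_summary()] row.
#' @return `TRUE` iff each genotype class has `>= 2` donors.
#' @export
genotype_presence <- function(trend) {
  trend$n_g0 >= 2 & trend$n_g1 >= 2 & trend$n_g2 >= 2
}

#' Cascade condition 3: strictly monotone genotype trend
#'
#' TRUE iff, for at least one statistic (mean or median), the per-genotype
#' values are strictly monotone across g0 -> g1 -> g2 in *both* the raw and
#' the normalized counts, with the same orientation in both series.
#'
#' @param trend A [trend_summary()] row; all three classes must be
#'   non-empty (gate on [genotype_presence()] first).
#' @return Logical.
#' @export
monotone_trend <- function(trend) {
  mono <- function(a, b, c) {
    if (anyNA(c(a, b, c))) return(0L)
    if (a < b && b < c) return(1L)
    if (a > b && b > c) return(-1L)
    0L
  }
  one <- function(stat) {
    r <- mono(trend[[paste0(stat, "_raw_g0")]],
              trend[[paste0(stat, "_raw_g1")]],
              trend[[paste0(stat, "_raw_g2")]])
    n <- mono(trend[[paste0(stat, "_norm_g0")]],
              trend[[paste0(stat, "_norm_g1")]],
              trend[[paste0(stat, "_norm_g2")]])
    r != 0L && r == n
  }
  one("mean") || one("median")
}

#' Cascade condition 4: allele reads follow the genotype trend
#'
#' TRUE iff the allelic direction (mean alt reads minus mean ref reads over
#' heterozygous donors) matches the genotype direction (mean normalized
#' count at the alternate homozygous class minus the reference homozygous
#' class), both being nonzero.
#'
#' @param trend A [trend_summary()] row.
#' @return Logical.
#' @export
allele_concordance <- function(trend) {
  a <- trend$allele_alt_mean - trend$allele_ref_mean
  g <- trend$mean_norm_g2 - trend$mean_norm_g0
  if (anyNA(c(a, g))) return(FALSE)
  sign(a) != 0 && sign(a) == sign(g)
}

#' Default cascade thresholds
#'
#' @param fdr_def,fdr_pop,p_as Significance thresholds (all default 0.05).
#' @return Named list of thresholds.
#' @export
iqtl_thresholds <- function(fdr_def = 0.05, fdr_pop = 0.05, p_as = 0.05) {
  list(fdr_def = fdr_def, fdr_pop = fdr_pop, p_as = p_as)
}

#' Apply the four-condition filtering cascade
#'
#' Turns significant associations into the final iQTL call set. A pair is
#' accepted iff all of the following hold: (a) `fdr_def` below threshold;
#' (b) every genotype class present in at least two donors; (c) when the
#' genotype-only model is not significant (`fdr_pop >=` threshold), the
#' allele-paired test must be (`p_as <` threshold) *and* (e) the allele
#' direction must match the genotype direction; (d) when the genotype-only
#' model is significant but the allele test is missing or non-significant,
#' the per-genotype counts must show a strictly monotone trend. The reason
#' code names the first failed clause (ordered `fdr_def`, `presence`, then
#' the branch clause); accepted rows record which branch admitted them
#' (`"both"`, `"pop_trend"` or `"as"`).
#'
#' @param records Tibble carrying `fdr_def`, `fdr_pop`, `p_as` and the
#'   [trend_summary()] columns (one row per pair).
#' @param thresholds See [iqtl_thresholds()].
#' @return `records` with `accepted`, `branch`, `reason` appended.
#' @export
apply_filter_cascade <- function(records, thresholds = iqtl_thresholds()) {
  records <- as_tibble(records)
  needed <- c("fdr_def", "fdr_pop", "p_as", "n_g0", "n_g1", "n_g2")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    abort(paste0("records lack cascade inputs: ", paste(miss, collapse = ", ")))
  }
  decide <- function(row) {
    if (is.na(row$fdr_def) || row$fdr_def >= thresholds$fdr_def) {
      return(c(FALSE, NA, "fdr_def"))
    }
    if (!genotype_presence(row)) return(c(FALSE, NA, "presence"))
    as_sig <- !is.na(row$p_as) && row$p_as < thresholds$p_as
    pop_sig <- !is.na(row$fdr_pop) && row$fdr_pop < thresholds$fdr_pop
    if (!pop_sig) {
      if (!as_sig) return(c(FALSE, NA, "p_as"))
      if (!allele_concordance(row)) return(c(FALSE, NA, "concordance"))
      return(c(TRUE, "as", NA))
    }
    if (as_sig) return(c(TRUE, "both", NA))
    if (!monotone_trend(row)) return(c(FALSE, NA, "trend"))
    c(TRUE, "pop_trend", NA)
  }
  dec <- map(seq_len(nrow(records)), function(i) decide(records[i, ]))
  records$accepted <- map_lgl(dec, ~ as.logical(.x[1]))
  records$branch <- map_chr_na(dec, 2L)
  records$reason <- map_chr_na(dec, 3L)
  records
}

map_chr_na <- function(x, i) {
  vapply(x, function(v) {
    out <- v[i]
    if (is.na(out)) NA_character_ else as.character(out)
  }, character(1))
}
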