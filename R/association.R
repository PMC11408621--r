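#' Depth-normalize raw contact counts
#'
#' Counts-per-million scaling by each donor's valid cis read-pair total:
#' `normalized = raw * 1e6 / depth`. Zeros are preserved, and scaling every
#' depth by a common constant leaves all downstream test statistics
#' unchanged.
#'
#' @param observed Numeric matrix (loops x donors).
#' @param depth Named numeric vector of per-donor depths (names matching the
#'   columns of `observed`), or a [genotype_panel()] whose covariates carry
#'   a `depth` column.
#' @return Matrix of normalized counts with the same dimensions.
#' @export
normalize_counts <- function(observed, depth) {
  if (inherits(depth, "genotype_panel")) {
    depth <- setNames(depth$covariates$depth, depth$covariates$donor)
  }
  if (is.null(names(depth))) names(depth) <- colnames(observed)
  depth <- depth[colnames(observed)]
  if (anyNA(depth) || any(depth <= 0)) abort("invalid donor depths")
  sweep(observed, 2L, depth, "/") * 1e6
}

#' Estimate expected contact counts from distance decay
#'
#' Substitute for an expected-count column when the loop table lacks one:
#' per donor, loops are grouped into log-spaced distance strata (default 8
#' per decade) and the expected count of a loop is its stratum's mean
#' observed count; strata with zero mean receive a 0.5 pseudocount so the
#' expected count is always positive.
#'
#' @param profiles A [contact_profiles()] object.
#' @param per_decade Number of strata per distance decade.
#' @return The profiles with the `expected` matrix filled in.
#' @export
estimate_expected_counts <- function(profiles, per_decade = 8) {
  n_loops <- nrow(profiles$loops)
  if (n_loops < 20) abort("need >= 20 loops per donor to estimate expected counts")
  if (any(colSums(profiles$observed) == 0)) {
    abort("donor with all-zero counts; cannot estimate expected counts")
  }
  stratum <- distance_stratum(profiles$loops$distance, per_decade)
  expected <- apply(profiles$observed, 2L, function(obs) {
    means <- tapply(obs, stratum, mean)
    e <- as.numeric(means[as.character(stratum)])
    e[e == 0] <- 0.5
    e
  })
  dimnames(expected) <- dimnames(profiles$observed)
  profiles$expected <- expected
  profiles
}

#' Genotype-trend test for one SNP-loop pair
#'
#' Ordinary least squares of `log2(normalized count + 1)` on the
#' alternate-allele dosage (0/1/2), optionally adjusted for categorical
#' donor covariates; the reported p-value is the F-test for the dosage term
#' (equivalently the squared-t test, dosage being a single degree of
#' freedom) and the slope sign defines the genotype trend direction.
#'
#' @param normalized Named per-donor normalized counts.
#' @param dosage Named per-donor dosages in `{0, 1, 2, NA}`; donors with a
#'   missing genotype are excluded.
#' @param covariates Optional tibble with `donor` plus categorical columns
#'   (`sex`, `age_group`, `race`); depth must enter via normalization, not
#'   here.
#' @return A one-row tibble: `p_geno`, `slope`, `n_used`, `testable`.
#' @export
genotype_trend_test <- function(normalized, dosage, covariates = NULL) {
  donors <- names(normalized) %||% names(dosage)
  if (!is.null(names(dosage))) dosage <- dosage[donors]
  keep <- !is.na(dosage) & !is.na(normalized)
  y <- log2(normalized[keep] + 1)
  g <- as.numeric(dosage[keep])
  n <- length(y)
  untestable <- tibble(p_geno = NA_real_, slope = NA_real_,
                       n_used = n, testable = FALSE)
  if (n < 3 || length(unique(g)) < 2L) return(untestable)
  df <- tibble(y = y, g = g)
  form <- y ~ g
  if (!is.null(covariates)) {
    cov <- as_tibble(covariates)
    cov <- cov[match(donors[keep], cov$donor), , drop = FALSE]
    keep_cols <- setdiff(names(cov), c("donor", "depth"))
    for (cl in keep_cols) {
      v <- factor(cov[[cl]])
      if (nlevels(v) > 1L) df[[cl]] <- v
    }
    terms <- setdiff(names(df), "y")
    form <- stats::reformulate(terms, response = "y")
  }
  fit <- lm(form, data = df)
  if (fit$df.residual < 4L) return(untestable)
  slope <- coef(fit)[["g"]]
  if (is.na(slope)) return(untestable)
  if (stats::var(y) < 1e-24) {
    return(tibble(p_geno = 1, slope = 0, n_used = n, testable = TRUE))
  }
  sm <- summary(fit)
  sigma2 <- sm$sigma^2
  if (!is.finite(sigma2) || sigma2 < 1e-24) {
    # numerically perfect fit
    p <- if (abs(slope) > 0) 0 else 1
    return(tibble(p_geno = p, slope = unname(slope), n_used = n,
                  testable = TRUE))
  }
  p <- sm$coefficients["g", "Pr(>|t|)"]
  tibble(p_geno = unname(p), slope = unname(slope), n_used = n,
         testable = TRUE)
}

#' One-sided paired t-test on allele-specific reads
#'
#' Tests per-donor differences `alt_reads - ref_reads` across heterozygous
#' donors with at least one allele-assignable read, one-sided in the
#' supplied direction (normally the sign of the genotype-trend slope; when
#' that is unavailable, the sign of the observed mean difference).
#'
#' @param ref_reads,alt_reads Per-donor allele read counts (heterozygous
#'   donors only).
#' @param direction Numeric; only its sign is used. `0` falls back to the
#'   sign of the mean difference.
#' @param min_donors Minimum usable donors (default 3); below it `p_as` is
#'   `NA` and the cascade cannot use the allele-specific branch.
#' @return One-row tibble: `p_as`, `mean_diff`, `n_het_used`.
#' @export
allele_paired_ttest <- function(ref_reads, alt_reads, direction = 0,
                                min_donors = 3) {
  usable <- (ref_reads + alt_reads) > 0 & !is.na(ref_reads) & !is.na(alt_reads)
  d <- (alt_reads - ref_reads)[usable]
  n <- length(d)
  if (n < min_donors) {
    return(tibble(p_as = NA_real_, mean_diff = if (n > 0) mean(d) else
      NA_real_, n_het_used = n))
  }
  m <- mean(d)
  s <- sd(d)
  dir <- sign(direction)
  if (dir == 0) dir <- sign(m)
  if (s == 0) {
    # degenerate: t -> +/-Inf in the tested direction
    p <- if (m == 0) 1 else if (sign(m) == dir) 0 else 1
    return(tibble(p_as = p, mean_diff = m, n_het_used = n))
  }
  tstat <- m / (s / sqrt(n))
  p <- if (dir >= 0) {
    pt(tstat, df = n - 1, lower.tail = FALSE)
  } else {
    pt(tstat, df = n - 1, lower.tail = TRUE)
  }
  tibble(p_as = p, mean_diff = m, n_het_used = n)
}

#' Combine test p-values and control the FDR
#'
#' Adds `p_comb` (Fisher's combination of `p_geno` and `p_as` where the
#' allele-specific p exists, else `p_geno` alone), `fdr_def`
#' (Benjamini-Hochberg over `p_comb`: the combined-model significance) and
#' `fdr_pop` (BH over `p_geno`: the genotype-only significance). BH is the
#' step-up procedure with monotonicity enforcement; the multiple-testing
#' family is all testable pairs in `records`.
#'
#' @param records Tibble with `p_geno` (`NA` = untestable) and `p_as`
#'   columns.
#' @return `records` with `p_comb`, `fdr_def`, `fdr_pop` appended.
#' @export
combine_and_fdr <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    return(mutate(records, p_comb = numeric(0), fdr_def = numeric(0),
                  fdr_pop = numeric(0)))
  }
  clamp <- function(p) pmin(pmax(p, 1e-300), 1)
  p_geno <- records$p_geno
  p_as <- records$p_as
  p_comb <- ifelse(
    is.na(p_as), p_geno,
    pchisq(-2 * (log(clamp(p_geno)) + log(clamp(p_as))),
           df = 4, lower.tail = FALSE)
  )
  testable <- !is.na(p_geno)
  fdr_def <- fdr_pop <- rep(NA_real_, nrow(records))
  fdr_def[testable] <- p.adjust(p_comb[testable], method = "BH")
  fdr_pop[testable] <- p.adjust(p_geno[testable], method = "BH")
  records$p_comb <- p_comb
  records$fdr_def <- fdr_def
  records$fdr_pop <- fdr_pop
  records
}
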