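#' Construct a genotype panel
#'
#' A genotype panel bundles bi-allelic SNP metadata, the donor-by-SNP
#' alternate-allele dosage matrix and per-donor covariates. Dosage encodes the
#' three genotype classes: 0 = reference homozygous (0|0), 1 = heterozygous
#' (0|1), 2 = alternate homozygous (1|1); `NA` marks a missing call.
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`. Only autosomal, strictly bi-allelic SNVs are accepted.
#' @param dosage Integer matrix, one row per SNP, one column per donor,
#'   entries in `{0, 1, 2, NA}`. Row names must equal `snps$snp_id`.
#' @param covariates Tibble with a `donor` column matching the dosage
#'   column names, a numeric `depth` column (valid cis read pairs used for
#'   depth normalisation), and optional categorical columns (`sex`,
#'   `age_group`, `race`) used as regression covariates.
#' @param autosomes Character vector of admissible chromosome labels.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(snps, dosage, covariates,
                           autosomes = default_autosomes()) {
  snps <- as_tibble(snps)
  stopifnot(all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(snps)))
  if (anyDuplicated(snps$snp_id) > 0L) abort("duplicate snp_id in panel")
  bad_chr <- setdiff(unique(snps$chrom), autosomes)
  if (length(bad_chr)) {
    abort(paste0("non-autosomal chromosomes in panel: ",
                 paste(bad_chr, collapse = ", ")))
  }
  if (any(snps$pos < 0)) abort("SNP positions must be >= 0 (0-based)")
  if (any(snps$ref == snps$alt)) abort("ref and alt alleles must differ")
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(snps)) {
    abort("dosage must have one row per SNP")
  }
  rownames(dosage) <- snps$snp_id
  if (is.null(colnames(dosage))) abort("dosage needs donor column names")
  if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage))) {
    abort("dosage entries must be 0, 1, 2 or NA")
  }
  covariates <- as_tibble(covariates)
  stopifnot("donor" %in% names(covariates))
  if (!setequal(covariates$donor, colnames(dosage))) {
    abort("covariate donors do not match dosage columns")
  }
  covariates <- covariates[match(colnames(dosage), covariates$donor), ]
  structure(
    list(snps = snps, donors = colnames(dosage), dosage = dosage,
         covariates = covariates),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d SNPs x %d donors on %d chromosome(s)\n",
              nrow(x$snps), length(x$donors),
              length(unique(x$snps$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%; covariates: %s\n", 100 * miss,
              paste(setdiff(names(x$covariates), "donor"), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.genotype_panel <- function(x, ...) {
  as_tibble(x$dosage, rownames = "snp_id") |>
    pivot_longer(-"snp_id", names_to = "donor", values_to = "dosage") |>
    left_join(x$snps, by = "snp_id") |>
    select("snp_id", "chrom", "pos", "ref", "alt", "donor", "dosage")
}

#' Construct a set of donor-resolved contact profiles
#'
#' A contact-profile object holds the union of loops across donors together
#' with per-donor observed counts, expected (distance-decay) counts and
#' per-donor significance flags (FDR < 0.01 loop calls as supplied or
#' simulated). Loops absent from a donor carry observed = 0 and
#' significant = FALSE.
#'
#' @param loops Tibble with columns `chrom`, `b1_start`, `b2_start`,
#'   `resolution`; anchors are `[start, start + resolution)` bins with
#'   `b1_start < b2_start`, starts multiples of the resolution.
#' @param observed,expected Numeric matrices (loops x donors); `expected`
#'   may be `NULL` when the source table lacks it (estimate it with
#'   [estimate_expected_counts()]).
#' @param significant Logical matrix (loops x donors).
#' @param dist_range Admissible anchor distance range in bp.
#'
#' @return An object of class `contact_profiles`.
#' @export
contact_profiles <- function(loops, observed, expected = NULL, significant,
                             dist_range = c(10000, 3000000)) {
  loops <- as_tibble(loops)
  stopifnot(all(c("chrom", "b1_start", "b2_start", "resolution") %in% names(loops)))
  res <- unique(loops$resolution)
  if (length(res) > 1L) abort("mixed resolutions in one loop set")
  if (any(loops$b1_start %% loops$resolution != 0) ||
      any(loops$b2_start %% loops$resolution != 0)) {
    abort("anchor starts must be multiples of the resolution")
  }
  if (any(loops$b1_start >= loops$b2_start)) {
    abort("loops must satisfy b1_start < b2_start")
  }
  loops <- loops |>
    mutate(distance = .data$b2_start - .data$b1_start)
  if (any(loops$distance < dist_range[1] | loops$distance > dist_range[2])) {
    abort(sprintf("loop distances must lie in [%d, %d]",
                  dist_range[1], dist_range[2]))
  }
  if (!"loop_id" %in% names(loops)) {
    loops$loop_id <- loop_key(loops$chrom, loops$b1_start, loops$b2_start)
  }
  if (anyDuplicated(loops$loop_id) > 0L) abort("duplicate loops")
  observed <- as.matrix(observed)
  significant <- as.matrix(significant)
  storage.mode(significant) <- "logical"
  if (nrow(observed) != nrow(loops)) abort("observed rows must match loops")
  if (any(observed < 0)) abort("observed counts must be non-negative")
  if (is.null(colnames(observed))) abort("observed needs donor column names")
  if (!is.null(expected)) {
    expected <- as.matrix(expected)
    if (!all(dim(expected) == dim(observed))) abort("expected dims mismatch")
    if (any(expected <= 0)) abort("expected counts must be positive")
    colnames(expected) <- colnames(observed)
  }
  if (!all(dim(significant) == dim(observed))) abort("significant dims mismatch")
  colnames(significant) <- colnames(observed)
  rownames(observed) <- loops$loop_id
  if (!is.null(expected)) rownames(expected) <- loops$loop_id
  rownames(significant) <- loops$loop_id
  structure(
    list(loops = loops, donors = colnames(observed), observed = observed,
         expected = expected, significant = significant,
         resolution = res, dist_range = dist_range),
    class = "contact_profiles"
  )
}

#' Canonical loop key
#'
#' @param chrom,b1_start,b2_start Loop coordinates (anchor bin starts).
#' @return Character key, stable across the package and its files.
#' @export
loop_key <- function(chrom, b1_start, b2_start) {
  sprintf("%s:%d-%d", chrom, as.integer(b1_start), as.integer(b2_start))
}

#' @export
print.contact_profiles <- function(x, ...) {
  cat(sprintf("<contact_profiles> %d loops x %d donors (%d bp bins)\n",
              nrow(x$loops), length(x$donors), x$resolution))
  cat(sprintf("  distance range %s-%s bp; expected counts: %s\n",
              format(min(x$loops$distance), big.mark = ","),
              format(max(x$loops$distance), big.mark = ","),
              if (is.null(x$expected)) "absent" else "present"))
  invisible(x)
}

#' @export
tidy.contact_profiles <- function(x, ...) {
  to_long <- function(m, name) {
    as_tibble(m, rownames = "loop_id") |>
      pivot_longer(-"loop_id", names_to = "donor", values_to = name)
  }
  long <- to_long(x$observed, "observed") |>
    left_join(to_long(x$significant, "significant"),
              by = c("loop_id", "donor"))
  if (!is.null(x$expected)) {
    long <- long |>
      left_join(to_long(x$expected, "expected"), by = c("loop_id", "donor")) |>
      mutate(ratio = .data$observed / .data$expected)
  }
  left_join(long, x$loops, by = "loop_id") |>
    relocate("chrom", "b1_start", "b2_start", .after = "loop_id")
}

#' Observed/expected contact ratios
#'
#' @param profiles A [contact_profiles()] object with expected counts.
#' @return Numeric matrix of obs/exp ratios (loops x donors).
#' @export
contact_ratios <- function(profiles) {
  if (is.null(profiles$expected)) {
    abort("profiles lack expected counts; run estimate_expected_counts() first")
  }
  profiles$observed / profiles$expected
}

#' Restrict a contact-profile set to selected loops or donors
#'
#' @param profiles A [contact_profiles()] object.
#' @param loop_ids Optional loop keys to keep.
#' @param donors Optional donor ids to keep.
#' @return A [contact_profiles()] object.
#' @export
filter_profiles <- function(profiles, loop_ids = NULL, donors = NULL) {
  keep_l <- if (is.null(loop_ids)) seq_len(nrow(profiles$loops)) else
    match(loop_ids, profiles$loops$loop_id)
  if (anyNA(keep_l)) abort("unknown loop_id in filter_profiles()")
  keep_d <- if (is.null(donors)) seq_along(profiles$donors) else
    match(donors, profiles$donors)
  if (anyNA(keep_d)) abort("unknown donor in filter_profiles()")
  contact_profiles(
    loops = profiles$loops[keep_l, setdiff(names(profiles$loops), "distance")],
    observed = profiles$observed[keep_l, keep_d, drop = FALSE],
    expected = if (!is.null(profiles$expected))
      profiles$expected[keep_l, keep_d, drop = FALSE],
    significant = profiles$significant[keep_l, keep_d, drop = FALSE],
    dist_range = profiles$dist_range
  )
}
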