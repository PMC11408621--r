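#' Read bi-allelic autosomal genotypes from a VCF
#'
#' Parses a VCF 4.x file (via `VariantAnnotation::readVcf()`), keeping only
#' strictly bi-allelic SNVs on the configured autosomes. Positions are
#' converted from the 1-based VCF convention to the package-wide 0-based
#' convention; dosage is the count of alternate alleles in the GT field, with
#' missing calls stored as `NA`. Records skipped by the bi-allelic/SNV/
#' autosome filters are tallied in the `skip_log` attribute.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param donor_subset Optional character vector of donors to keep (all
#'   donors must be present in the VCF header).
#' @param covariates Optional tibble of per-donor covariates (see
#'   [genotype_panel()]); when `NULL` a depth-only placeholder of 1e6 read
#'   pairs per donor is attached so depth normalisation is a no-op.
#' @param autosomes Admissible chromosome labels.
#'
#' @return A [genotype_panel()] with a `skip_log` attribute (named counts of
#'   skipped records).
#' @export
read_genotype_vcf <- function(path, donor_subset = NULL, covariates = NULL,
                              autosomes = default_autosomes()) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) abort("VCF lacks a GT genotype field")
  donors <- colnames(gt)
  if (!is.null(donor_subset)) {
    missing_d <- setdiff(donor_subset, donors)
    if (length(missing_d)) {
      abort(paste0("donors absent from VCF header: ",
                   paste(missing_d, collapse = ", ")))
    }
    gt <- gt[, donor_subset, drop = FALSE]
    donors <- donor_subset
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1L] <- as.character(unlist(alt_list[n_alt == 1L]))

  keep_bi <- n_alt == 1L
  keep_snv <- keep_bi & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 != "" & ref != alt1
  keep_auto <- chrom %in% autosomes
  keep <- keep_snv & keep_auto
  skip_log <- c(
    multi_allelic = sum(!keep_bi),
    non_snv = sum(keep_bi & !keep_snv),
    non_autosomal = sum(keep_snv & !keep_auto)
  )

  ids <- names(rr) %||% paste0("snp", seq_along(rr))
  snps <- tibble(
    snp_id = ids[keep],
    chrom = chrom[keep],
    pos = GenomicRanges::start(rr)[keep] - 1L,  # 1-based VCF -> 0-based
    ref = ref[keep],
    alt = alt1[keep]
  )
  dosage <- gt_to_dosage(gt[keep, , drop = FALSE])
  if (is.null(covariates)) {
    covariates <- tibble(donor = donors, depth = 1e6)
  } else {
    covariates <- as_tibble(covariates)
    no_cov <- setdiff(donors, covariates$donor)
    if (length(no_cov)) {
      abort(paste0("covariates missing for donors: ",
                   paste(no_cov, collapse = ", ")))
    }
    covariates <- covariates[covariates$donor %in% donors, ]
  }
  panel <- genotype_panel(snps, dosage, covariates, autosomes = autosomes)
  attr(panel, "skip_log") <- skip_log
  panel
}

# "0|1", "0/1", "." etc -> alt-allele dosage; anything unparseable is NA.
gt_to_dosage <- function(gt) {
  parse1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    suppressWarnings(n <- as.integer(alleles))
    if (anyNA(n) || any(n > 1L)) return(NA_integer_)
    sum(n)
  }
  out <- vapply(gt, parse1, integer(1))
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only genotypes using phased-style separators
#' (`0|0`, `0|1`, `1|1`, `.` for missing). Internal 0-based positions are
#' converted back to the 1-based VCF convention, so a write/read round trip
#' through [read_genotype_vcf()] recovers the dosage matrix exactly.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(panel, path) {
  gt_codes <- c("0|0", "0|1", "1|1")
  snps <- panel$snps |> arrange(.data$chrom, .data$pos, .data$snp_id)
  dos <- panel$dosage[snps$snp_id, , drop = FALSE]
  gt <- matrix(".", nrow = nrow(dos), ncol = ncol(dos))
  idx <- !is.na(dos)
  gt[idx] <- gt_codes[dos[idx] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$donors), collapse = "\t")
  )
  body <- paste(snps$chrom, snps$pos + 1L, snps$snp_id, snps$ref, snps$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read the multi-donor loop-table dialect
#'
#' The dialect is a TSV with anchor columns `chr1 s1 e1 chr2 s2 e2`
#' followed, per donor, by `<donor>_obs`, `<donor>_exp`, `<donor>_sig`
#' (expected columns may be absent). Alternatively a character vector of
#' per-donor FitHiChIP-style files (`chr1 s1 e1 chr2 s2 e2 obs [exp] [sig]`)
#' is unioned: loops are keyed by `(chrom, b1_start, b2_start)`; donors
#' missing a loop get observed = 0, significant = FALSE. Inter-chromosomal
#' rows are rejected; unsorted anchors are swapped with a warning; rows
#' outside `dist_range` are dropped with a message.
#'
#' @param path_or_paths One multi-donor TSV, or a named character vector of
#'   per-donor files (names are donor ids; unnamed paths use the file stem).
#' @param resolution Bin size in bp (anchor spans must equal it).
#' @param dist_range Admissible anchor distance range in bp.
#'
#' @return A [contact_profiles()] object.
#' @export
read_loop_table <- function(path_or_paths, resolution = 5000,
                            dist_range = c(10000, 3000000)) {
  paths <- path_or_paths
  if (length(paths) == 1L && is.null(names(paths))) {
    return(read_loop_table_multi(paths, resolution, dist_range))
  }
  donors <- names(paths) %||% tools::file_path_sans_ext(basename(paths))
  if (is.null(names(paths))) names(paths) <- donors
  per_donor <- imap(paths, function(p, d) {
    raw <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    names(raw)[1:6] <- c("chr1", "s1", "e1", "chr2", "s2", "e2")
    obs_col <- intersect(c("obs", "cc", "observed"), names(raw))[1]
    if (is.na(obs_col)) abort(sprintf("%s: no observed-count column", p))
    exp_col <- intersect(c("exp", "expected", "exp_cc"), names(raw))[1]
    sig_col <- intersect(c("sig", "significant"), names(raw))[1]
    tibble(
      chr1 = raw$chr1, s1 = raw$s1, e1 = raw$e1,
      chr2 = raw$chr2, s2 = raw$s2, e2 = raw$e2,
      donor = d,
      observed = raw[[obs_col]],
      expected = if (!is.na(exp_col)) raw[[exp_col]] else NA_real_,
      significant = if (!is.na(sig_col)) as.logical(raw[[sig_col]]) else TRUE
    )
  }) |> list_rbind()
  long_to_profiles(per_donor, donors, resolution, dist_range)
}

read_loop_table_multi <- function(path, resolution, dist_range) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("chr1", "s1", "e1", "chr2", "s2", "e2") %in% names(raw)))
  obs_cols <- grep("_obs$", names(raw), value = TRUE)
  if (!length(obs_cols)) abort("multi-donor table has no *_obs columns")
  donors <- sub("_obs$", "", obs_cols)
  per_donor <- map(donors, function(d) {
    tibble(
      chr1 = raw$chr1, s1 = raw$s1, e1 = raw$e1,
      chr2 = raw$chr2, s2 = raw$s2, e2 = raw$e2,
      donor = d,
      observed = raw[[paste0(d, "_obs")]],
      expected = if (paste0(d, "_exp") %in% names(raw))
        raw[[paste0(d, "_exp")]] else NA_real_,
      significant = if (paste0(d, "_sig") %in% names(raw))
        as.logical(raw[[paste0(d, "_sig")]]) else TRUE
    )
  }) |> list_rbind()
  long_to_profiles(per_donor, donors, resolution, dist_range)
}

long_to_profiles <- function(per_donor, donors, resolution, dist_range) {
  if (any(per_donor$chr1 != per_donor$chr2)) {
    abort("inter-chromosomal loop rows are not allowed")
  }
  if (any(per_donor$e1 - per_donor$s1 != resolution) ||
      any(per_donor$e2 - per_donor$s2 != resolution)) {
    abort(sprintf("anchor spans must equal the resolution (%d bp)", resolution))
  }
  swap <- per_donor$s1 > per_donor$s2
  if (any(swap)) {
    warn(sprintf("%d row(s) had unsorted anchors; swapped", sum(swap)))
    tmp <- per_donor$s1[swap]
    per_donor$s1[swap] <- per_donor$s2[swap]
    per_donor$s2[swap] <- tmp
  }
  dist <- per_donor$s2 - per_donor$s1
  in_range <- dist >= dist_range[1] & dist <= dist_range[2]
  if (any(!in_range)) {
    inform(sprintf("dropped %d row(s) outside the %d-%d bp distance range",
                   sum(!in_range), dist_range[1], dist_range[2]))
    per_donor <- per_donor[in_range, ]
  }
  per_donor$loop_id <- loop_key(per_donor$chr1, per_donor$s1, per_donor$s2)
  loops <- per_donor |>
    distinct(.data$loop_id, chrom = .data$chr1, b1_start = .data$s1,
             b2_start = .data$s2) |>
    arrange(.data$chrom, .data$b1_start, .data$b2_start) |>
    mutate(resolution = resolution)
  wide <- function(col, fill) {
    m <- matrix(fill, nrow = nrow(loops), ncol = length(donors),
                dimnames = list(loops$loop_id, donors))
    i <- match(per_donor$loop_id, loops$loop_id)
    j <- match(per_donor$donor, donors)
    vals <- per_donor[[col]]
    ok <- !is.na(vals)
    m[cbind(i[ok], j[ok])] <- vals[ok]
    m
  }
  obs <- wide("observed", 0)
  sig <- wide("significant", FALSE)
  has_exp <- !all(is.na(per_donor$expected))
  expd <- if (has_exp) {
    e <- wide("expected", NA_real_)
    if (anyNA(e)) {
      # donors missing a union loop: fall back to the loop's mean expected
      row_mean <- rowMeans(e, na.rm = TRUE)
      e[is.na(e)] <- row_mean[row(e)[is.na(e)]]
    }
    e
  }
  contact_profiles(loops, obs, expd, sig, dist_range = dist_range)
}

#' Write contact profiles in the multi-donor loop-table dialect
#'
#' @param profiles A [contact_profiles()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loop_table <- function(profiles, path) {
  loops <- profiles$loops |>
    arrange(.data$chrom, .data$b1_start, .data$b2_start)
  ord <- match(loops$loop_id, profiles$loops$loop_id)
  out <- tibble(
    chr1 = loops$chrom, s1 = loops$b1_start,
    e1 = loops$b1_start + loops$resolution,
    chr2 = loops$chrom, s2 = loops$b2_start,
    e2 = loops$b2_start + loops$resolution
  )
  for (d in profiles$donors) {
    out[[paste0(d, "_obs")]] <- profiles$observed[ord, d]
    if (!is.null(profiles$expected)) {
      out[[paste0(d, "_exp")]] <- profiles$expected[ord, d]
    }
    out[[paste0(d, "_sig")]] <- profiles$significant[ord, d]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read BED intervals
#'
#' Reads a BED3+ file into a tibble of 0-based half-open intervals, sorted
#' within chromosome. Overlapping intervals are retained un-merged.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end` (and `name` if
#'   present), sorted by `(chrom, start, end)`.
#' @export
read_bed_intervals <- function(path) {
  if (file.size(path) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr)
  )
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  if (any(out$start > out$end)) abort("BED interval with start > end")
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Read / write the read-pair TSV dialect
#'
#' Read pairs carry one row per paired-end cis contact: donor, chromosome,
#' the 5'-most mapped coordinate of each end (`pos1`, `pos2`), mapping
#' qualities, and an optional allele tag (`tag_pos`, `tag_base`) for ends
#' overlapping a SNP.
#'
#' @param path File path.
#' @return Tibble of read pairs.
#' @export
read_read_pairs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    donor = "c", chrom = "c", pos1 = "i", pos2 = "i",
                    mapq1 = "i", mapq2 = "i", tag_pos = "i", tag_base = "c"
                  ))
}

#' @rdname read_read_pairs
#' @param read_pairs Tibble of read pairs.
#' @export
write_read_pairs <- function(read_pairs, path) {
  cols <- c("donor", "chrom", "pos1", "pos2", "mapq1", "mapq2",
            "tag_pos", "tag_base")
  readr::write_tsv(read_pairs[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write (and re-read) a results table
#'
#' Writes association / connectivity / enrichment record tibbles as TSV with
#' a deterministic column order and a stable sort, so reruns are
#' byte-identical and write-then-read is the identity.
#'
#' @param records A tibble of one record kind.
#' @param path Output path.
#' @param kind One of `"association"`, `"connectivity"`, `"enrichment"`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path,
                                kind = c("association", "connectivity",
                                         "enrichment")) {
  kind <- match.arg(kind)
  records <- as_tibble(records)
  sort_cols <- switch(kind,
    association = c("chrom", "b1_start", "b2_start", "snp_id"),
    connectivity = c("chrom", "r1s", "r2e", "snp_id"),
    enrichment = c("set_name", "annotation")
  )
  sort_cols <- intersect(sort_cols, names(records))
  if (length(sort_cols)) {
    records <- arrange(records, !!!rlang::syms(sort_cols))
  }
  records <- relocate(records, any_of(c("snp_id", "chrom", "b1_start",
                                        "b2_start")))
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
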