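#' Candidate SNP-loop pairs over anchor windows
#'
#' For each loop between 5 kb bins b1 and b2, the SNPs considered are those
#' inside the windows `[b1 - w, b1 + resolution + w)` and
#' `[b2 - w, b2 + resolution + w)` (half-open; with the default `w` = 5000
#' and 5 kb bins each window spans 15 kb, i.e. the anchor bin plus one
#' flanking bin on each side). A SNP falling in both windows of the same
#' loop yields a single tested pair with `side = "both"`.
#'
#' @param profiles A [contact_profiles()] object.
#' @param panel A [genotype_panel()].
#' @param w Window flank in bp (default 5000).
#' @return Tibble with one row per SNP-loop pair: `snp_id`, `loop_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `b1_start`, `b2_start`, `resolution`,
#'   `side` ("1", "2" or "both") and `in_core_bin` (TRUE iff the SNP lies
#'   inside a 5 kb anchor bin itself rather than a flank).
#' @export
candidate_pairs <- function(profiles, panel, w = 5000) {
  if (w < 0) abort("window flank w must be >= 0")
  res <- profiles$resolution
  loops <- profiles$loops |>
    select("loop_id", "chrom", "b1_start", "b2_start", "resolution")
  snps <- panel$snps
  joined <- inner_join(snps, loops, by = "chrom",
                       relationship = "many-to-many")
  joined <- joined |>
    mutate(
      in1 = .data$pos >= .data$b1_start - w &
        .data$pos < .data$b1_start + res + w,
      in2 = .data$pos >= .data$b2_start - w &
        .data$pos < .data$b2_start + res + w
    ) |>
    filter(.data$in1 | .data$in2) |>
    mutate(
      side = case_when(.data$in1 & .data$in2 ~ "both",
                       .data$in1 ~ "1",
                       TRUE ~ "2"),
      in_core_bin =
        (.data$pos >= .data$b1_start & .data$pos < .data$b1_start + res) |
        (.data$pos >= .data$b2_start & .data$pos < .data$b2_start + res)
    ) |>
    select("snp_id", "loop_id", "chrom", "pos", "ref", "alt",
           "b1_start", "b2_start", "resolution", "side", "in_core_bin") |>
    arrange(.data$chrom, .data$b1_start, .data$b2_start, .data$snp_id)
  joined
}

#' Count allele-specific reads per heterozygous donor
#'
#' For each candidate pair and donor heterozygous at the SNP, counts the
#' paired-end HiChIP read pairs whose allele-tagged end overlaps the SNP
#' with the reference (alternate) base and whose other end lands inside the
#' opposite anchor window `[opp - w, opp + resolution + w)`, requiring both
#' end MAPQs `>= min_mapq` and a pair span inside `dist_range`. For
#' `side = "both"` pairs, reads are counted toward the anchor farther from
#' the SNP. Reads carrying a third base at the SNP are ignored and tallied
#' in the `n_ignored_base` attribute; non-heterozygous donors are skipped
#' and tallied in `n_skipped_nonhet`.
#'
#' @param read_pairs Read-pair tibble (see [read_read_pairs()]).
#' @param pairs Candidate pairs from [candidate_pairs()].
#' @param panel A [genotype_panel()] (supplies heterozygosity).
#' @param w Window flank in bp.
#' @param min_mapq Minimum mapping quality on both ends (default 10).
#' @param dist_range Admissible pair span in bp (default 10 kb - 3 Mb).
#' @return Tibble `snp_id`, `loop_id`, `donor`, `ref_reads`, `alt_reads`,
#'   one row per heterozygous (pair, donor), zero counts included.
#' @export
count_allele_reads <- function(read_pairs, pairs, panel, w = 5000,
                               min_mapq = 10,
                               dist_range = c(10000, 3000000)) {
  res <- unique(pairs$resolution)
  stopifnot(length(res) == 1L)
  pr <- pairs |>
    mutate(opp_start = case_when(
      .data$side == "1" ~ .data$b2_start,
      .data$side == "2" ~ .data$b1_start,
      # side "both": count toward the anchor farther from the SNP
      abs(.data$pos - .data$b1_start) >= abs(.data$pos - .data$b2_start) ~
        .data$b1_start,
      TRUE ~ .data$b2_start
    ))

  het <- tidy(panel) |>
    filter(!is.na(.data$dosage)) |>
    select("snp_id", "donor", "dosage")

  tagged <- read_pairs |>
    filter(!is.na(.data$tag_pos), !is.na(.data$tag_base)) |>
    inner_join(pr |> select("snp_id", "loop_id", "chrom", "pos", "ref",
                            "alt", "opp_start"),
               by = c("chrom", tag_pos = "pos"),
               relationship = "many-to-many") |>
    mutate(
      tagged_is_1 = abs(.data$pos1 - .data$tag_pos) <=
        abs(.data$pos2 - .data$tag_pos),
      other_pos = ifelse(.data$tagged_is_1, .data$pos2, .data$pos1),
      span = abs(.data$pos2 - .data$pos1)
    ) |>
    filter(.data$mapq1 >= min_mapq, .data$mapq2 >= min_mapq,
           .data$span >= dist_range[1], .data$span <= dist_range[2],
           .data$other_pos >= .data$opp_start - w,
           .data$other_pos < .data$opp_start + res + w)

  n_ignored <- sum(tagged$tag_base != tagged$ref &
                     tagged$tag_base != tagged$alt)
  tagged <- tagged |>
    filter(.data$tag_base == .data$ref | .data$tag_base == .data$alt)

  with_gt <- tagged |>
    left_join(het, by = c("snp_id", "donor"))
  n_skipped <- with_gt |>
    filter(is.na(.data$dosage) | .data$dosage != 1L) |>
    nrow()
  counted <- with_gt |>
    filter(.data$dosage == 1L) |>
    group_by(.data$snp_id, .data$loop_id, .data$donor) |>
    summarise(ref_reads = sum(.data$tag_base == .data$ref),
              alt_reads = sum(.data$tag_base == .data$alt),
              .groups = "drop")

  # complete over all heterozygous donors of each candidate pair
  grid <- pr |>
    select("snp_id", "loop_id") |>
    inner_join(het |> filter(.data$dosage == 1L) |> select(-"dosage"),
               by = "snp_id", relationship = "many-to-many")
  out <- grid |>
    left_join(counted, by = c("snp_id", "loop_id", "donor")) |>
    mutate(ref_reads = as.integer(.data$ref_reads %na% 0L),
           alt_reads = as.integer(.data$alt_reads %na% 0L)) |>
    arrange(.data$snp_id, .data$loop_id, .data$donor)
  attr(out, "n_ignored_base") <- n_ignored
  attr(out, "n_skipped_nonhet") <- n_skipped
  out
}
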