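#' Simulation configuration for synthetic HiChIP cohorts
#'
#' Describes the stated world the generator emulates: a cohort of ~30 donors
#' with Hardy-Weinberg genotypes, negative-binomial loop counts on a
#' power-law distance-decay background, donor-specific sequencing depths,
#' multiplicative per-alt-copy genotype effects at planted SNP-loop pairs
#' and matching allelic imbalance in heterozygous donors.
#'
#' @param n_donors Number of donors (default 30, the cohort size the design
#'   emulates). Fewer than 6 is refused: the downstream presence filter
#'   needs at least two donors per genotype class to ever pass.
#' @param n_loops Number of regular (singleton) loops.
#' @param n_snps Number of SNPs; defaults to one per regular loop. Extra
#'   SNPs are cycled over loops.
#' @param resolution Bin size in bp.
#' @param maf_range Range of minor-allele frequencies.
#' @param depth_range Range of per-donor valid cis read-pair totals.
#' @param baseline_range Range of per-loop baseline intensities (expected
#'   count at 100 kb for a 1e5-read-pair donor).
#' @param decay Distance-decay exponent of the expected count.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param n_effects Number of planted iQTL pairs among the regular loops.
#' @param effect_size Multiplicative contact effect per alternate-allele
#'   copy at planted pairs.
#' @param allelic_ratio Planted alt/ref allele-read ratio in heterozygotes.
#' @param discordant If `TRUE`, allelic imbalance is planted opposite to the
#'   genotype effect (exercises the concordance filter).
#' @param n_region_loci Number of connectivity loci: clusters of
#'   `region_n_loops` mutually adjacent loops sharing one SNP whose planted
#'   effect (`region_effect`) spans the whole cluster.
#' @param region_n_loops,region_effect See `n_region_loci`.
#' @param region_null If `TRUE`, region loci are generated without any
#'   effect (matched nulls for connectivity recovery).
#' @param w Anchor flank used when placing SNPs inside loop windows.
#' @param dist_range Admissible loop distance range in bp.
#' @param sig_quantile Per-donor, per-distance-stratum obs/exp quantile
#'   above which a loop is flagged significant (stand-in for FDR < 0.01
#'   loop calls; only the flag's downstream role matters).
#' @param as_read_frac Mean fraction of a donor's loop count that is
#'   SNP-linked and allele-assignable.
#' @param decoy_rate Rate of decoy read pairs (low MAPQ, off-window or
#'   third-base) emitted to exercise the counting filters.
#' @param chrom Chromosome label for the synthetic loops.
#' @param seed Integer seed; fixes every draw.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_donors = 30, n_loops = 100, n_snps = NULL,
                       resolution = 5000,
                       maf_range = c(0.1, 0.5),
                       depth_range = c(1e5, 3e5),
                       baseline_range = c(5, 50),
                       decay = 1.0, dispersion = 0.2,
                       n_effects = 10, effect_size = 1.5,
                       allelic_ratio = 1.5, discordant = FALSE,
                       n_region_loci = 0, region_n_loops = 8,
                       region_effect = 1.5, region_null = FALSE,
                       w = 5000, dist_range = c(10000, 3000000),
                       sig_quantile = 0.75, as_read_frac = 0.5,
                       decoy_rate = 0.05, chrom = "chr1", seed = 1) {
  if (n_donors < 6) {
    abort("n_donors < 6 refused: the genotype-presence filter could never pass")
  }
  if (allelic_ratio <= 0) abort("allelic_ratio must be positive")
  if (effect_size <= 0 || region_effect <= 0) abort("effects must be positive")
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            depth_range[1] > 0, dispersion >= 0,
            n_effects <= n_loops)
  if (is.null(n_snps)) n_snps <- n_loops
  if (n_snps < n_loops) n_snps <- n_loops  # every regular loop gets its SNP
  structure(
    list(n_donors = n_donors, n_loops = n_loops, n_snps = n_snps,
         resolution = resolution, maf_range = maf_range,
         depth_range = depth_range, baseline_range = baseline_range,
         decay = decay, dispersion = dispersion, n_effects = n_effects,
         effect_size = effect_size, allelic_ratio = allelic_ratio,
         discordant = discordant, n_region_loci = n_region_loci,
         region_n_loops = region_n_loops, region_effect = region_effect,
         region_null = region_null, w = w, dist_range = dist_range,
         sig_quantile = sig_quantile, as_read_frac = as_read_frac,
         decoy_rate = decoy_rate, chrom = chrom, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Evaluate `expr` under a derived seed without disturbing the caller's RNG.
with_sim_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

# Deterministic loop/SNP scaffold shared by the generator stages. Regular
# loops are spaced ~400 kb apart (never spatially adjacent at the 10 kb
# slack); each region locus is a chain of loops whose anchors advance one
# bin at a time, forming exactly one connected component.
sim_scaffold <- function(config) {
  res <- config$resolution
  with_sim_seed(config$seed, 101, {
    b1 <- 1e6 + (seq_len(config$n_loops) - 1L) * 4e5
    dist <- round(exp(runif(config$n_loops, log(2e4), log(3.5e5)))/res) * res
    dist <- pmin(pmax(dist, 2e4), 3.5e5)
    loops <- tibble(
      chrom = config$chrom,
      b1_start = as.integer(b1),
      b2_start = as.integer(b1 + dist),
      resolution = res,
      region_id = NA_integer_
    )
    if (config$n_region_loci > 0) {
      base0 <- 1e6 + config$n_loops * 4e5 + 1e6
      region <- map(seq_len(config$n_region_loci), function(j) {
        base <- base0 + (j - 1L) * 3e6
        k <- seq_len(config$region_n_loops) - 1L
        tibble(
          chrom = config$chrom,
          b1_start = as.integer(base + k * res),
          b2_start = as.integer(base + 3e5 + k * res),
          resolution = res,
          region_id = j
        )
      }) |> list_rbind()
      loops <- bind_rows(loops, region)
    }
    loops$loop_id <- loop_key(loops$chrom, loops$b1_start, loops$b2_start)
    loops$baseline <- runif(nrow(loops), config$baseline_range[1],
                            config$baseline_range[2])

    # SNPs: one per regular loop (cycled if n_snps > n_loops), placed inside
    # the b1 anchor window; one SNP per region locus shared by its loops.
    snp_loop <- rep(seq_len(config$n_loops), length.out = config$n_snps)
    offs <- sample(seq(-config$w, res + config$w - 1L),
                   config$n_snps, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    snps <- tibble(
      snp_id = sprintf("rs_s%04d", seq_len(config$n_snps)),
      chrom = config$chrom,
      pos = loops$b1_start[snp_loop] + offs,
      maf = runif(config$n_snps, config$maf_range[1], config$maf_range[2]),
      loop_idx = snp_loop
    )
    if (config$n_region_loci > 0) {
      rsnps <- loops |>
        filter(!is.na(.data$region_id)) |>
        group_by(.data$region_id) |>
        summarise(pos = min(.data$b1_start) + res %/% 2L,
                  loop_idx = which(loops$region_id %in% .data$region_id[1])[1],
                  .groups = "drop") |>
        mutate(snp_id = sprintf("rs_r%04d", .data$region_id),
               chrom = config$chrom,
               maf = 0.4) |>
        select("snp_id", "chrom", "pos", "maf", "loop_idx")
      snps <- bind_rows(snps, rsnps)
    }
    ra <- t(vapply(seq_len(nrow(snps)), function(i) sample(bases, 2L),
                   character(2)))
    snps$ref <- ra[, 1]
    snps$alt <- ra[, 2]

    # Effect table: first n_effects regular SNPs, plus every region SNP
    # (unless region_null) acting on all loops of its region.
    reg_idx <- which(grepl("^rs_s", snps$snp_id))[seq_len(config$n_effects)]
    effects <- tibble(
      snp_id = snps$snp_id[reg_idx],
      loop_id = loops$loop_id[snps$loop_idx[reg_idx]],
      effect = config$effect_size,
      allelic_ratio = if (config$discordant) 1 / config$allelic_ratio
                      else config$allelic_ratio,
      region_id = NA_integer_
    )
    if (config$n_region_loci > 0 && !config$region_null) {
      reff <- loops |>
        filter(!is.na(.data$region_id)) |>
        transmute(snp_id = sprintf("rs_r%04d", .data$region_id),
                  loop_id = .data$loop_id,
                  effect = config$region_effect,
                  allelic_ratio = if (config$discordant)
                    1 / config$allelic_ratio else config$allelic_ratio,
                  region_id = .data$region_id)
      effects <- bind_rows(effects, reff)
    }
    list(loops = loops, snps = snps, effects = effects)
  })
}

#' Simulate a genotyped cohort
#'
#' Draws Hardy-Weinberg genotype dosages at each SNP of the scaffold implied
#' by `config`, plus per-donor covariates (sequencing depth uniform over the
#' configured range; sex, age group and race categorical).
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()].
#' @export
simulate_cohort <- function(config) {
  sc <- sim_scaffold(config)
  with_sim_seed(config$seed, 202, {
    donors <- sprintf("D%02d", seq_len(config$n_donors))
    dosage <- vapply(sc$snps$maf, function(m) {
      rbinom(config$n_donors, 2L, m)
    }, integer(config$n_donors))
    dosage <- t(dosage)
    dimnames(dosage) <- list(sc$snps$snp_id, donors)
    covariates <- tibble(
      donor = donors,
      depth = round(runif(config$n_donors, config$depth_range[1],
                          config$depth_range[2])),
      sex = sample(c("F", "M"), config$n_donors, replace = TRUE),
      age_group = sample(c("18-30", "31-50", "51+"), config$n_donors,
                         replace = TRUE),
      race = sample(c("A", "B", "C"), config$n_donors, replace = TRUE)
    )
    snps <- sc$snps[, c("snp_id", "chrom", "pos", "ref", "alt")]
    genotype_panel(snps, dosage, covariates)
  })
}

#' Simulate donor-resolved loop contacts with planted genotype effects
#'
#' Per loop and donor, the expected count follows the donor depth and a
#' power-law distance decay; the observed count is negative-binomial with
#' mean multiplied by `effect^dosage` at planted pairs. Significance flags
#' mark loops whose obs/exp ratio exceeds the configured quantile within the
#' donor's distance stratum.
#'
#' @param panel A [genotype_panel()] from [simulate_cohort()].
#' @param config The same [sim_config()].
#' @return A list with `profiles` (a [contact_profiles()]) and `truth`
#'   (tibble: planted SNP-loop pairs with effect sizes, allelic ratios and
#'   connectivity-locus labels).
#' @export
simulate_contacts <- function(panel, config) {
  sc <- sim_scaffold(config)
  loops <- sc$loops
  with_sim_seed(config$seed, 303, {
    depth <- panel$covariates$depth
    dist <- loops$b2_start - loops$b1_start
    expected <- outer(loops$baseline * (dist / 1e5)^(-config$decay),
                      depth / 1e5)
    dimnames(expected) <- list(loops$loop_id, panel$donors)
    mu <- expected
    for (i in seq_len(nrow(sc$effects))) {
      e <- sc$effects[i, ]
      dos <- panel$dosage[e$snp_id, ]
      li <- match(e$loop_id, loops$loop_id)
      mu[li, ] <- mu[li, ] * e$effect^(dos %na% 0)
    }
    observed <- matrix(
      if (config$dispersion > 0) {
        rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion)
      } else {
        rpois(length(mu), as.vector(mu))
      },
      nrow = nrow(mu), dimnames = dimnames(mu)
    )
    ratio <- observed / expected
    stratum <- distance_stratum(dist)
    significant <- matrix(FALSE, nrow(ratio), ncol(ratio),
                          dimnames = dimnames(ratio))
    for (s in unique(stratum)) {
      rows <- stratum == s
      thr <- apply(ratio[rows, , drop = FALSE], 2L, quantile,
                   probs = config$sig_quantile, names = FALSE)
      significant[rows, ] <- sweep(ratio[rows, , drop = FALSE], 2L, thr,
                                   ">=") & observed[rows, , drop = FALSE] > 0
    }
    profiles <- contact_profiles(
      loops[, c("loop_id", "chrom", "b1_start", "b2_start", "resolution")],
      observed, expected, significant, dist_range = config$dist_range
    )
    truth <- sc$effects |>
      mutate(is_iqtl = TRUE,
             is_connectivity_locus = !is.na(.data$region_id))
    list(profiles = profiles, truth = truth)
  })
}

# Log-spaced distance strata, 8 per decade (shared with expected-count
# estimation).
distance_stratum <- function(distance, per_decade = 8) {
  as.integer(floor(log10(pmax(distance, 1)) * per_decade))
}

#' Simulate allele-specific read data for heterozygous donors
#'
#' For each scaffold SNP-loop pair and heterozygous donor, draws the number
#' of SNP-linked, allele-assignable read pairs proportional to the donor's
#' observed loop count, splits them between alleles (alt fraction
#' `ratio / (1 + ratio)` at planted pairs, 0.5 at nulls) and, optionally,
#' emits raw read-pair records (allele-tagged ends at the SNP, mates inside
#' the opposite anchor bin) plus decoys that must be rejected by the
#' counting filters, so aggregate and raw representations stay consistent.
#'
#' @param panel A [genotype_panel()].
#' @param profiles `profiles` from [simulate_contacts()].
#' @param config The same [sim_config()].
#' @param emit_read_pairs If `FALSE`, only aggregate [tibble] allele records
#'   are produced (faster for large cohorts).
#' @return List with `allele_records` (snp_id, loop_id, donor, ref_reads,
#'   alt_reads) and `read_pairs` (tibble or `NULL`).
#' @export
simulate_allele_data <- function(panel, profiles, config,
                                 emit_read_pairs = TRUE) {
  sc <- sim_scaffold(config)
  res <- config$resolution
  with_sim_seed(config$seed, 404, {
    pairs <- sc$snps |>
      mutate(loop_id = sc$loops$loop_id[.data$loop_idx]) |>
      select("snp_id", "pos", "ref", "alt", "loop_id")
    # region SNPs pair with every loop of their region
    if (config$n_region_loci > 0) {
      extra <- sc$loops |>
        filter(!is.na(.data$region_id)) |>
        mutate(snp_id = sprintf("rs_r%04d", .data$region_id)) |>
        left_join(sc$snps |> select("snp_id", "pos", "ref", "alt"),
                  by = "snp_id") |>
        select("snp_id", "pos", "ref", "alt", "loop_id")
      pairs <- bind_rows(pairs |> filter(!grepl("^rs_r", .data$snp_id)), extra)
    }
    eff <- sc$effects |> select("snp_id", "loop_id", "allelic_ratio")
    pairs <- pairs |>
      left_join(eff, by = c("snp_id", "loop_id")) |>
      mutate(p_alt = ifelse(is.na(.data$allelic_ratio), 0.5,
                            .data$allelic_ratio / (1 + .data$allelic_ratio)))

    het <- tidy(panel) |>
      filter(.data$dosage == 1L) |>
      select("snp_id", "donor")
    obs_long <- as_tibble(profiles$observed, rownames = "loop_id") |>
      pivot_longer(-"loop_id", names_to = "donor", values_to = "observed")
    recs <- pairs |>
      inner_join(het, by = "snp_id", relationship = "many-to-many") |>
      left_join(obs_long, by = c("loop_id", "donor")) |>
      mutate(total = rpois(n(), config$as_read_frac * (.data$observed %na% 0)),
             alt_reads = rbinom(n(), .data$total, .data$p_alt),
             ref_reads = .data$total - .data$alt_reads)
    allele_records <- recs |>
      select("snp_id", "loop_id", "donor", "ref_reads", "alt_reads")

    read_pairs <- NULL
    if (emit_read_pairs) {
      loops_tb <- profiles$loops
      rp_src <- recs |>
        left_join(loops_tb |> select("loop_id", "b1_start", "b2_start"),
                  by = "loop_id") |>
        mutate(opp_start = ifelse(
          abs(.data$pos - .data$b1_start) <= abs(.data$pos - .data$b2_start),
          .data$b2_start, .data$b1_start))
      emit <- function(n_col, base_col) {
        rp_src |>
          mutate(.n = .data[[n_col]]) |>
          filter(.data$.n > 0) |>
          uncount(.data$.n) |>
          mutate(donor = .data$donor,
                 chrom = config$chrom,
                 pos1 = .data$pos,
                 pos2 = .data$opp_start +
                   sample.int(res, n(), replace = TRUE) - 1L,
                 mapq1 = 30L, mapq2 = 30L,
                 tag_pos = .data$pos,
                 tag_base = .data[[base_col]]) |>
          select("donor", "chrom", "pos1", "pos2", "mapq1", "mapq2",
                 "tag_pos", "tag_base")
      }
      read_pairs <- bind_rows(emit("ref_reads", "ref"),
                              emit("alt_reads", "alt"))
      if (config$decoy_rate > 0 && nrow(rp_src) > 0) {
        n_decoy <- rpois(1L, config$decoy_rate * sum(rp_src$total))
        if (n_decoy > 0) {
          src <- rp_src[sample.int(nrow(rp_src), n_decoy, replace = TRUE), ]
          kind <- sample(c("lowmapq", "offwindow", "thirdbase"), n_decoy,
                         replace = TRUE)
          decoys <- src |>
            mutate(kind = kind,
                   chrom = config$chrom,
                   pos1 = .data$pos,
                   pos2 = ifelse(kind == "offwindow",
                                 .data$opp_start + res + config$w + 10000L +
                                   sample.int(5000L, n_decoy, replace = TRUE),
                                 .data$opp_start +
                                   sample.int(res, n_decoy, replace = TRUE) - 1L),
                   mapq1 = ifelse(kind == "lowmapq", 5L, 30L),
                   mapq2 = 30L,
                   tag_pos = .data$pos,
                   tag_base = ifelse(
                     kind == "thirdbase",
                     vapply(seq_len(n_decoy), function(i) {
                       setdiff(c("A", "C", "G", "T"),
                               c(src$ref[i], src$alt[i]))[1]
                     }, character(1)),
                     ifelse(rbinom(n_decoy, 1L, 0.5) == 1L, src$ref, src$alt))) |>
            select("donor", "chrom", "pos1", "pos2", "mapq1", "mapq2",
                   "tag_pos", "tag_base")
          read_pairs <- bind_rows(read_pairs, decoys)
        }
      }
      read_pairs <- read_pairs |>
        arrange(.data$donor, .data$tag_pos, .data$pos1, .data$pos2,
                .data$tag_base)
    }
    list(allele_records = allele_records, read_pairs = read_pairs)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_cohort()], [simulate_contacts()]
#' and [simulate_allele_data()] under one configuration.
#'
#' @param config A [sim_config()].
#' @param emit_read_pairs Passed to [simulate_allele_data()].
#' @return List with `panel`, `profiles`, `truth`, `allele_records`,
#'   `read_pairs`, `config`.
#' @export
simulate_dataset <- function(config, emit_read_pairs = TRUE) {
  panel <- simulate_cohort(config)
  contacts <- simulate_contacts(panel, config)
  allele <- simulate_allele_data(panel, contacts$profiles, config,
                                 emit_read_pairs = emit_read_pairs)
  list(panel = panel, profiles = contacts$profiles, truth = contacts$truth,
       allele_records = allele$allele_records,
       read_pairs = allele$read_pairs, config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits the on-disk bundle the pipeline consumes: a VCF, the multi-donor
#' loop table, a read-pair TSV (when present), a covariate TSV, the truth
#' table and the configuration as JSON.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    loops = file.path(dir, "loops.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "sim_config.json")
  )
  write_genotype_vcf(dataset$panel, paths[["vcf"]])
  write_loop_table(dataset$profiles, paths[["loops"]])
  readr::write_tsv(dataset$panel$covariates, paths[["covariates"]],
                   progress = FALSE)
  readr::write_tsv(dataset$truth, paths[["truth"]], progress = FALSE)
  jsonlite::write_json(unclass(dataset$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(dataset$read_pairs)) {
    paths[["read_pairs"]] <- file.path(dir, "read_pairs.tsv")
    write_read_pairs(dataset$read_pairs, paths[["read_pairs"]])
  }
  invisible(paths)
}
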