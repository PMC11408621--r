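#' Map iQTLs across all candidate SNP-loop pairs
#'
#' Runs the full association stage: keeps loops significant in at least one
#' donor, depth-normalizes counts, enumerates candidate pairs over anchor
#' windows, computes the genotype-trend and allele-paired statistics,
#' combines them, controls the FDR genome-wide and applies the filtering
#' cascade. SNPs accepted for more than one loop are additionally tested
#' for the multi-loop label.
#'
#' @param profiles A [contact_profiles()]; expected counts are estimated
#'   with [estimate_expected_counts()] when absent.
#' @param panel A [genotype_panel()] over the same donors.
#' @param allele_records Optional aggregate allele-read tibble (`snp_id`,
#'   `loop_id`, `donor`, `ref_reads`, `alt_reads`).
#' @param read_pairs Optional raw read-pair tibble; used to compute
#'   `allele_records` via [count_allele_reads()] when those are absent.
#' @param w Anchor window flank in bp (default 5000).
#' @param min_mapq Minimum mapping quality for allele counting.
#' @param thresholds Cascade thresholds, see [iqtl_thresholds()].
#' @param use_covariates Include categorical donor covariates in the trend
#'   regression.
#' @param min_het Minimum usable heterozygous donors for the paired t-test.
#' @param multiloop_alpha Pooled-regression threshold for the multi-loop
#'   label (default 1e-5).
#' @return An `iqtl_fit` object; `tidy()` returns the per-pair association
#'   table, `glance()` the stage funnel.
#' @export
map_iqtls <- function(profiles, panel, allele_records = NULL,
                      read_pairs = NULL, w = 5000, min_mapq = 10,
                      thresholds = iqtl_thresholds(), use_covariates = TRUE,
                      min_het = 3, multiloop_alpha = 1e-5) {
  mismatch <- c(setdiff(profiles$donors, panel$donors),
                setdiff(panel$donors, profiles$donors))
  if (length(mismatch)) {
    abort(paste0("donor sets differ between loops and genotypes: ",
                 paste(unique(mismatch), collapse = ", ")))
  }
  if (is.null(profiles$expected)) {
    profiles <- estimate_expected_counts(profiles)
  }
  sig_any <- rowSums(profiles$significant) > 0
  n_dropped <- sum(!sig_any)
  profiles <- filter_profiles(profiles, profiles$loops$loop_id[sig_any])

  depth <- setNames(panel$covariates$depth, panel$covariates$donor)
  normalized <- normalize_counts(profiles$observed, depth)

  pairs <- candidate_pairs(profiles, panel, w = w)
  if (is.null(allele_records) && !is.null(read_pairs)) {
    allele_records <- count_allele_reads(read_pairs, pairs, panel, w = w,
                                         min_mapq = min_mapq,
                                         dist_range = profiles$dist_range)
  }
  allele_split <- if (!is.null(allele_records)) {
    split(allele_records,
          paste(allele_records$snp_id, allele_records$loop_id))
  } else {
    list()
  }
  covariates <- if (use_covariates) panel$covariates else NULL

  stats_rows <- map(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    raw <- profiles$observed[p$loop_id, ]
    norm <- normalized[p$loop_id, ]
    dos <- panel$dosage[p$snp_id, ]
    trend_fit <- genotype_trend_test(norm, dos, covariates)
    ar <- allele_split[[paste(p$snp_id, p$loop_id)]]
    if (!is.null(ar) && nrow(ar) > 0) {
      as_fit <- allele_paired_ttest(ar$ref_reads, ar$alt_reads,
                                    direction = trend_fit$slope %na% 0,
                                    min_donors = min_het)
      use <- ar$ref_reads + ar$alt_reads > 0
      ts <- trend_summary(raw, norm, dos,
                          ref_reads = ar$ref_reads[use],
                          alt_reads = ar$alt_reads[use])
    } else {
      as_fit <- tibble(p_as = NA_real_, mean_diff = NA_real_, n_het_used = 0L)
      ts <- trend_summary(raw, norm, dos)
    }
    bind_cols(p, trend_fit, as_fit, ts)
  }) |> list_rbind()

  stats_rows <- combine_and_fdr(stats_rows)
  stats_rows <- apply_filter_cascade(stats_rows, thresholds)

  accepted <- filter(stats_rows, .data$accepted)
  multi <- accepted |>
    group_by(.data$snp_id) |>
    summarise(loop_ids = list(.data$loop_id), .groups = "drop") |>
    filter(lengths(.data$loop_ids) > 1L)
  multiloop_snps <- character()
  if (nrow(multi) > 0) {
    is_multi <- map_lgl(seq_len(nrow(multi)), function(i) {
      label_multiloop(multi$snp_id[i], multi$loop_ids[[i]], profiles, panel,
                      alpha = multiloop_alpha)
    })
    multiloop_snps <- multi$snp_id[is_multi]
  }
  stats_rows$multiloop <- stats_rows$accepted &
    stats_rows$snp_id %in% multiloop_snps

  structure(
    list(associations = stats_rows, profiles = profiles, panel = panel,
         thresholds = thresholds, w = w,
         n_loops_dropped_nonsignificant = n_dropped),
    class = "iqtl_fit"
  )
}

#' @export
print.iqtl_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<iqtl_fit> %d SNP-loop pairs tested (%d testable), %d donors\n",
    "  FDR_Def < %.2g: %d;  accepted after cascade: %d (%d SNPs, %d loops)\n",
    "  multi-loop iQTL SNPs: %d\n"),
    g$n_pairs, g$n_testable, g$n_donors, x$thresholds$fdr_def,
    g$n_fdr_def, g$n_accepted, g$n_snps_accepted, g$n_loops_accepted,
    g$n_multiloop_snps))
  invisible(x)
}

#' @export
tidy.iqtl_fit <- function(x, ...) {
  x$associations
}

#' @export
glance.iqtl_fit <- function(x, ...) {
  a <- x$associations
  acc <- filter(a, .data$accepted)
  tibble(
    n_pairs = nrow(a),
    n_testable = sum(a$testable),
    n_donors = length(x$panel$donors),
    n_fdr_def = sum(a$fdr_def < x$thresholds$fdr_def, na.rm = TRUE),
    n_accepted = nrow(acc),
    n_snps_accepted = n_distinct(acc$snp_id),
    n_loops_accepted = n_distinct(acc$loop_id),
    n_multiloop_snps = n_distinct(acc$snp_id[acc$multiloop])
  )
}

#' Accepted iQTL calls from a fit
#'
#' @param fit An `iqtl_fit`.
#' @return Tibble of accepted rows (the final call set).
#' @export
iqtl_calls <- function(fit) {
  filter(fit$associations, .data$accepted)
}

#' Assemble a pipeline run configuration
#'
#' Bundles input paths and every tunable parameter with its default: 5 kb
#' resolution, w = 5000 (15 kb anchor windows), MAPQ >= 10, 10 kb - 3 Mb
#' distance range, 0.05 significance thresholds for FDR_Def / FDR_Pop /
#' P_AS, 1e-5 pooled-regression alpha for multi-loop and connectivity
#' tests, 0.005 Bonferroni-adjusted threshold, 0.1 percentile step, 10 kb
#' component slack and a 20 kb loop-matched null window.
#'
#' @param genotypes,loops,read_pairs,covariates,annotations Input paths
#'   (only `genotypes` and `loops` are required to map iQTLs).
#' @param out_dir Output directory.
#' @param sim Optional list of [sim_config()] overrides for the `simulate`
#'   stage.
#' @param resolution,w,min_mapq,dist_range,fdr_def,fdr_pop,p_as
#'   Core parameters (paper-default values as above).
#' @param multiloop_alpha,connectivity_alpha,bonf_alpha,step_thr,slack_t
#'   Multi-loop / connectivity parameters.
#' @param null_window Loop-matched null anchor neighborhood in bp.
#' @param seed Integer seed used by every stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
iqtl_config <- function(genotypes = NULL, loops = NULL, read_pairs = NULL,
                        covariates = NULL, annotations = NULL,
                        out_dir = "iqtl_out", sim = list(),
                        resolution = 5000, w = 5000, min_mapq = 10,
                        dist_range = c(10000, 3000000),
                        fdr_def = 0.05, fdr_pop = 0.05, p_as = 0.05,
                        multiloop_alpha = 1e-5, connectivity_alpha = 1e-5,
                        bonf_alpha = 0.005, step_thr = 0.1, slack_t = 10000,
                        null_window = 20000, seed = 1,
                        log_level = c("info", "quiet")) {
  structure(
    list(
      paths = list(genotypes = genotypes, loops = loops,
                   read_pairs = read_pairs, covariates = covariates,
                   annotations = annotations, out_dir = out_dir),
      sim = sim,
      params = list(resolution = resolution, w = w, min_mapq = min_mapq,
                    dist_range = dist_range, fdr_def = fdr_def,
                    fdr_pop = fdr_pop, p_as = p_as,
                    multiloop_alpha = multiloop_alpha,
                    connectivity_alpha = connectivity_alpha,
                    bonf_alpha = bonf_alpha, step_thr = step_thr,
                    slack_t = slack_t, null_window = null_window),
      seed = as.integer(seed),
      log_level = match.arg(log_level)
    ),
    class = "run_config"
  )
}

log_stage <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  inform(sprintf(paste0("[loopqtl] ", fmt), ...))
}

#' Run the pipeline stages behind a configuration
#'
#' `simulate` writes a seeded synthetic cohort bundle; `map-iqtl` maps and
#' filters iQTLs from the configured inputs; `connectivity` derives
#' connectivity-QTLs from the accepted calls; `enrich` runs the
#' loop-matched enrichment against the configured annotation BED; `all`
#' chains every applicable stage. Each stage persists deterministic TSVs
#' under `out_dir` and the run ends with a manifest (frozen config, seed,
#' input checksums, per-stage row counts). Reruns with identical config and
#' inputs are byte-identical.
#'
#' @param config A [iqtl_config()] list or the path of a JSON file holding
#'   one.
#' @param subcommand One of `"simulate"`, `"map-iqtl"`, `"connectivity"`,
#'   `"enrich"`, `"all"`.
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config,
                         subcommand = c("all", "simulate", "map-iqtl",
                                        "connectivity", "enrich")) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) {
    config <- utils::modifyList(
      iqtl_config(),
      jsonlite::read_json(config, simplifyVector = TRUE))
  }
  p <- config$params
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  counts <- list()

  do_sim <- subcommand == "simulate" ||
    (subcommand == "all" && is.null(config$paths$genotypes))
  if (do_sim) {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% config$seed
    sc <- do.call(sim_config, sim_args)
    ds <- simulate_dataset(sc)
    paths <- write_cohort(ds, file.path(out_dir, "sim"))
    config$paths$genotypes <- paths[["vcf"]]
    config$paths$loops <- paths[["loops"]]
    config$paths$covariates <- paths[["covariates"]]
    if ("read_pairs" %in% names(paths)) {
      config$paths$read_pairs <- paths[["read_pairs"]]
    }
    outputs$sim <- paths
    counts$sim_loops <- nrow(ds$profiles$loops)
    counts$sim_snps <- nrow(ds$panel$snps)
    log_stage(config, "simulate: %d loops, %d SNPs, %d donors",
              counts$sim_loops, counts$sim_snps, length(ds$panel$donors))
    if (subcommand == "simulate") {
      manifest <- write_manifest(config, outputs, counts)
      return(invisible(list(outputs = outputs, manifest = manifest)))
    }
  }

  for (nm in c("genotypes", "loops")) {
    pth <- config$paths[[nm]]
    if (is.null(pth) || !file.exists(pth)) {
      abort(sprintf("missing input for stage: %s (path: %s)", nm,
                    pth %||% "<unset>"))
    }
  }
  covars <- if (!is.null(config$paths$covariates)) {
    readr::read_tsv(config$paths$covariates, show_col_types = FALSE,
                    progress = FALSE)
  }
  panel <- read_genotype_vcf(config$paths$genotypes, covariates = covars)
  profiles <- read_loop_table(config$paths$loops,
                              resolution = p$resolution,
                              dist_range = p$dist_range)
  read_pairs <- if (!is.null(config$paths$read_pairs)) {
    read_read_pairs(config$paths$read_pairs)
  }
  fit <- map_iqtls(profiles, panel, read_pairs = read_pairs, w = p$w,
                   min_mapq = p$min_mapq,
                   thresholds = iqtl_thresholds(p$fdr_def, p$fdr_pop, p$p_as),
                   multiloop_alpha = p$multiloop_alpha)
  assoc_path <- file.path(out_dir, "associations.tsv")
  write_results_table(select(tidy(fit), -any_of("resolution")), assoc_path,
                      kind = "association")
  outputs$associations <- assoc_path
  g <- glance(fit)
  counts$pairs_tested <- g$n_pairs
  counts$pairs_significant <- g$n_fdr_def
  counts$pairs_accepted <- g$n_accepted
  log_stage(config, "map-iqtl: %d pairs -> %d significant -> %d accepted",
            g$n_pairs, g$n_fdr_def, g$n_accepted)

  if (subcommand %in% c("connectivity", "all")) {
    conn <- call_connectivity_qtls(
      iqtl_calls(fit), fit$profiles, panel,
      alpha = p$connectivity_alpha, bonf_alpha = p$bonf_alpha,
      thr = p$step_thr, slack_t = p$slack_t)
    conn_path <- file.path(out_dir, "connectivity.tsv")
    write_results_table(conn, conn_path, kind = "connectivity")
    outputs$connectivity <- conn_path
    counts$connectivity_evaluated <- nrow(conn)
    counts$connectivity_called <- sum(conn$called)
    log_stage(config, "connectivity: %d regions evaluated, %d called",
              nrow(conn), sum(conn$called))
  }

  if (subcommand %in% c("enrich", "all") &&
      !is.null(config$paths$annotations)) {
    intervals <- read_bed_intervals(config$paths$annotations)
    calls <- iqtl_calls(fit)
    iqtl_snps <- panel$snps |> filter(.data$snp_id %in% calls$snp_id)
    controls <- loop_matched_null_sample(
      calls, panel$snps, fit$profiles$loops,
      window = p$null_window, seed = config$seed)
    enr <- enrichment_report(iqtl_snps, controls, intervals)
    enr_path <- file.path(out_dir, "enrichment.tsv")
    write_results_table(enr, enr_path, kind = "enrichment")
    outputs$enrichment <- enr_path
    counts$enrichment_controls <- nrow(controls)
    log_stage(config, "enrich: OR = %.3g, p = %.3g",
              enr$odds_ratio, enr$p_value)
  }

  manifest <- write_manifest(config, outputs, counts)
  invisible(list(fit = fit, outputs = outputs, manifest = manifest))
}

write_manifest <- function(config, outputs, counts) {
  inputs <- purrr::compact(config$paths[c("genotypes", "loops", "read_pairs",
                                          "covariates", "annotations")])
  checksums <- map(inputs, function(pth) {
    if (file.exists(pth)) unname(tools::md5sum(pth)) else NA_character_
  })
  frozen <- file.path(config$paths$out_dir, "config.json")
  cfg_plain <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(cfg_plain, frozen, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(frozen)),
                   inputs = checksums,
                   outputs = map(outputs, identity),
                   row_counts = counts)
  jsonlite::write_json(manifest,
                       file.path(config$paths$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}
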