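#' Volcano-style overview of an iQTL fit
#'
#' Genotype slope against combined significance, colored by the cascade
#' decision; one point per tested SNP-loop pair.
#'
#' @param object An `iqtl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iqtl_fit <- function(object, ...) {
  a <- object$associations |>
    filter(.data$testable) |>
    mutate(status = case_when(
      .data$multiloop ~ "multi-loop iQTL",
      .data$accepted ~ "iQTL",
      TRUE ~ paste0("rejected (", .data$reason %na% "ns", ")")
    ))
  ggplot2::ggplot(a, ggplot2::aes(x = .data$slope,
                                  y = -log10(pmax(.data$p_comb, 1e-300)),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::geom_hline(yintercept = -log10(object$thresholds$fdr_def),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "genotype slope (log2 CPM per alt allele)",
                  y = expression(-log[10]~p[comb]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-genotype contact counts for one SNP-loop pair
#'
#' Boxplots of depth-normalized contact counts in the three genotype
#' classes, the visual counterpart of the monotone-trend condition.
#'
#' @param fit An `iqtl_fit`.
#' @param snp_id,loop_id The pair to display.
#' @return A ggplot object.
#' @export
plot_genotype_trend <- function(fit, snp_id, loop_id) {
  depth <- setNames(fit$panel$covariates$depth, fit$panel$covariates$donor)
  norm <- normalize_counts(fit$profiles$observed, depth)[loop_id, ]
  dos <- fit$panel$dosage[snp_id, ]
  df <- tibble(donor = names(dos), dosage = as.integer(dos),
               normalized = norm[names(dos)]) |>
    filter(!is.na(.data$dosage)) |>
    mutate(genotype = factor(c("0|0", "0|1", "1|1")[.data$dosage + 1L],
                             levels = c("0|0", "0|1", "1|1")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype,
                                   y = .data$normalized)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.8, size = 1.5) +
    ggplot2::labs(title = paste(snp_id, "x", loop_id),
                  x = NULL, y = "contacts per million") +
    ggplot2::theme_minimal()
}

#' Genotype-aggregated contact maps of a component region
#'
#' One panel per genotype class, tiles at the loop bin pairs of the region,
#' filled by the class-mean obs/exp ratio (log2).
#'
#' @param object A `genotype_contact_map` from [aggregate_genotype_maps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_contact_map <- function(object, ...) {
  long <- object$cells |>
    pivot_longer(c("m_ref", "m_het", "m_alt"),
                 names_to = "genotype", values_to = "ratio") |>
    mutate(genotype = factor(.data$genotype,
                             levels = c("m_ref", "m_het", "m_alt"),
                             labels = c("0|0", "0|1", "1|1")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$b1_start / 1e6,
                                     y = .data$b2_start / 1e6,
                                     fill = log2(.data$ratio))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::scale_fill_viridis_c(na.value = "grey95") +
    ggplot2::labs(x = "anchor 1 (Mb)", y = "anchor 2 (Mb)",
                  fill = expression(log[2]~"obs/exp"),
                  title = object$snp_id) +
    ggplot2::theme_minimal()
}
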