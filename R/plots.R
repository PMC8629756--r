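#' PPV versus odds ratio for significant associations
#'
#' The display that motivates the screen: each significant association's
#' empirical penetrance (PPV) against its odds ratio, per cohort and stratum,
#' with the PPV threshold drawn as a horizontal line. Points resting on fewer
#' than `min_carrier_cases_display` carrier cases (default 5) are suppressed,
#' because small strata produce unreliable PPVs.
#'
#' @param report A `screen_report` (see [build_report()]).
#' @param cohort_labels Length-2 labels for the cohorts.
#' @return A ggplot object.
#' @export
plot_ppv_or <- function(report, cohort_labels = c("cohort_a", "cohort_b")) {
  stopifnot(inherits(report, "screen_report"))
  t <- report$thresholds
  s <- report$screen
  if (nrow(s) == 0L) abort("no significant associations to plot")
  long <- dplyr::bind_rows(
    dplyr::transmute(s, gene_id = .data$gene_id,
                     cohort = cohort_labels[1], stratum = "all ages",
                     ppv = .data$ppv_all_ages_a, or = .data$odds_ratio_a,
                     carrier_cases = .data$a_a,
                     candidate = .data$candidate),
    dplyr::transmute(s, gene_id = .data$gene_id,
                     cohort = cohort_labels[2], stratum = "all ages",
                     ppv = .data$ppv_all_ages_b, or = .data$odds_ratio_b,
                     carrier_cases = .data$a_b,
                     candidate = .data$candidate),
    dplyr::transmute(s, gene_id = .data$gene_id,
                     cohort = cohort_labels[1], stratum = "60+",
                     ppv = .data$ppv_60plus_a, or = .data$odds_ratio_a,
                     carrier_cases = .data$carrier_cases_60plus_a,
                     candidate = .data$candidate),
    dplyr::transmute(s, gene_id = .data$gene_id,
                     cohort = cohort_labels[2], stratum = "60+",
                     ppv = .data$ppv_60plus_b, or = .data$odds_ratio_b,
                     carrier_cases = .data$carrier_cases_60plus_b,
                     candidate = .data$candidate)) |>
    dplyr::filter(!is.na(.data$ppv),
                  .data$carrier_cases >= t$min_carrier_cases_display)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$or, y = .data$ppv,
                                     colour = .data$candidate,
                                     shape = .data$stratum)) +
    ggplot2::geom_hline(yintercept = t$ppv_min, linetype = "dashed") +
    ggplot2::geom_point(size = 2.5, alpha = 0.85) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = "odds ratio (log scale)",
                  y = "positive predictive value",
                  colour = "candidate", shape = "stratum") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ppv_or
#' @param object A `screen_report`.
#' @param ... Passed to [plot_ppv_or()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.screen_report <- function(object, ...) plot_ppv_or(object, ...)

#' Meta-analysis p-value overview
#'
#' Manhattan-style strip of gene-phecode meta p-values with the Bonferroni
#' line; significant triples are highlighted.
#'
#' @param meta Gated meta tibble (see [significance_gate()]).
#' @inheritParams qualify_variants
#' @return A ggplot object.
#' @export
plot_meta_significance <- function(meta, thresholds = NULL) {
  t <- as_thresholds(thresholds)
  ggplot2::ggplot(meta, ggplot2::aes(x = .data$gene_id,
                                     y = -log10(.data$p_meta),
                                     colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(t$bonferroni_alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "-log10 meta p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
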