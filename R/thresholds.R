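#' Screening thresholds
#'
#' Bundles every tunable cutoff used along the pipeline: variant and CNV
#' qualification, phenotype inclusion, genome-wide significance, and the
#' positive-predictive-value (PPV) screen. Defaults reproduce the published
#' two-cohort screening analysis this package implements.
#'
#' @param maf_max Maximum allele frequency for a qualifying variant; applied to
#'   every gnomAD population frequency and to the local cohort frequency
#'   (default 0.001, i.e. 0.1%).
#' @param polyphen_benign_below PolyPhen scores strictly below this value call
#'   a missense variant benign (default 0.15).
#' @param sift_benign_above SIFT scores strictly above this value call a
#'   variant benign (default 0.05).
#' @param benign_rule `"either"` (default) excludes a variant if either
#'   predictor calls it benign; `"both"` requires both predictors to agree.
#' @param cnv_freq_max Maximum within-cohort frequency for a qualifying CNV,
#'   applied at both the exon and the event level (default 0.001).
#' @param bonferroni_alpha Genome-wide significance level for the meta-analysis
#'   p-value (default 1e-9).
#' @param ppv_min Minimum PPV, i.e. empirical penetrance, required in both
#'   cohorts for a screening candidate (default 0.3).
#' @param min_cases_small_cohort Minimum case count in the smaller cohort for a
#'   phenotype to enter the analysis (default 30).
#' @param min_carrier_cases_display Minimum carrier-case count for a
#'   cohort-stratum PPV to be considered reliable enough to display
#'   (default 5).
#' @param age_stratum_cut Age (years) delimiting the lifetime-risk stratum
#'   (default 60; the stratum is ages `>= age_stratum_cut`).
#' @param undefined_stratum_policy How to treat a 60+ cohort-stratum whose PPV
#'   is undefined or rests on fewer than `min_carrier_cases_display` carrier
#'   cases when the other cohort passes: `"fallback_all_ages"` (default) lets
#'   that cohort pass via its all-ages PPV and flags the pair for manual
#'   review; `"strict"` fails the stratum.
#'
#' @return A list of class `screen_thresholds`.
#' @examples
#' screen_thresholds()
#' screen_thresholds(ppv_min = 0.5)
#' @export
screen_thresholds <- function(maf_max = 0.001,
                              polyphen_benign_below = 0.15,
                              sift_benign_above = 0.05,
                              benign_rule = c("either", "both"),
                              cnv_freq_max = 0.001,
                              bonferroni_alpha = 1e-9,
                              ppv_min = 0.3,
                              min_cases_small_cohort = 30L,
                              min_carrier_cases_display = 5L,
                              age_stratum_cut = 60,
                              undefined_stratum_policy = c("fallback_all_ages",
                                                           "strict")) {
  benign_rule <- match.arg(benign_rule)
  undefined_stratum_policy <- match.arg(undefined_stratum_policy)
  num <- c(maf_max = maf_max, polyphen_benign_below = polyphen_benign_below,
           sift_benign_above = sift_benign_above, cnv_freq_max = cnv_freq_max,
           bonferroni_alpha = bonferroni_alpha, ppv_min = ppv_min,
           min_cases_small_cohort = min_cases_small_cohort,
           min_carrier_cases_display = min_carrier_cases_display,
           age_stratum_cut = age_stratum_cut)
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("all thresholds must be finite and positive")
  }
  if (ppv_min >= 1) abort("`ppv_min` must lie in (0, 1)")
  structure(
    list(maf_max = maf_max,
         polyphen_benign_below = polyphen_benign_below,
         sift_benign_above = sift_benign_above,
         benign_rule = benign_rule,
         cnv_freq_max = cnv_freq_max,
         bonferroni_alpha = bonferroni_alpha,
         ppv_min = ppv_min,
         min_cases_small_cohort = as.integer(min_cases_small_cohort),
         min_carrier_cases_display = as.integer(min_carrier_cases_display),
         age_stratum_cut = age_stratum_cut,
         undefined_stratum_policy = undefined_stratum_policy),
    class = "screen_thresholds")
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat("<screen_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_thresholds <- function(t) {
  if (inherits(t, "screen_thresholds")) return(t)
  if (is.null(t)) return(screen_thresholds())
  if (is.list(t)) return(do.call(screen_thresholds, t))
  abort("`thresholds` must be a screen_thresholds object or a list")
}

# Consequence vocabulary. The LoF set is a subset of the coding set.
lof_consequences <- c("stop_lost", "start_lost", "splice_donor_variant",
                      "frameshift_variant", "splice_acceptor_variant",
                      "stop_gained")

coding_consequences <- c("stop_lost", "missense_variant", "start_lost",
                         "splice_donor_variant", "inframe_deletion",
                         "frameshift_variant", "splice_acceptor_variant",
                         "stop_gained", "inframe_insertion")

non_qualifying_consequences <- c("synonymous_variant", "intron_variant",
                                 "5_prime_UTR_variant", "3_prime_UTR_variant",
                                 "splice_region_variant", "upstream_gene_variant",
                                 "downstream_gene_variant")

consequence_vocabulary <- function() {
  c(coding_consequences, non_qualifying_consequences)
}

check_model <- function(model) {
  if (!is.character(model) || length(model) != 1L ||
      !model %in% c("coding", "lof")) {
    abort('`model` must be "coding" or "lof"')
  }
  model
}

model_consequences <- function(model) {
  switch(check_model(model), coding = coding_consequences, lof = lof_consequences)
}
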