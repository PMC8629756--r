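#' Published two-cohort screening summary: significant associations
#'
#' A bundled summary of the 27 genes with population-level significant
#' (meta p < 1e-9) rare-variant gene-disease associations reported by a
#' published two-cohort exome screening study, with each gene's best
#' association, odds ratio and whether its PPV reached 0.3 in both cohorts in
#' the 60+ and all-ages strata. Useful as a worked example for the screening
#' gate and for validating the candidate-selection logic offline.
#'
#' @return Tibble with columns `gene_id`, `model`, `phenotype`, `p_meta`,
#'   `odds_ratio`, `ppv_pass_60plus`, `ppv_pass_all_ages`.
#' @examples
#' published_associations() |> ppv_flag_candidates()
#' @export
published_associations <- function() {
  tibble::tribble(
    ~gene_id, ~model, ~phenotype, ~p_meta, ~odds_ratio,
    ~ppv_pass_60plus, ~ppv_pass_all_ages,
    "HBB",      "lof",    "Other hemoglobinopathies",            1.91e-129, 197.2, TRUE,  TRUE,
    "PKD1",     "lof",    "Cystic kidney disease",               4.54e-48,   78.5, TRUE,  FALSE,
    "GCK",      "coding", "Type 2 diabetes",                     1.46e-33,   11.3, TRUE,  TRUE,
    "LDLR",     "lof",    "Coronary atherosclerosis",            1.46e-12,   17.5, TRUE,  TRUE,
    "BRCA2",    "lof",    "Malignant neoplasm of female breast", 3.96e-45,    8.5, TRUE,  FALSE,
    "BRCA1",    "lof",    "Malignant neoplasm of female breast", 8.77e-28,   14.2, TRUE,  FALSE,
    "MIP",      "coding", "Cataract",                            1.56e-10,    4.6, TRUE,  FALSE,
    "JAK2",     "coding", "Myeloproliferative disease",          6.41e-62,    7.6, FALSE, FALSE,
    "COL4A4",   "lof",    "Hematuria",                           8.96e-23,    4.6, FALSE, FALSE,
    "TTN",      "lof",    "Atrial fibrillation and flutter",     1.91e-17,    1.8, FALSE, FALSE,
    "MSH6",     "lof",    "Malignant neoplasm of uterus",        2.11e-17,   19.6, FALSE, FALSE,
    "MYBPC3",   "lof",    "Other hypertrophic cardiomyopathy",   5.07e-17,   70.2, FALSE, FALSE,
    "IFT140",   "lof",    "Cyst of kidney, acquired",            3.81e-16,   10.2, FALSE, FALSE,
    "NF1",      "lof",    "Other benign neoplasm of connective and other soft tissue", 1.25e-15, 14.9, FALSE, FALSE,
    "PKD2",     "coding", "Cystic kidney disease",               1.85e-15,    3.9, FALSE, FALSE,
    "TET2",     "lof",    "Neutropenia",                         2.34e-15,    4.8, FALSE, FALSE,
    "VWF",      "coding", "Von Willebrand disease",              2.77e-15,    6.7, FALSE, FALSE,
    "SF3B1",    "coding", "Myeloproliferative disease",          4.21e-13,   13.0, FALSE, FALSE,
    "CDKN2A",   "coding", "Melanomas of skin",                   5.57e-13,   10.2, FALSE, FALSE,
    "TSHR",     "coding", "Hypothyroidism not otherwise specified", 1.52e-12, 1.9, FALSE, FALSE,
    "PALB2",    "lof",    "Malignant neoplasm of female breast", 8.22e-12,    5.0, FALSE, FALSE,
    "ASXL1",    "lof",    "Myeloproliferative disease",          9.75e-12,   13.0, FALSE, FALSE,
    "PROC",     "coding", "Phlebitis and thrombophlebitis",      1.35e-11,    4.9, FALSE, FALSE,
    "ATM",      "lof",    "Malignant neoplasm of female breast", 2.49e-11,    4.9, FALSE, FALSE,
    "SLC22A12", "coding", "Gout",                                4.86e-11,    0.1, FALSE, FALSE,
    "MLH1",     "lof",    "Colon cancer",                        1.54e-10,  240.7, FALSE, FALSE,
    "SLC4A1",   "coding", "Other hereditary hemolytic anemias",  1.99e-10,   19.8, FALSE, FALSE)
}

#' Published two-cohort screening summary: candidate conditions
#'
#' Per-gene summary of the seven conditions that passed the dual-cohort
#' PPV >= 0.3 screen in the same published study: carrier frequency
#' (percent of participants with qualifying variants), best PPV, and whether
#' the gene is already part of existing population screening programs
#' (CDC Tier 1). The gestational-diabetes row is a secondary phenotype of
#' GCK; its carrier frequency is not counted again.
#'
#' @return Tibble with columns `gene_id`, `condition`, `pct_with_variant`,
#'   `ppv`, `in_existing_program`.
#' @examples
#' novel_screening_reach(published_screen_summary())
#' @export
published_screen_summary <- function() {
  tibble::tribble(
    ~gene_id, ~condition, ~pct_with_variant, ~ppv, ~in_existing_program,
    "BRCA1", "Hereditary breast and ovarian cancer", 0.11, 0.43, TRUE,
    "BRCA2", "Hereditary breast and ovarian cancer", 0.36, 0.35, TRUE,
    "GCK",   "Type 2 diabetes",                      0.06, 0.50, FALSE,
    "GCK",   "Gestational diabetes",                 NA,   0.82, FALSE,
    "HBB",   "Beta-thalassemia minor and intermedia", 0.06, 0.59, FALSE,
    "LDLR",  "Familial hypercholesterolemia",        0.03, 0.50, TRUE,
    "MIP",   "Cataracts",                            0.06, 0.43, FALSE,
    "PKD1",  "Chronic kidney disease",               0.03, 0.44, FALSE)
}

#' Candidate genes from printed dual-cohort PPV flags
#'
#' Applies the screening gate to a table of per-gene PPV flags: a gene is a
#' candidate when its PPV reached the threshold in both cohorts in the
#' all-ages stratum or in the 60+ stratum.
#'
#' @param associations Tibble with columns `gene_id`, `ppv_pass_60plus`,
#'   `ppv_pass_all_ages` (see [published_associations()]).
#' @return Character vector of candidate gene ids.
#' @examples
#' ppv_flag_candidates(published_associations())
#' @export
ppv_flag_candidates <- function(associations) {
  associations |>
    dplyr::filter(.data$ppv_pass_60plus | .data$ppv_pass_all_ages) |>
    dplyr::distinct(.data$gene_id) |>
    dplyr::pull("gene_id")
}

#' Additional screening reach of novel candidate genes
#'
#' Sums the carrier frequencies (percent of participants with qualifying
#' variants) of candidate genes not already covered by existing population
#' screening programs — the fraction of participants that adding the novel
#' genes to a screening panel would newly reach.
#'
#' @param summary Tibble as returned by [published_screen_summary()].
#' @return Percentage (e.g. 0.21 means 0.21% of participants).
#' @export
novel_screening_reach <- function(summary) {
  summary |>
    dplyr::filter(!.data$in_existing_program, !is.na(.data$pct_with_variant)) |>
    dplyr::distinct(.data$gene_id, .data$pct_with_variant) |>
    dplyr::summarise(reach = sum(.data$pct_with_variant)) |>
    dplyr::pull("reach")
}
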