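#' Sample-size-weighted Z-score meta-analysis statistic
#'
#' Combines two cohorts' signed Z statistics with weights
#' `z = (w_a z_a + w_b z_b) / sqrt(w_a^2 + w_b^2)` — the weighted-Z scheme
#' used for summary-statistic meta-analysis of binary traits.
#'
#' @param z_a,z_b Signed per-cohort Z statistics (vectorized).
#' @param w_a,w_b Per-cohort weights, conventionally the square root of the
#'   effective sample size `4 / (1/n_cases + 1/n_controls)`.
#' @return Numeric combined Z.
#' @examples
#' weighted_z(3, 3, 1, 1)  # sqrt(2) * 3
#' @export
weighted_z <- function(z_a, z_b, w_a, w_b) {
  (w_a * z_a + w_b * z_b) / sqrt(w_a^2 + w_b^2)
}

effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

#' Meta-analyze two cohorts' burden association results
#'
#' Joins the per-cohort association tables on (gene, phecode, model) and
#' combines their signed Z statistics by the sample-size-weighted Z-score,
#' weighting each cohort by the square root of its effective sample size
#' `4 / (1/n_cases + 1/n_controls)` (raw total n available as an option).
#' Triples present in only one cohort are ineligible and dropped.
#'
#' @param res_a,res_b Per-cohort association tibbles from
#'   [associate_cohort()] (suffixes `_a`/`_b` in the output follow this
#'   argument order).
#' @param weight_scheme `"effective_n"` (default) or `"raw_n"`.
#' @return Tibble with one row per shared triple: `z_meta`, `p_meta`
#'   (two-sided normal), per-cohort weights, carriers, p-values and the
#'   stratified PPV columns needed by [ppv_screen()].
#' @export
meta_analyze <- function(res_a, res_b,
                         weight_scheme = c("effective_n", "raw_n")) {
  weight_scheme <- match.arg(weight_scheme)
  keys <- c("gene_id", "phecode", "model")
  joined <- dplyr::inner_join(res_a, res_b, by = keys,
                              suffix = c("_a", "_b"))
  if (nrow(joined) == 0L) return(empty_meta_table())
  w_of <- function(n, n_cases) {
    if (weight_scheme == "effective_n") {
      sqrt(effective_n(n_cases, n - n_cases))
    } else {
      sqrt(n)
    }
  }
  joined |>
    dplyr::mutate(
      w_a = w_of(.data$n_a, .data$n_cases_a),
      w_b = w_of(.data$n_b, .data$n_cases_b),
      z_meta = weighted_z(.data$z_a, .data$z_b, .data$w_a, .data$w_b),
      p_meta = pmin(pmax(2 * pnorm(-abs(.data$z_meta)),
                         .Machine$double.xmin), 1)) |>
    dplyr::select(dplyr::all_of(keys), "z_meta", "p_meta", "w_a", "w_b",
                  "carriers_a", "carriers_b", "p_a", "p_b",
                  "odds_ratio_a", "odds_ratio_b",
                  "ppv_all_ages_a", "ppv_all_ages_b",
                  "ppv_60plus_a", "ppv_60plus_b",
                  "carrier_cases_60plus_a", "carrier_cases_60plus_b",
                  "a_a", "a_b")
}

empty_meta_table <- function() {
  tibble::tibble(gene_id = character(), phecode = character(),
                 model = character(), z_meta = numeric(), p_meta = numeric(),
                 w_a = numeric(), w_b = numeric(), carriers_a = integer(),
                 carriers_b = integer(), p_a = numeric(), p_b = numeric(),
                 odds_ratio_a = numeric(), odds_ratio_b = numeric(),
                 ppv_all_ages_a = numeric(), ppv_all_ages_b = numeric(),
                 ppv_60plus_a = numeric(), ppv_60plus_b = numeric(),
                 carrier_cases_60plus_a = integer(),
                 carrier_cases_60plus_b = integer(),
                 a_a = integer(), a_b = integer())
}

#' Apply the meta-analysis significance gates
#'
#' A triple is significant when (1) at least one carrier exists in each
#' cohort, (2) the meta p-value is strictly lower (better) than both
#' per-cohort p-values, and (3) it clears the Bonferroni level
#' (default p < 1e-9).
#'
#' @param meta Tibble from [meta_analyze()].
#' @inheritParams qualify_variants
#' @return `meta` with logical columns `gate_carriers_both`,
#'   `gate_meta_better`, `gate_bonferroni`, `significant` appended.
#' @export
significance_gate <- function(meta, thresholds = NULL) {
  t <- as_thresholds(thresholds)
  meta |>
    dplyr::mutate(
      gate_carriers_both = .data$carriers_a >= 1L & .data$carriers_b >= 1L,
      gate_meta_better = .data$p_meta < pmin(.data$p_a, .data$p_b),
      gate_bonferroni = .data$p_meta < t$bonferroni_alpha,
      significant = .data$gate_carriers_both & .data$gate_meta_better &
        .data$gate_bonferroni)
}

cohort_stratum_flag <- function(ppv, carrier_cases, ppv_min, min_display) {
  dplyr::case_when(
    is.na(ppv) | carrier_cases < min_display ~ "undefined",
    ppv >= ppv_min ~ "pass",
    TRUE ~ "fail")
}

#' Dual-cohort PPV screen of significant associations
#'
#' Partitions significant, risk-increasing associations by empirical
#' penetrance: a triple is a screening candidate when its PPV reaches
#' `ppv_min` (default 0.3) in *both* cohorts, in either the all-ages or the
#' 60+ (lifetime-risk) stratum — 60+ associations are included even if the
#' PPV was lower before age 60. A 60+ cohort-stratum whose PPV is undefined
#' or rests on fewer than `min_carrier_cases_display` carrier cases is not
#' taken at face value: under the default policy it passes through the
#' cohort's all-ages PPV and the pair is flagged for manual review; the
#' strict policy fails it.
#'
#' @param meta Gated tibble from [significance_gate()].
#' @inheritParams qualify_variants
#' @return Tibble of significant triples with per-cohort stratum flags
#'   (`"pass"`/`"fail"`/`"undefined"`), `displayable_*` indicators (at least
#'   5 carrier cases), `candidate`, `manual_review` and a `rationale` string
#'   recording which stratum carried the decision.
#' @export
ppv_screen <- function(meta, thresholds = NULL) {
  t <- as_thresholds(thresholds)
  if (!"significant" %in% names(meta)) meta <- significance_gate(meta, t)
  sig <- dplyr::filter(meta, .data$significant)
  if (nrow(sig) == 0L) return(dplyr::mutate(sig, flag_all_a = character(),
    flag_all_b = character(), flag_60_a = character(), flag_60_b = character(),
    displayable_60_a = logical(), displayable_60_b = logical(),
    candidate = logical(), manual_review = logical(), rationale = character()))

  sig |>
    dplyr::mutate(
      flag_all_a = cohort_stratum_flag(.data$ppv_all_ages_a, .data$a_a,
                                       t$ppv_min, 0L),
      flag_all_b = cohort_stratum_flag(.data$ppv_all_ages_b, .data$a_b,
                                       t$ppv_min, 0L),
      flag_60_a = cohort_stratum_flag(.data$ppv_60plus_a,
                                      .data$carrier_cases_60plus_a,
                                      t$ppv_min, t$min_carrier_cases_display),
      flag_60_b = cohort_stratum_flag(.data$ppv_60plus_b,
                                      .data$carrier_cases_60plus_b,
                                      t$ppv_min, t$min_carrier_cases_display),
      displayable_60_a = .data$carrier_cases_60plus_a >=
        t$min_carrier_cases_display,
      displayable_60_b = .data$carrier_cases_60plus_b >=
        t$min_carrier_cases_display,
      pass_all = .data$flag_all_a == "pass" & .data$flag_all_b == "pass",
      ok60_a = stratum_pass(.data$flag_60_a, .data$flag_all_a,
                            t$undefined_stratum_policy),
      ok60_b = stratum_pass(.data$flag_60_b, .data$flag_all_b,
                            t$undefined_stratum_policy),
      pass_60 = .data$ok60_a & .data$ok60_b,
      manual_review = .data$pass_60 & !.data$pass_all &
        (.data$flag_60_a == "undefined" | .data$flag_60_b == "undefined"),
      candidate = .data$z_meta > 0 & (.data$pass_all | .data$pass_60),
      rationale = dplyr::case_when(
        .data$z_meta <= 0 ~ "protective direction: excluded from PPV screen",
        .data$pass_all & .data$pass_60 ~ "PPV >= threshold in both cohorts (all ages and 60+)",
        .data$pass_all ~ "PPV >= threshold in both cohorts (all ages)",
        .data$pass_60 & .data$manual_review ~
          "PPV >= threshold in both cohorts (60+; one stratum undersized, passed via all-ages; manual review)",
        .data$pass_60 ~ "PPV >= threshold in both cohorts (60+)",
        TRUE ~ "below PPV threshold in at least one cohort")) |>
    dplyr::select(-"pass_all", -"pass_60", -"ok60_a", -"ok60_b")
}

stratum_pass <- function(flag60, flag_all, policy) {
  if (policy == "strict") return(flag60 == "pass")
  flag60 == "pass" | (flag60 == "undefined" & flag_all == "pass")
}

#' Assemble the screening report
#'
#' Combines the gated meta-analysis and the PPV screen into the final report:
#' the full association table (sorted candidates first, then by meta
#' p-value), and the candidate table keeping, for each gene, the significant
#' association with the best (highest) PPV.
#'
#' @param meta Gated tibble from [significance_gate()].
#' @inheritParams qualify_variants
#' @return Object of class `screen_report`: list with `associations` (full
#'   gated meta table), `screen` (per-significant-triple PPV decisions),
#'   `candidates` (one row per candidate gene, best PPV first) and `log`
#'   (character summary lines).
#' @export
build_report <- function(meta, thresholds = NULL) {
  t <- as_thresholds(thresholds)
  if (!"significant" %in% names(meta)) meta <- significance_gate(meta, t)
  screen <- ppv_screen(meta, t)
  best_ppv <- function(...) {
    v <- c(...)
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
  }
  screen <- screen |>
    dplyr::rowwise() |>
    dplyr::mutate(ppv_best = best_ppv(.data$ppv_all_ages_a, .data$ppv_all_ages_b,
                                      .data$ppv_60plus_a, .data$ppv_60plus_b)) |>
    dplyr::ungroup()
  candidates <- screen |>
    dplyr::filter(.data$candidate) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$ppv_best, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p_meta)
  associations <- meta |>
    dplyr::left_join(screen[, c("gene_id", "phecode", "model", "candidate")],
                     by = c("gene_id", "phecode", "model")) |>
    dplyr::mutate(candidate = !is.na(.data$candidate) & .data$candidate) |>
    dplyr::arrange(dplyr::desc(.data$candidate), .data$p_meta)
  log_lines <- c(
    sprintf("%d triples meta-analyzed", nrow(meta)),
    sprintf("%d significant (carriers in both cohorts, meta p better than both, p < %g)",
            sum(meta$significant), t$bonferroni_alpha),
    sprintf("%d candidate gene(s) with PPV >= %g in both cohorts",
            nrow(candidates), t$ppv_min))
  structure(list(associations = associations, screen = screen,
                 candidates = candidates, log = log_lines,
                 thresholds = t),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  for (l in x$log) cat(" ", l, "\n")
  if (nrow(x$candidates) > 0L) {
    cat("  candidates:\n")
    print(x$candidates[, c("gene_id", "phecode", "model", "p_meta",
                           "ppv_best", "rationale")])
  }
  invisible(x)
}

#' @rdname build_report
#' @param x A `screen_report`.
#' @param ... Unused.
#' @export
tidy.screen_report <- function(x, ...) x$screen

#' @rdname build_report
#' @export
glance.screen_report <- function(x, ...) {
  tibble::tibble(n_triples = nrow(x$associations),
                 n_significant = sum(x$associations$significant),
                 n_candidates = nrow(x$candidates))
}
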