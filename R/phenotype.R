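#' Map dated ICD diagnoses to a binary phecode matrix
#'
#' Codes each sample 1 for a phecode if at least one of its diagnosis events
#' maps to that phecode under the event's ICD system, 0 otherwise. A single
#' ICD code mapping to several phecodes sets all of them. ICD codes absent
#' from the map are counted and reported, never fatal.
#'
#' Age at first diagnosis is computed per (sample, phecode) under the
#' medical-history rule: the age at the earliest mapping event is kept only if
#' the first diagnosis of any condition in the sample's record occurred at
#' least 5 years before that event, or the event itself falls in the first
#' five years of life; otherwise the age is missing. Case status itself uses
#' all events and is not gated by the history rule.
#'
#' @param diagnoses Tibble with columns `sample_id`, `icd_code`, `icd_system`
#'   (`"icd9"`, `"icd10"` or `"icd10cm"`), `date` (Date).
#' @param phecode_map Tibble with columns `icd_code`, `icd_system`, `phecode`.
#' @param samples Sample manifest with `sample_id` and, for ages, `birth_date`.
#' @param phecodes Optional phecode universe (columns of the matrix); defaults
#'   to every phecode in the map.
#' @return An object of class `phenotype_matrix`: integer samples-by-phecodes
#'   0/1 matrix with attributes `ages` (tibble `sample_id`, `phecode`,
#'   `age_at_diagnosis`, `NA` when the history rule fails) and
#'   `n_unmapped_codes`. Use [tidy.phenotype_matrix()] for a long tibble.
#' @examples
#' m <- make_phecode_map("250.2")
#' dx <- tibble::tibble(sample_id = "S1", icd_code = m$icd_code[1],
#'                      icd_system = "icd9", date = as.Date("2018-01-01"))
#' sm <- tibble::tibble(sample_id = c("S1", "S2"),
#'                      birth_date = as.Date("1960-06-01"))
#' map_diagnoses(dx, m, sm)["S1", "250.2"]
#' @export
map_diagnoses <- function(diagnoses, phecode_map, samples, phecodes = NULL) {
  known_systems <- c("icd9", "icd10", "icd10cm")
  bad_sys <- setdiff(unique(diagnoses$icd_system), known_systems)
  if (length(bad_sys) > 0L) {
    abort(paste("unknown icd_system:", paste(bad_sys, collapse = ", ")))
  }
  unknown_samp <- setdiff(unique(diagnoses$sample_id), samples$sample_id)
  if (length(unknown_samp) > 0L) {
    abort(paste("diagnosis references sample(s) absent from manifest:",
                paste(head(unknown_samp, 5L), collapse = ", ")))
  }
  if (is.null(phecodes)) phecodes <- sort(unique(phecode_map$phecode))
  sample_ids <- samples$sample_id

  mapped <- dplyr::inner_join(diagnoses, phecode_map,
                              by = c("icd_code", "icd_system"),
                              relationship = "many-to-many")
  n_unmapped <- nrow(dplyr::anti_join(diagnoses, phecode_map,
                                      by = c("icd_code", "icd_system")))
  if (n_unmapped > 0L) {
    inform(sprintf("%d diagnosis event(s) had ICD codes absent from the phecode map",
                   n_unmapped))
  }

  m <- matrix(0L, nrow = length(sample_ids), ncol = length(phecodes),
              dimnames = list(sample_ids, phecodes))
  hits <- dplyr::distinct(mapped, .data$sample_id, .data$phecode)
  hits <- dplyr::filter(hits, .data$phecode %in% phecodes)
  if (nrow(hits) > 0L) {
    m[cbind(match(hits$sample_id, sample_ids),
            match(hits$phecode, phecodes))] <- 1L
  }

  ages <- if ("birth_date" %in% names(samples)) {
    diagnosis_ages(diagnoses, mapped, samples)
  } else {
    tibble::tibble(sample_id = character(), phecode = character(),
                   age_at_diagnosis = numeric())
  }
  structure(m, class = c("phenotype_matrix", "matrix", "array"),
            ages = ages, n_unmapped_codes = n_unmapped)
}

# history rule: >= 5 years of record before the first mapping event, or the
# event in the first five years of life
diagnosis_ages <- function(diagnoses, mapped, samples) {
  if (nrow(mapped) == 0L) {
    return(tibble::tibble(sample_id = character(), phecode = character(),
                          age_at_diagnosis = numeric()))
  }
  if (any(is.na(diagnoses$date))) abort("diagnosis dates must be parseable")
  first_any <- diagnoses |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(first_any_date = min(.data$date), .groups = "drop")
  mapped |>
    dplyr::group_by(.data$sample_id, .data$phecode) |>
    dplyr::summarise(first_dx_date = min(.data$date), .groups = "drop") |>
    dplyr::left_join(first_any, by = "sample_id") |>
    dplyr::left_join(samples[, c("sample_id", "birth_date")],
                     by = "sample_id") |>
    dplyr::mutate(
      age_raw = as.numeric(.data$first_dx_date - .data$birth_date) / 365.25,
      history_ok = as.numeric(.data$first_dx_date - .data$first_any_date) >=
        5 * 365.25 | .data$age_raw < 5,
      age_at_diagnosis = ifelse(.data$history_ok, floor(.data$age_raw),
                                NA_real_)) |>
    dplyr::select("sample_id", "phecode", "age_at_diagnosis") |>
    (\(x) { if (any(x$age_at_diagnosis < 0, na.rm = TRUE))
      abort("diagnosis event precedes birth date"); x })()
}

#' Age at the first history-valid diagnosis of one phecode for one sample
#'
#' @param events Tibble of one sample's diagnosis events (`icd_code`,
#'   `icd_system`, `date`).
#' @param phecode The phecode of interest.
#' @param phecode_map Map tibble (`icd_code`, `icd_system`, `phecode`).
#' @param birth_date The sample's birth date.
#' @return Age in completed years at the earliest event mapping to `phecode`,
#'   or `NA` if no event maps or the medical-history rule fails.
#' @export
age_at_first_valid_diagnosis <- function(events, phecode, phecode_map,
                                         birth_date) {
  if (nrow(events) == 0L) abort("sample has no events")
  dx <- events |> dplyr::mutate(sample_id = "s")
  samples <- tibble::tibble(sample_id = "s", birth_date = as.Date(birth_date))
  mapped <- dplyr::inner_join(dx, phecode_map, by = c("icd_code", "icd_system"),
                              relationship = "many-to-many") |>
    dplyr::filter(.data$phecode == .env$phecode)
  ages <- diagnosis_ages(dx, mapped, samples)
  if (nrow(ages) == 0L) return(NA_real_)
  ages$age_at_diagnosis[[1L]]
}

#' Per-phecode case counts
#' @param x A `phenotype_matrix`.
#' @return Named integer vector (column sums).
#' @export
case_counts <- function(x) {
  stopifnot(inherits(x, "phenotype_matrix"))
  colSums(unclass(x))
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("<phenotype_matrix> %d samples x %d phecodes, %d case entries (%d unmapped ICD events)\n",
              nrow(x), ncol(x), sum(x), attr(x, "n_unmapped_codes")))
  invisible(x)
}

#' Tidy a phenotype matrix into a long case tibble
#'
#' @param x A `phenotype_matrix`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `phecode`, `case`, `age_at_diagnosis`
#'   (cases only; age `NA` when the history rule failed).
#' @export
tidy.phenotype_matrix <- function(x, ...) {
  idx <- which(unclass(x) == 1L, arr.ind = TRUE)
  tibble::tibble(sample_id = rownames(x)[idx[, 1L]],
                 phecode = colnames(x)[idx[, 2L]],
                 case = 1L) |>
    dplyr::left_join(attr(x, "ages"), by = c("sample_id", "phecode")) |>
    dplyr::arrange(.data$phecode, .data$sample_id)
}

#' Restrict analysis phenotypes to those testable in both cohorts
#'
#' Keeps phecodes with at least one case in the larger cohort and at least
#' `min_cases_small_cohort` cases (default 30) in the smaller cohort.
#'
#' @param pm_a,pm_b `phenotype_matrix` objects for the two cohorts (any
#'   order; the smaller cohort is identified by its sample count).
#' @inheritParams qualify_variants
#' @return Sorted character vector of retained phecodes.
#' @export
filter_phenotypes <- function(pm_a, pm_b, thresholds = NULL) {
  t <- as_thresholds(thresholds)
  stopifnot(inherits(pm_a, "phenotype_matrix"),
            inherits(pm_b, "phenotype_matrix"))
  shared <- intersect(colnames(pm_a), colnames(pm_b))
  if (nrow(pm_a) >= nrow(pm_b)) {
    big <- pm_a; small <- pm_b
  } else {
    big <- pm_b; small <- pm_a
  }
  nb <- case_counts(big)[shared]
  ns <- case_counts(small)[shared]
  sort(shared[nb >= 1L & ns >= t$min_cases_small_cohort])
}
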