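#' Read and write cohort data bundles
#'
#' A cohort bundle is four tab-separated files in one directory:
#' `samples.tsv` (sample_id, sex, age, birth_date, record_start, record_end),
#' `variants.tsv` (annotated variants with a comma-separated `carriers`
#' column), `cnvs.tsv` (may be empty apart from the header) and
#' `diagnoses.tsv` (sample_id, icd_code, icd_system, date). ICD codes and
#' phecodes are always read as strings so leading zeros and decimal points
#' survive round trips.
#'
#' Reading enforces cross-file referential integrity: every variant carrier
#' and every diagnosis sample must appear in the manifest, all allele and CNV
#' frequencies must lie in `[0, 1]`, and dates must parse; violations are
#' fatal and name the offending sample or column.
#'
#' @param dir Directory holding (or receiving) the four files.
#' @param cohort Cohort bundle: list with `samples`, `variants`, `cnvs`,
#'   `diagnoses` tibbles.
#' @return `read_cohort_data()` returns a cohort bundle list;
#'   `write_cohort_data()` returns `dir` invisibly.
#' @export
read_cohort_data <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("samples.tsv", "variants.tsv", "cnvs.tsv", "diagnoses.tsv")) {
    if (!file.exists(path(f))) abort(paste("missing input file:", path(f)))
  }
  samples <- readr::read_tsv(
    path("samples.tsv"), show_col_types = FALSE,
    col_types = readr::cols(sample_id = "c", sex = "c", age = "i",
                            birth_date = readr::col_date(),
                            record_start = readr::col_date(),
                            record_end = readr::col_date()))
  variants <- readr::read_tsv(
    path("variants.tsv"), show_col_types = FALSE,
    col_types = readr::cols(variant_id = "c", gene_id = "c",
                            consequence = "c", carriers = "c",
                            .default = readr::col_double()))
  cnvs <- readr::read_tsv(
    path("cnvs.tsv"), show_col_types = FALSE,
    col_types = readr::cols(sample_id = "c", gene_id = "c", cnv_type = "c",
                            n_exons_overlapped = "i", qc_pass = "l",
                            exon_freq = "d", event_freq = "d"))
  diagnoses <- readr::read_tsv(
    path("diagnoses.tsv"), show_col_types = FALSE,
    col_types = readr::cols(sample_id = "c", icd_code = "c",
                            icd_system = "c", date = readr::col_date()))
  validate_cohort(list(samples = samples, variants = variants, cnvs = cnvs,
                       diagnoses = diagnoses))
}

#' @rdname read_cohort_data
#' @export
write_cohort_data <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"),
                   quote = "all")
  readr::write_tsv(cohort$variants, file.path(dir, "variants.tsv"),
                   quote = "all")
  readr::write_tsv(cohort$cnvs, file.path(dir, "cnvs.tsv"), quote = "all")
  readr::write_tsv(cohort$diagnoses, file.path(dir, "diagnoses.tsv"),
                   quote = "all")
  invisible(dir)
}

validate_cohort <- function(cohort) {
  req <- list(
    samples = c("sample_id", "sex", "age"),
    variants = c("variant_id", "gene_id", "consequence", "polyphen_score",
                 "sift_score", "local_af", "carriers"),
    cnvs = c("sample_id", "gene_id", "cnv_type", "n_exons_overlapped",
             "qc_pass", "exon_freq", "event_freq"),
    diagnoses = c("sample_id", "icd_code", "icd_system", "date"))
  for (tbl in names(req)) {
    miss <- setdiff(req[[tbl]], names(cohort[[tbl]]))
    if (length(miss) > 0L) {
      abort(sprintf("%s.tsv lacks column(s): %s", tbl,
                    paste(miss, collapse = ", ")))
    }
  }
  ids <- cohort$samples$sample_id
  carr <- carrier_pairs(cohort$variants)
  bad <- setdiff(carr$sample_id, ids)
  if (length(bad) > 0L) {
    abort(paste("variant carrier(s) absent from manifest:",
                paste(head(bad, 5L), collapse = ", ")))
  }
  bad <- setdiff(cohort$diagnoses$sample_id, ids)
  if (length(bad) > 0L) {
    abort(paste("diagnosis references unknown sample(s):",
                paste(head(bad, 5L), collapse = ", ")))
  }
  bad <- setdiff(cohort$cnvs$sample_id, ids)
  if (length(bad) > 0L) {
    abort(paste("CNV references unknown sample(s):",
                paste(head(bad, 5L), collapse = ", ")))
  }
  freq_cols <- c(grep("^gnomad_af_", names(cohort$variants), value = TRUE),
                 "local_af")
  for (cl in freq_cols) {
    v <- cohort$variants[[cl]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort(paste("allele frequency outside [0, 1] in column", cl))
    }
  }
  if (any(is.na(cohort$diagnoses$date))) abort("unparseable diagnosis dates")
  cohort
}

#' Read or write a phecode map CSV
#'
#' Columns `icd_code`, `icd_system`, `phecode`, all strings (leading zeros
#' and decimal points are preserved).
#'
#' @param path CSV file path.
#' @param map Map tibble.
#' @return The map tibble (reading); `path` invisibly (writing).
#' @export
read_phecode_map <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  miss <- setdiff(c("icd_code", "icd_system", "phecode"), names(m))
  if (length(miss) > 0L) {
    abort(paste("phecode map lacks column(s):", paste(miss, collapse = ", ")))
  }
  if (any(!nzchar(m$phecode) | is.na(m$phecode))) {
    abort("phecode map contains empty phecode entries")
  }
  m
}

#' @rdname read_phecode_map
#' @export
write_phecode_map <- function(map, path) {
  readr::write_csv(map, path)
  invisible(path)
}

#' Read an emitted summary-statistics TSV
#'
#' Reads back any table written by [write_screen_run()], forcing identifier
#' columns (`gene_id`, `phecode`, `model`, ICD codes) to stay strings.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_screen_table <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1L), "\t")[[1]]
  hdr <- gsub('"', "", hdr, fixed = TRUE)
  string_cols <- intersect(hdr, c("gene_id", "phecode", "model", "rationale",
                                  "icd_code", "icd_system", "sample_id"))
  spec <- stats::setNames(
    lapply(string_cols, function(x) readr::col_character()), string_cols)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = do.call(readr::cols, spec))
}

#' Load a pipeline run configuration from YAML
#'
#' The YAML file names the two cohort directories, the phecode map, the
#' models to run, the seed and any threshold overrides, e.g.:
#' ```yaml
#' cohorts:
#'   cohort_a: data/cohort_a
#'   cohort_b: data/cohort_b
#' phecode_map: data/phecode_map.csv
#' models: [coding, lof]
#' seed: 1
#' thresholds:
#'   ppv_min: 0.3
#' ```
#'
#' @param path YAML file.
#' @return List with `cohorts` (named paths), `phecode_map`, `models`,
#'   `seed`, `thresholds` (a [screen_thresholds()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cohorts) || length(cfg$cohorts) != 2L) {
    abort("config must name exactly two cohorts")
  }
  for (p in unlist(cfg$cohorts)) {
    if (!dir.exists(p)) abort(paste("cohort directory does not exist:", p))
  }
  if (is.null(cfg$phecode_map) || !file.exists(cfg$phecode_map)) {
    abort("config must point at an existing phecode_map CSV")
  }
  list(cohorts = cfg$cohorts,
       phecode_map = cfg$phecode_map,
       models = cfg$models %||% c("coding", "lof"),
       seed = cfg$seed %||% 1L,
       thresholds = as_thresholds(cfg$thresholds))
}

#' Run the full screening pipeline in memory
#'
#' Chains the stages on two cohort bundles: collapse qualifying variants and
#' CNVs into burden matrices (per model), build phecode phenotype matrices,
#' restrict to analysis phenotypes (cases in both cohorts, at least 30 in the
#' smaller), run the covariate-adjusted Firth burden scan per cohort,
#' meta-analyze by weighted Z-score, gate significance, and issue the
#' dual-cohort PPV screen.
#'
#' @param cohorts Named list of two cohort bundles (first = cohort "a"); see
#'   [read_cohort_data()] or [generate_cohorts()].
#' @param phecode_map Map tibble (`icd_code`, `icd_system`, `phecode`).
#' @inheritParams qualify_variants
#' @param models Collapsing models to run (subset of `"coding"`, `"lof"`).
#' @inheritParams fit_burden_test
#' @return Object of class `screen_run`: list with `per_model` (for each
#'   model: `assoc_a`, `assoc_b`, `meta`, `report`), `filtered_phecodes`,
#'   `phenotypes` (per-cohort matrices), `thresholds`, `models`.
#' @examples
#' sim <- generate_cohorts(sim_config(cohort_sizes = c(1200, 600), seed = 3),
#'                         default_sim_truth(n_null = 3, n_causal = 1))
#' run <- run_screen(sim$cohorts, sim$phecode_map,
#'                   thresholds = list(min_cases_small_cohort = 2),
#'                   models = "lof")
#' glance(run$per_model$lof$report)
#' @export
run_screen <- function(cohorts, phecode_map, thresholds = NULL,
                       models = c("coding", "lof"), method = "LRT") {
  t <- as_thresholds(thresholds)
  stopifnot(length(cohorts) == 2L)
  models <- match.arg(models, c("coding", "lof"), several.ok = TRUE)
  ids <- names(cohorts) %||% c("a", "b")

  genes <- sort(unique(unlist(lapply(cohorts, function(co) {
    c(co$variants$gene_id, co$cnvs$gene_id)
  }))))
  phecodes <- sort(unique(phecode_map$phecode))

  pms <- lapply(cohorts, function(co) {
    map_diagnoses(co$diagnoses, phecode_map, co$samples, phecodes = phecodes)
  })
  keep_ph <- filter_phenotypes(pms[[1]], pms[[2]], t)

  per_model <- list()
  for (model in models) {
    res <- lapply(seq_along(cohorts), function(k) {
      co <- cohorts[[k]]
      bm <- collapse_burden(co$variants, co$samples, cnvs = co$cnvs,
                            model = model, thresholds = t, genes = genes)
      associate_cohort(bm, pms[[k]], co$samples, phecodes = keep_ph,
                       thresholds = t, method = method)
    })
    meta <- significance_gate(meta_analyze(res[[1]], res[[2]]), t)
    report <- build_report(meta, t)
    per_model[[model]] <- list(assoc_a = res[[1]], assoc_b = res[[2]],
                               meta = meta, report = report)
  }
  structure(list(per_model = per_model, filtered_phecodes = keep_ph,
                 phenotypes = stats::setNames(pms, ids), thresholds = t,
                 models = models, cohort_ids = ids),
            class = "screen_run")
}

#' @export
print.screen_run <- function(x, ...) {
  cat(sprintf("<screen_run> cohorts: %s; %d analysis phenotypes\n",
              paste(x$cohort_ids, collapse = ", "),
              length(x$filtered_phecodes)))
  for (m in names(x$per_model)) {
    g <- glance(x$per_model[[m]]$report)
    cat(sprintf("  %-6s model: %d triples, %d significant, %d candidate gene(s)\n",
                m, g$n_triples, g$n_significant, g$n_candidates))
  }
  invisible(x)
}

#' Candidate table across models of a pipeline run
#'
#' One row per candidate (gene, phecode) keeping the model with the best PPV,
#' mirroring the layout of a published candidate table: gene, model,
#' phenotype, meta p, odds ratios and PPV flags per stratum.
#'
#' @param run A `screen_run`.
#' @return Tibble of candidates sorted by meta p-value.
#' @export
candidate_table <- function(run) {
  stopifnot(inherits(run, "screen_run"))
  all_cand <- dplyr::bind_rows(lapply(run$per_model,
                                      function(m) m$report$candidates))
  if (nrow(all_cand) == 0L) return(all_cand)
  all_cand |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$ppv_best, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p_meta)
}

#' Write a pipeline run to an artifact directory
#'
#' Emits, per model, the two per-cohort summary-statistic TSVs, the gated
#' meta TSV and the candidate TSV, plus a `provenance.yaml` sidecar carrying
#' the threshold set, the input hash and the package version, so a rerun can
#' be verified byte-for-byte.
#'
#' @param run A `screen_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_run <- function(run, dir) {
  stopifnot(inherits(run, "screen_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(run$per_model)) {
    pm <- run$per_model[[m]]
    readr::write_tsv(pm$assoc_a, file.path(dir, paste0("assoc_", m, "_a.tsv")),
                     quote = "all")
    readr::write_tsv(pm$assoc_b, file.path(dir, paste0("assoc_", m, "_b.tsv")),
                     quote = "all")
    readr::write_tsv(pm$meta, file.path(dir, paste0("meta_", m, ".tsv")),
                     quote = "all")
    readr::write_tsv(pm$report$screen,
                     file.path(dir, paste0("screen_", m, ".tsv")),
                     quote = "all")
  }
  cand <- candidate_table(run)
  readr::write_tsv(cand, file.path(dir, "candidates.tsv"), quote = "all")
  prov <- list(
    package = "ppvscreen",
    version = as.character(utils::packageVersion("ppvscreen")),
    models = run$models,
    thresholds = unclass(run$thresholds),
    content_hash = rlang::hash(lapply(run$per_model, function(m) m$meta)))
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
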