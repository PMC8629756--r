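#' Simulation configuration for a two-cohort screening study
#'
#' Describes two population cohorts of differing size, sex ratio, age range and
#' ICD coding dialect, emulating a biobank-style cohort (restricted ages,
#' ICD-9 + ICD-10) alongside a health-system cohort (wide ages,
#' ICD-9 + ICD-10-CM) at desk scale.
#'
#' @param cohort_sizes Two positive, unequal sample counts (default
#'   `c(20000, 5000)`).
#' @param cohort_ids Names for the two cohorts.
#' @param sex_fraction_female Per-cohort probability that a sample is female
#'   (defaults 0.55 and 0.68).
#' @param age_range List of two `c(min, max)` age ranges in years (defaults
#'   40-69 and 18-89).
#' @param icd_dialects List of two character vectors naming the ICD systems
#'   each cohort's records use (subset of `"icd9"`, `"icd10"`, `"icd10cm"`).
#' @param cnv_cohorts Cohort ids whose platform calls CNVs; other cohorts emit
#'   none (default: the second cohort only).
#' @param seed Integer seed; fully determines the generated data.
#' @param extraction_date Date at which ages and record spans are measured.
#' @param history_ok_fraction Fraction of simulated cases whose first target
#'   diagnosis falls at least 5 years after the start of their record, so that
#'   age-at-diagnosis passes the medical-history rule (default 1).
#' @param background_phecodes Tibble with columns `phecode`, `prevalence`
#'   giving disease codes unrelated to any gene; `NULL` for a default set.
#'
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(cohort_sizes = c(2000, 800), seed = 7)
#' @export
sim_config <- function(cohort_sizes = c(20000L, 5000L),
                       cohort_ids = c("cohort_a", "cohort_b"),
                       sex_fraction_female = c(0.55, 0.68),
                       age_range = list(c(40, 69), c(18, 89)),
                       icd_dialects = list(c("icd9", "icd10"),
                                           c("icd9", "icd10cm")),
                       cnv_cohorts = cohort_ids[2],
                       seed = 1L,
                       extraction_date = as.Date("2020-07-01"),
                       history_ok_fraction = 1,
                       background_phecodes = NULL) {
  if (length(cohort_sizes) != 2L || any(cohort_sizes <= 0)) {
    abort("`cohort_sizes` must be two positive counts")
  }
  if (cohort_sizes[1] == cohort_sizes[2]) {
    abort("cohort sizes must differ (the screen distinguishes a larger and a smaller cohort)")
  }
  if (length(cohort_ids) != 2L || anyDuplicated(cohort_ids)) {
    abort("`cohort_ids` must be two distinct names")
  }
  stopifnot(length(sex_fraction_female) == 2L,
            all(sex_fraction_female >= 0 & sex_fraction_female <= 1),
            length(age_range) == 2L, length(icd_dialects) == 2L)
  ok_sys <- c("icd9", "icd10", "icd10cm")
  if (!all(unlist(icd_dialects) %in% ok_sys)) {
    abort("icd_dialects entries must be among icd9, icd10, icd10cm")
  }
  if (history_ok_fraction < 0 || history_ok_fraction > 1) {
    abort("`history_ok_fraction` must lie in [0, 1]")
  }
  if (is.null(background_phecodes)) {
    background_phecodes <- tibble::tibble(
      phecode = c("401.1", "272.1", "296.2", "562.1", "079.9"),
      prevalence = c(0.20, 0.12, 0.08, 0.04, 0.002))
  }
  structure(
    list(cohort_sizes = as.integer(cohort_sizes), cohort_ids = cohort_ids,
         sex_fraction_female = sex_fraction_female, age_range = age_range,
         icd_dialects = icd_dialects, cnv_cohorts = cnv_cohorts,
         seed = as.integer(seed), extraction_date = as.Date(extraction_date),
         history_ok_fraction = history_ok_fraction,
         background_phecodes = background_phecodes),
    class = "sim_config")
}

#' Per-gene simulation truth
#'
#' One row per gene: whether the gene is causal for its target phecode, the
#' carrier frequency of qualifying variants, the lifetime penetrance among
#' carriers, and the background prevalence among non-carriers.
#'
#' @param gene_id Character gene identifiers.
#' @param is_causal Logical; causal genes raise the probability of the target
#'   phecode among carriers to `penetrance`.
#' @param carrier_freq Per-gene probability that a sample carries a qualifying
#'   variant or CNV (must be `<= 0.01`; rare-variant regime).
#' @param penetrance Probability that a carrier of a causal gene acquires the
#'   target phecode.
#' @param target_phecode Phecode raised by the gene (`NA` for null genes).
#' @param background_prevalence Probability that a non-carrier acquires the
#'   target phecode.
#' @param lof_fraction Fraction of qualifying variant sites that are
#'   loss-of-function (the rest are damaging missense).
#' @param cnv_fraction Fraction of carriers whose qualifying event is an
#'   exonic deletion call rather than a sequence variant (applies only in
#'   cohorts whose platform calls CNVs).
#'
#' @return A tibble of class `sim_truth`.
#' @examples
#' sim_truth("GENE1", TRUE, 0.004, 0.8, "250.2", 0.01)
#' @export
sim_truth <- function(gene_id, is_causal, carrier_freq, penetrance,
                      target_phecode = NA_character_,
                      background_prevalence = 0.01,
                      lof_fraction = 0.7, cnv_fraction = 0) {
  out <- tibble::tibble(
    gene_id = as.character(gene_id),
    is_causal = as.logical(is_causal),
    carrier_freq = as.numeric(carrier_freq),
    penetrance = as.numeric(penetrance),
    target_phecode = as.character(target_phecode),
    background_prevalence = as.numeric(background_prevalence),
    lof_fraction = as.numeric(lof_fraction),
    cnv_fraction = as.numeric(cnv_fraction))
  probs <- c(out$carrier_freq, out$penetrance, out$background_prevalence,
             out$lof_fraction, out$cnv_fraction)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (any(out$carrier_freq > 0.01)) {
    abort("`carrier_freq` must be <= 0.01 (rare-variant regime)")
  }
  bad <- out$is_causal & (out$penetrance < out$background_prevalence)
  if (any(bad)) abort("causal genes need penetrance >= background_prevalence")
  if (any(out$is_causal & is.na(out$target_phecode))) {
    abort("causal genes need a target_phecode")
  }
  class(out) <- c("sim_truth", class(out))
  out
}

#' Default desk-scale truth set
#'
#' 50 null genes plus 5 causal genes whose carrier frequencies (0.1-0.4%) and
#' penetrances (0.4-0.8) span the regime in which population screening
#' candidates live.
#'
#' @param n_null,n_causal Gene counts.
#' @param cnv_fraction Fraction of causal-gene carriers carrying an exonic
#'   deletion instead of a sequence variant (default 0.15).
#' @return A `sim_truth` tibble.
#' @export
default_sim_truth <- function(n_null = 50L, n_causal = 5L, cnv_fraction = 0.15) {
  null_freqs <- rep(c(0.0005, 0.001, 0.002, 0.003, 0.004), length.out = n_null)
  causal_freq <- rep(c(0.004, 0.003, 0.0025, 0.002, 0.001), length.out = n_causal)
  causal_pen <- rep(c(0.8, 0.7, 0.6, 0.5, 0.4), length.out = n_causal)
  dplyr::bind_rows(
    sim_truth(sprintf("NULLG%03d", seq_len(n_null)), FALSE, null_freqs,
              penetrance = 0, target_phecode = NA_character_,
              background_prevalence = 0, cnv_fraction = cnv_fraction),
    sim_truth(sprintf("CAUSG%03d", seq_len(n_causal)), TRUE, causal_freq,
              causal_pen,
              target_phecode = sprintf("%.1f", 700 + seq_len(n_causal) / 10),
              background_prevalence = 0.01, cnv_fraction = cnv_fraction))
}

#' Synthetic phecode map fixture
#'
#' Builds a deterministic ICD-to-phecode map covering the requested phecodes in
#' all three ICD systems (one ICD-9, one ICD-10 and one ICD-10-CM code per
#' phecode). The codes are synthetic; the map's structure (string codes,
#' decimal phecodes, per-system tables) mirrors the published phecode map
#' layout.
#'
#' @param phecodes Character vector of phecodes to cover.
#' @return A tibble with columns `icd_code`, `icd_system`, `phecode`.
#' @examples
#' make_phecode_map(c("250.2", "401.1"))
#' @export
make_phecode_map <- function(phecodes) {
  phecodes <- unique(as.character(phecodes))
  i <- seq_along(phecodes)
  tibble::tibble(
    icd_code = c(sprintf("%03d.%02d", 100 + i, i %% 100),
                 sprintf("Q%02d.%d", i %% 100, i %% 10),
                 sprintf("R%02d.%d", i %% 100, i %% 10)),
    icd_system = rep(c("icd9", "icd10", "icd10cm"), each = length(i)),
    phecode = rep(phecodes, times = 3L))
}

#' Emit an ICD diagnosis stream for one sample's phecodes
#'
#' Inverse of the phenotype mapping: for each truth phecode, selects an ICD
#' code from the map that resolves back to that phecode under the requested
#' dialect. Mapping the emitted stream through the same map recovers exactly
#' the truth phecode set.
#'
#' @param phecodes Character vector of phecodes the sample truly has.
#' @param phecode_map Map tibble (`icd_code`, `icd_system`, `phecode`).
#' @param dialect Character vector of ICD systems available to this cohort.
#' @return Tibble with columns `icd_code`, `icd_system`, `phecode`; zero rows
#'   for an empty truth set.
#' @examples
#' m <- make_phecode_map("250.2")
#' emit_icd_stream("250.2", m, c("icd9", "icd10"))
#' @export
emit_icd_stream <- function(phecodes, phecode_map, dialect) {
  phecodes <- as.character(phecodes)
  if (length(phecodes) == 0L) {
    return(tibble::tibble(icd_code = character(), icd_system = character(),
                          phecode = character()))
  }
  pool <- dplyr::filter(phecode_map, .data$icd_system %in% dialect)
  missing <- setdiff(phecodes, pool$phecode)
  if (length(missing) > 0L) {
    abort(paste0("phecode(s) absent from map for dialect [",
                 paste(dialect, collapse = ","), "]: ",
                 paste(missing, collapse = ", ")))
  }
  # rotate through the available systems so every dialect member is exercised
  pool |>
    dplyr::filter(.data$phecode %in% phecodes) |>
    dplyr::group_by(.data$phecode) |>
    dplyr::slice(1L + (dplyr::cur_group_id() %% dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::select("icd_code", "icd_system", "phecode")
}

cohort_stream_seed <- function(seed, cohort_index) {
  as.integer((as.numeric(seed) * 1000003 + cohort_index * 7919) %% 2147483647)
}

#' Generate two synthetic cohorts with known genetic truth
#'
#' Draws, per cohort, a sample manifest, an annotated rare-variant table (with
#' benign, common and synonymous decoys interleaved so every qualification
#' clause is exercised), exon-level CNV calls where the cohort's platform
#' supports them, and a dated ICD diagnosis stream consistent with a phecode
#' map fixture. Carriers of a causal gene acquire its target phecode with
#' probability `penetrance`; non-carriers with `background_prevalence`.
#'
#' @param config A [sim_config()].
#' @param truth A [sim_truth()] tibble.
#' @return A list of class `sim_cohorts`: `cohorts` (named per-cohort lists
#'   with tibbles `samples`, `variants`, `cnvs`, `diagnoses`, plus truth
#'   labels `truth_carriers` and `truth_cases`), `phecode_map`, `truth`,
#'   `config`.
#' @examples
#' cfg <- sim_config(cohort_sizes = c(1500, 600), seed = 11)
#' sim <- generate_cohorts(cfg, default_sim_truth(n_null = 5, n_causal = 2))
#' names(sim$cohorts)
#' @export
generate_cohorts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(truth, "sim_truth")) truth <- sim_truth_validate(truth)
  if (nrow(truth) == 0L) abort("gene set must be non-empty")

  target_phecodes <- unique(stats::na.omit(truth$target_phecode))
  all_phecodes <- union(target_phecodes, config$background_phecodes$phecode)
  phecode_map <- make_phecode_map(all_phecodes)

  cohorts <- list()
  for (k in 1:2) {
    cohorts[[config$cohort_ids[k]]] <-
      generate_one_cohort(config, truth, phecode_map, k)
  }
  structure(list(cohorts = cohorts, phecode_map = phecode_map,
                 truth = truth, config = config),
            class = "sim_cohorts")
}

sim_truth_validate <- function(truth) {
  do.call(sim_truth, as.list(truth[, c("gene_id", "is_causal", "carrier_freq",
                                       "penetrance", "target_phecode",
                                       "background_prevalence", "lof_fraction",
                                       "cnv_fraction")]))
}

#' @export
print.sim_cohorts <- function(x, ...) {
  cat("<sim_cohorts>\n")
  for (id in names(x$cohorts)) {
    co <- x$cohorts[[id]]
    cat(sprintf("  %s: %d samples, %d variants, %d CNVs, %d diagnoses\n",
                id, nrow(co$samples), nrow(co$variants), nrow(co$cnvs),
                nrow(co$diagnoses)))
  }
  cat(sprintf("  %d genes (%d causal), %d phecodes in map\n",
              nrow(x$truth), sum(x$truth$is_causal),
              length(unique(x$phecode_map$phecode))))
  invisible(x)
}

generate_one_cohort <- function(config, truth, phecode_map, k) {
  n <- config$cohort_sizes[k]
  cohort_id <- config$cohort_ids[k]
  dialect <- config$icd_dialects[[k]]
  has_cnv <- cohort_id %in% config$cnv_cohorts
  set.seed(cohort_stream_seed(config$seed, k))

  ## ---- manifest ----
  prefix <- toupper(substr(cohort_id, nchar(cohort_id), nchar(cohort_id)))
  sample_id <- sprintf("%s%06d", prefix, seq_len(n))
  sex <- ifelse(runif(n) < config$sex_fraction_female[k], "F", "M")
  rng <- config$age_range[[k]]
  age <- floor(runif(n, rng[1], rng[2] + 1))
  extraction <- config$extraction_date
  birth_date <- extraction - round(age * 365.25 + runif(n, 0, 364))
  record_years <- runif(n, 8, 25)
  record_start <- pmax(birth_date, extraction - round(record_years * 365.25))
  samples <- tibble::tibble(sample_id, sex, age = as.integer(age),
                            birth_date, record_start, record_end = extraction)

  ## ---- carriers and variant table (gene order fixed by truth order) ----
  variant_rows <- vector("list", nrow(truth))
  cnv_rows <- vector("list", nrow(truth))
  carrier_rows <- vector("list", nrow(truth))
  # per-site carrier chunk keeps each site's local AF near half the MAF cutoff
  chunk <- max(1L, floor(2 * n * 0.0005))
  gnomad_pops <- c("afr", "amr", "eas", "nfe", "sas")

  for (g in seq_len(nrow(truth))) {
    tr <- truth[g, ]
    gene <- tr$gene_id
    carriers <- sample_id[runif(n) < tr$carrier_freq]
    via_cnv <- logical(length(carriers))
    if (has_cnv && length(carriers) > 0L && tr$cnv_fraction > 0) {
      via_cnv <- runif(length(carriers)) < tr$cnv_fraction
    }
    carrier_rows[[g]] <- tibble::tibble(gene_id = gene, sample_id = carriers,
                                        via_cnv = via_cnv)
    seq_carriers <- carriers[!via_cnv]

    ## qualifying variant sites carrying the sequence carriers
    vr <- list()
    if (length(seq_carriers) > 0L) {
      n_sites <- ceiling(length(seq_carriers) / chunk)
      site_of <- rep(seq_len(n_sites), each = chunk)[seq_along(seq_carriers)]
      is_lof <- runif(n_sites) < tr$lof_fraction
      for (s in seq_len(n_sites)) {
        members <- seq_carriers[site_of == s]
        cons <- if (is_lof[s]) {
          sample(lof_consequences, 1L)
        } else "missense_variant"
        scored <- cons == "missense_variant"
        vr[[length(vr) + 1L]] <- variant_row(
          gene, g, 1000L + s * 10L, cons,
          polyphen = if (scored) round(runif(1, 0.6, 1), 3) else NA_real_,
          sift = if (scored) round(runif(1, 0, 0.03), 3) else NA_real_,
          gnomad = round(runif(length(gnomad_pops), 0, 5e-4), 6),
          local_af = length(members) / (2 * n), carriers = members,
          pops = gnomad_pops)
      }
    }

    ## decoys: one per qualification clause
    decoy_specs <- list(
      list(pos = 1L, cons = "synonymous_variant", poly = NA_real_,
           sift = NA_real_, gno = 2e-4, freq = 0.0008),
      list(pos = 2L, cons = "missense_variant", poly = 0.05, sift = 0.01,
           gno = 2e-4, freq = 0.0008),
      list(pos = 3L, cons = "missense_variant", poly = 0.9, sift = 0.5,
           gno = 2e-4, freq = 0.0008),
      list(pos = 4L, cons = "missense_variant", poly = 0.9, sift = 0.01,
           gno = 5e-3, freq = 0.0008),
      list(pos = 5L, cons = "missense_variant", poly = 0.9, sift = 0.01,
           gno = 2e-4, freq = NA))
    for (d in decoy_specs) {
      members <- if (is.na(d$freq)) {
        # locally common decoy: carrier count pinned above the MAF cutoff
        sample(sample_id, max(3L, ceiling(n * 0.003)))
      } else {
        sample_id[runif(n) < d$freq]
      }
      if (length(members) == 0L) next
      gno <- round(runif(length(gnomad_pops), 0, 2e-4), 6)
      gno[4] <- d$gno
      vr[[length(vr) + 1L]] <- variant_row(
        gene, g, d$pos, d$cons, d$poly, d$sift, gno,
        local_af = length(members) / (2 * n), carriers = members,
        pops = gnomad_pops)
    }
    variant_rows[[g]] <- dplyr::bind_rows(vr)

    ## CNV events: qualifying deletions for CNV carriers, plus decoys
    if (has_cnv) {
      cnv_carriers <- carriers[via_cnv]
      cr <- list()
      if (length(cnv_carriers) > 0L) {
        # each carrier's deletion has its own breakpoints and exon span, so
        # both the event- and exon-level frequencies are singleton frequencies
        cr[[1]] <- tibble::tibble(
          sample_id = cnv_carriers, gene_id = gene, cnv_type = "deletion",
          n_exons_overlapped = 1L + rbinom(length(cnv_carriers), 4, 0.4),
          qc_pass = TRUE,
          exon_freq = 1 / n,
          event_freq = 1 / n)
      }
      decoy_cnv <- sample_id[runif(n) < 0.0004]
      if (length(decoy_cnv) > 0L) {
        half <- runif(length(decoy_cnv)) < 0.5
        cr[[length(cr) + 1L]] <- tibble::tibble(
          sample_id = decoy_cnv, gene_id = gene, cnv_type = "deletion",
          n_exons_overlapped = 2L,
          qc_pass = half,                       # QC-fail decoys
          exon_freq = ifelse(half, 0.004, 3e-4), # common-frequency decoys
          event_freq = ifelse(half, 0.004, 3e-4))
      }
      cnv_rows[[g]] <- dplyr::bind_rows(cr)
    }
  }
  variants <- dplyr::bind_rows(variant_rows)
  cnvs <- if (has_cnv) dplyr::bind_rows(cnv_rows) else empty_cnv_table()
  truth_carriers <- dplyr::bind_rows(carrier_rows)

  ## ---- phenotype truth and diagnosis stream ----
  case_rows <- vector("list", 0L)
  for (g in which(truth$is_causal)) {
    tr <- truth[g, ]
    is_carrier <- sample_id %in%
      truth_carriers$sample_id[truth_carriers$gene_id == tr$gene_id]
    p_case <- ifelse(is_carrier, tr$penetrance, tr$background_prevalence)
    cases <- sample_id[runif(n) < p_case]
    if (length(cases) > 0L) {
      case_rows[[length(case_rows) + 1L]] <-
        tibble::tibble(phecode = tr$target_phecode, sample_id = cases)
    }
  }
  bg <- config$background_phecodes
  for (b in seq_len(nrow(bg))) {
    cases <- sample_id[runif(n) < bg$prevalence[b]]
    if (length(cases) > 0L) {
      case_rows[[length(case_rows) + 1L]] <-
        tibble::tibble(phecode = bg$phecode[b], sample_id = cases)
    }
  }
  truth_cases <- dplyr::bind_rows(case_rows)
  if (nrow(truth_cases) == 0L) {
    truth_cases <- tibble::tibble(phecode = character(), sample_id = character())
  }

  diagnoses <- build_diagnoses(truth_cases, samples, phecode_map, dialect,
                               config$history_ok_fraction)
  list(samples = samples, variants = variants, cnvs = cnvs,
       diagnoses = diagnoses, truth_carriers = truth_carriers,
       truth_cases = truth_cases)
}

variant_row <- function(gene, gene_index, pos, cons, polyphen, sift, gnomad,
                        local_af, carriers, pops) {
  row <- tibble::tibble(
    variant_id = sprintf("chr%d:%d:A:G", 1 + (gene_index %% 22), pos),
    gene_id = gene, consequence = cons,
    polyphen_score = polyphen, sift_score = sift,
    local_af = local_af, carriers = paste(carriers, collapse = ","))
  for (i in seq_along(pops)) row[[paste0("gnomad_af_", pops[i])]] <- gnomad[i]
  row
}

empty_cnv_table <- function() {
  tibble::tibble(sample_id = character(), gene_id = character(),
                 cnv_type = character(), n_exons_overlapped = integer(),
                 qc_pass = logical(), exon_freq = numeric(),
                 event_freq = numeric())
}

build_diagnoses <- function(truth_cases, samples, phecode_map, dialect,
                            history_ok_fraction) {
  # anchor wellness record at record start (no phecode mapping) gives every
  # sample a medical-history origin against which the 5-year rule is judged
  anchor <- tibble::tibble(sample_id = samples$sample_id,
                           icd_code = "V70.0", icd_system = dialect[1],
                           date = samples$record_start)
  if (nrow(truth_cases) == 0L) return(anchor[order(anchor$sample_id), ])

  picks <- emit_icd_stream(unique(truth_cases$phecode), phecode_map, dialect)
  dx <- truth_cases |>
    dplyr::left_join(picks, by = "phecode") |>
    dplyr::left_join(samples[, c("sample_id", "record_start", "record_end")],
                     by = "sample_id")
  span_ok <- runif(nrow(dx)) < history_ok_fraction
  early <- as.numeric(dx$record_start) + runif(nrow(dx)) *
    pmin(4 * 365, as.numeric(dx$record_end) - as.numeric(dx$record_start))
  late_lo <- as.numeric(dx$record_start) + 5 * 365.25
  late <- late_lo + runif(nrow(dx)) *
    pmax(0, as.numeric(dx$record_end) - late_lo)
  dx$date <- as.Date(round(ifelse(span_ok, late, early)),
                     origin = "1970-01-01")
  out <- dplyr::bind_rows(
    anchor,
    dx[, c("sample_id", "icd_code", "icd_system", "date")])
  out[order(out$sample_id, out$date, out$icd_code), ]
}
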