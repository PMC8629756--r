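# Shared fixture builders and independent oracles for the test suite.

# One annotated variant row with sensible defaults; override any field.
variant_fixture <- function(variant_id = "chr1:100:A:G", gene_id = "GENE_A",
                            consequence = "missense_variant",
                            polyphen_score = 0.9, sift_score = 0.01,
                            local_af = 5e-4, gnomad = rep(5e-4, 5),
                            carriers = "S1") {
  v <- tibble::tibble(variant_id = variant_id, gene_id = gene_id,
                      consequence = consequence,
                      polyphen_score = polyphen_score,
                      sift_score = sift_score, local_af = local_af,
                      carriers = carriers)
  pops <- c("afr", "amr", "eas", "nfe", "sas")
  for (i in seq_along(pops)) v[[paste0("gnomad_af_", pops[i])]] <- gnomad[i]
  v
}

cnv_fixture <- function(sample_id = "S1", gene_id = "GENE_A",
                        cnv_type = "deletion", n_exons_overlapped = 3L,
                        qc_pass = TRUE, exon_freq = 4e-4, event_freq = 4e-4) {
  tibble::tibble(sample_id = sample_id, gene_id = gene_id,
                 cnv_type = cnv_type,
                 n_exons_overlapped = n_exons_overlapped, qc_pass = qc_pass,
                 exon_freq = exon_freq, event_freq = event_freq)
}

manifest_fixture <- function(ids = paste0("S", 1:4)) {
  tibble::tibble(sample_id = ids, sex = rep_len(c("F", "M"), length(ids)),
                 age = rep_len(c(45, 62, 70, 55), length(ids)),
                 birth_date = as.Date("1960-01-01"))
}

# Independent clause-by-clause re-evaluation of the qualification and
# collapsing rules, written as literal per-row loops so it shares no code
# with the vectorized implementation.
brute_force_carriers <- function(variants, cnvs, samples, model, t) {
  lof_set <- c("stop_lost", "start_lost", "splice_donor_variant",
               "frameshift_variant", "splice_acceptor_variant", "stop_gained")
  coding_set <- c(lof_set, "missense_variant", "inframe_deletion",
                  "inframe_insertion")
  cons_set <- if (model == "lof") lof_set else coding_set
  out <- list()
  for (g in unique(c(variants$gene_id, cnvs$gene_id))) out[[g]] <- character()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!(v$consequence %in% cons_set)) next
    benign <- FALSE
    if (!is.na(v$polyphen_score) && v$polyphen_score < t$polyphen_benign_below) {
      benign <- TRUE
    }
    if (!is.na(v$sift_score) && v$sift_score > t$sift_benign_above) {
      benign <- TRUE
    }
    if (benign) next
    afs <- c()
    for (cl in names(v)) {
      if (startsWith(cl, "gnomad_af_")) afs <- c(afs, v[[cl]])
    }
    afs <- c(afs, v$local_af)
    afs[is.na(afs)] <- 0
    if (!all(afs < t$maf_max)) next
    members <- strsplit(v$carriers, ",")[[1]]
    out[[v$gene_id]] <- union(out[[v$gene_id]], members[nzchar(members)])
  }
  for (i in seq_len(nrow(cnvs))) {
    cv <- cnvs[i, ]
    if (!isTRUE(cv$qc_pass)) next
    if (!(cv$exon_freq < t$cnv_freq_max && cv$event_freq < t$cnv_freq_max)) next
    if (model == "lof") {
      if (!(cv$cnv_type == "deletion" && cv$n_exons_overlapped >= 1)) next
    } else {
      if (!(cv$cnv_type %in% c("deletion", "duplication"))) next
    }
    out[[cv$gene_id]] <- union(out[[cv$gene_id]], cv$sample_id)
  }
  lapply(out, function(s) sort(intersect(s, samples$sample_id)))
}

# Random qualification instance generator for the oracle-equivalence tests.
random_instance <- function(seed, n_samples = 20, n_variants = 40,
                            n_cnvs = 8) {
  set.seed(seed)
  ids <- paste0("S", seq_len(n_samples))
  cons_pool <- c("missense_variant", "stop_gained", "frameshift_variant",
                 "synonymous_variant", "inframe_deletion", "splice_region_variant",
                 "splice_acceptor_variant", "stop_lost")
  vrows <- lapply(seq_len(n_variants), function(i) {
    variant_fixture(
      variant_id = sprintf("chr1:%d:A:G", i),
      gene_id = sample(c("G1", "G2", "G3"), 1),
      consequence = sample(cons_pool, 1),
      polyphen_score = sample(c(NA, round(runif(1), 2)), 1),
      sift_score = sample(c(NA, round(runif(1), 2)), 1),
      local_af = sample(c(5e-4, 2e-3), 1, prob = c(0.8, 0.2)),
      gnomad = sample(c(5e-4, 5e-3), 5, replace = TRUE, prob = c(0.85, 0.15)),
      carriers = paste(sample(ids, sample(1:3, 1)), collapse = ","))
  })
  crows <- lapply(seq_len(n_cnvs), function(i) {
    cnv_fixture(sample_id = sample(ids, 1),
                gene_id = sample(c("G1", "G2", "G3"), 1),
                cnv_type = sample(c("deletion", "duplication"), 1),
                n_exons_overlapped = sample(0:4, 1),
                qc_pass = runif(1) < 0.8,
                exon_freq = sample(c(4e-4, 4e-3), 1),
                event_freq = sample(c(4e-4, 4e-3), 1))
  })
  list(variants = dplyr::bind_rows(vrows), cnvs = dplyr::bind_rows(crows),
       samples = tibble::tibble(sample_id = ids))
}

# Covariate-ready synthetic cohort for association-level tests.
assoc_cohort <- function(n, seed = 1, prevalence = 0.2) {
  set.seed(seed)
  samples <- tibble::tibble(sample_id = paste0("S", seq_len(n)),
                            age = sample(40:69, n, TRUE),
                            sex = sample(c("F", "M"), n, TRUE))
  list(samples = samples, covs = build_covariates(samples),
       y = rbinom(n, 1, prevalence))
}
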