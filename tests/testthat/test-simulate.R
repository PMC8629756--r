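# cohorts must be large enough that a singleton variant (1 / 2n) and a
# singleton CNV event (1 / n) are still below the 0.1% frequency cutoffs,
# i.e. n > 1000 for a CNV-capable cohort
small_cfg <- function(seed = 1, ...) {
  sim_config(cohort_sizes = c(1600, 1100), seed = seed, ...)
}

test_that("generation is fully determined by the seed", {
  truth <- default_sim_truth(n_null = 3, n_causal = 2)
  a <- generate_cohorts(small_cfg(seed = 9), truth)
  b <- generate_cohorts(small_cfg(seed = 9), truth)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- generate_cohorts(small_cfg(seed = 10), truth)
  expect_false(identical(serialize(a, NULL), serialize(c, NULL)))
})

test_that("degenerate probabilities: carriers and only carriers become cases", {
  truth <- sim_truth("G1", TRUE, carrier_freq = 0.01, penetrance = 1,
                     target_phecode = "700.1", background_prevalence = 0)
  sim <- generate_cohorts(small_cfg(seed = 2), truth)
  for (co in sim$cohorts) {
    carriers <- sort(co$truth_carriers$sample_id)
    cases <- sort(co$truth_cases$sample_id[co$truth_cases$phecode == "700.1"])
    expect_identical(carriers, cases)
  }
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_config(cohort_sizes = c(0, 10)), "positive")
  expect_error(sim_config(cohort_sizes = c(500, 500)), "differ")
  expect_error(sim_truth("G1", TRUE, 0.004, penetrance = 1.2,
                         target_phecode = "700.1"), "\\[0, 1\\]")
  expect_error(sim_truth("G1", FALSE, carrier_freq = 0.05, penetrance = 0),
               "0.01")
})

test_that("observed carrier counts are binomially consistent with carrier_freq", {
  # 200 replicate seeds at n = 20000, carrier_freq 0.004: mean count near 80
  n <- 20000L
  cf <- 0.004
  bg <- tibble::tibble(phecode = "401.1", prevalence = 0.0005)
  truth <- sim_truth("G1", FALSE, cf, penetrance = 0,
                     background_prevalence = 0)
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(cohort_sizes = c(n, 100L), seed = s,
                      background_phecodes = bg)
    sim <- generate_cohorts(cfg, truth)
    nrow(sim$cohorts[[1]]$truth_carriers)
  }, numeric(1))
  se <- sqrt(n * cf * (1 - cf) / 200)
  expect_lt(abs(mean(counts) - n * cf), 3 * se)

  # 95% binomial CI around the observed count covers the true frequency
  covered <- vapply(counts, function(k) {
    ci <- binom.test(k, n)$conf.int
    cf >= ci[1] && cf <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("emitted ICD streams round-trip through the phecode map", {
  m <- make_phecode_map(c("250.2", "401.1", "296.2"))
  st <- emit_icd_stream(c("250.2", "401.1"), m, c("icd9", "icd10"))
  back <- dplyr::inner_join(st[, c("icd_code", "icd_system")], m,
                            by = c("icd_code", "icd_system"))
  expect_setequal(back$phecode, c("250.2", "401.1"))
  expect_true(all(st$icd_system %in% c("icd9", "icd10")))

  expect_equal(nrow(emit_icd_stream(character(), m, "icd9")), 0L)
  expect_error(emit_icd_stream("999.9", m, "icd9"), "absent")
})

test_that("phenotype module recovers simulated case labels exactly", {
  truth <- default_sim_truth(n_null = 2, n_causal = 2)
  sim <- generate_cohorts(small_cfg(seed = 4), truth)
  for (co in sim$cohorts) {
    pm <- suppressMessages(
      map_diagnoses(co$diagnoses, sim$phecode_map, co$samples))
    recovered <- tidy(pm)[, c("sample_id", "phecode")]
    expected <- dplyr::arrange(co$truth_cases[, c("sample_id", "phecode")],
                               phecode, sample_id)
    expect_equal(dplyr::arrange(recovered, phecode, sample_id), expected)
  }
})

test_that("collapsing recovers simulated carriers exactly (decoys rejected)", {
  truth <- default_sim_truth(n_null = 3, n_causal = 2)
  sim <- generate_cohorts(small_cfg(seed = 6), truth)
  for (co in sim$cohorts) {
    bm <- collapse_burden(co$variants, co$samples, cnvs = co$cnvs,
                          model = "coding")
    got <- tidy(bm)[, c("sample_id", "gene_id")]
    want <- dplyr::arrange(co$truth_carriers[, c("sample_id", "gene_id")],
                           gene_id, sample_id)
    expect_equal(dplyr::arrange(got, gene_id, sample_id), want)
  }
})
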