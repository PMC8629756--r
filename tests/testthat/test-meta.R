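meta_row <- function(z_a = 5, z_b = 5, n_a = 10000L, n_b = 4000L,
                     cases_a = 500L, cases_b = 200L, carriers_a = 20L,
                     carriers_b = 8L, p_a = 1e-8, p_b = 1e-4,
                     ppv_all = c(0.5, 0.5), ppv_60 = c(0.5, 0.5),
                     cc60 = c(10L, 6L), a = c(10L, 4L)) {
  ra <- tibble::tibble(gene_id = "G", phecode = "250.2", model = "lof",
                       n = n_a, n_cases = cases_a, carriers = carriers_a,
                       a = a[1], b = carriers_a - a[1], c = cases_a - a[1],
                       d = n_a - carriers_a - cases_a + a[1],
                       beta = z_a / 10, se = 0.1, z = z_a, p = p_a,
                       odds_ratio = 5, ppv_all_ages = ppv_all[1],
                       ppv_60plus = ppv_60[1], carrier_cases_60plus = cc60[1],
                       converged = TRUE)
  rb <- dplyr::mutate(ra, n = n_b, n_cases = cases_b, carriers = carriers_b,
                      a = a[2], b = carriers_b - a[2],
                      z = z_b, p = p_b, ppv_all_ages = ppv_all[2],
                      ppv_60plus = ppv_60[2], carrier_cases_60plus = cc60[2])
  list(a = ra, b = rb)
}

test_that("weighted-Z combination matches the closed form", {
  expect_equal(weighted_z(3, 3, 1, 1), 3 * sqrt(2), tolerance = 1e-12)
  expect_equal(weighted_z(2, -2, 1, 1), 0, tolerance = 1e-12)
  expect_equal(weighted_z(4, 0, 2, 1), 8 / sqrt(5), tolerance = 1e-12)
})

test_that("meta z reduces to the remaining cohort as a weight vanishes", {
  z <- weighted_z(3.2, 0.4, 1, 1e-6)
  expect_equal(z, 3.2, tolerance = 1e-5)
})

test_that("meta-analysis uses effective-sample-size weights by default", {
  r <- meta_row()
  m <- meta_analyze(r$a, r$b)
  wa <- sqrt(4 / (1 / 500 + 1 / 9500))
  wb <- sqrt(4 / (1 / 200 + 1 / 3800))
  expect_equal(m$w_a, wa)
  expect_equal(m$w_b, wb)
  expect_equal(m$z_meta, (wa * 5 + wb * 5) / sqrt(wa^2 + wb^2))
  expect_equal(m$p_meta, 2 * pnorm(-abs(m$z_meta)))

  m2 <- meta_analyze(r$a, r$b, weight_scheme = "raw_n")
  expect_equal(m2$w_a, sqrt(10000))
})

test_that("triples missing from one cohort are ineligible", {
  r <- meta_row()
  other <- dplyr::mutate(r$b, gene_id = "OTHER")
  expect_equal(nrow(meta_analyze(r$a, other)), 0L)
})

test_that("significance requires carriers in both cohorts, a better meta p, and Bonferroni", {
  r <- meta_row(z_a = 8, z_b = 6, p_a = 1e-12, p_b = 1e-8)
  m <- significance_gate(meta_analyze(r$a, r$b))
  expect_true(m$significant)

  # no carriers in one cohort fails regardless of p
  r0 <- meta_row(carriers_b = 0L, a = c(10L, 0L))
  m0 <- significance_gate(meta_analyze(r0$a, r0$b))
  expect_false(m0$gate_carriers_both)
  expect_false(m0$significant)

  # meta p must beat BOTH cohorts (strictly)
  r1 <- meta_row(z_a = 7.1, z_b = 0.5, p_a = 1.25e-12, p_b = 0.6)
  m1 <- significance_gate(meta_analyze(r1$a, r1$b))
  expect_lt(m1$p_meta, 1e-9)
  expect_gt(m1$p_meta, m1$p_a)
  expect_false(m1$gate_meta_better)
  expect_false(m1$significant)

  # sub-threshold meta p fails the Bonferroni gate
  r2 <- meta_row(z_a = 4, z_b = 4, p_a = 1e-4, p_b = 1e-3)
  m2 <- significance_gate(meta_analyze(r2$a, r2$b))
  expect_false(m2$gate_bonferroni)
})

test_that("the PPV screen demands the threshold in both cohorts", {
  t <- screen_thresholds()
  sig <- function(...) ppv_screen(significance_gate(
    meta_analyze(meta_row(z_a = 8, z_b = 6, p_a = 1e-12, p_b = 1e-8, ...)$a,
                 meta_row(z_a = 8, z_b = 6, p_a = 1e-12, p_b = 1e-8, ...)$b)), t)

  expect_true(sig(ppv_all = c(0.35, 0.32))$candidate)
  expect_false(sig(ppv_all = c(0.5, 0.2), ppv_60 = c(0.55, 0.2))$candidate)
  # 60+ rescues a pair whose all-ages PPV is low
  s <- sig(ppv_all = c(0.2, 0.22), ppv_60 = c(0.4, 0.31))
  expect_true(s$candidate)
  expect_match(s$rationale, "60\\+")
  # exactly at threshold passes (>= 0.3); just below fails
  expect_true(sig(ppv_all = c(0.3, 0.3), ppv_60 = c(0.29, 0.29))$candidate)
  expect_false(sig(ppv_all = c(0.3, 0.299), ppv_60 = c(0.29, 0.29))$candidate)
})

test_that("an undersized 60+ stratum falls back to all-ages under the default policy", {
  # one cohort has zero 60+ carrier cases but a strong all-ages PPV
  mk <- function(policy) {
    r <- meta_row(z_a = 8, z_b = 6, p_a = 1e-12, p_b = 1e-8,
                  ppv_all = c(0.35, 0.44), ppv_60 = c(0.45, NA),
                  cc60 = c(10L, 0L))
    t <- screen_thresholds(undefined_stratum_policy = policy)
    ppv_screen(significance_gate(meta_analyze(r$a, r$b), t), t)
  }
  s <- mk("fallback_all_ages")
  expect_true(s$candidate)
  strict <- mk("strict")
  # all-ages passes in both cohorts here, so candidacy survives even strict
  expect_true(strict$candidate)

  # when only the 60+ stratum can carry the decision, policy matters
  mk2 <- function(policy) {
    r <- meta_row(z_a = 8, z_b = 6, p_a = 1e-12, p_b = 1e-8,
                  ppv_all = c(0.2, 0.44), ppv_60 = c(0.45, NA),
                  cc60 = c(10L, 0L))
    t <- screen_thresholds(undefined_stratum_policy = policy)
    ppv_screen(significance_gate(meta_analyze(r$a, r$b), t), t)
  }
  s2 <- mk2("fallback_all_ages")
  expect_true(s2$candidate)
  expect_true(s2$manual_review)
  expect_false(mk2("strict")$candidate)
})

test_that("protective associations are excluded from candidacy", {
  r <- meta_row(z_a = -8, z_b = -6, p_a = 1e-12, p_b = 1e-8,
                ppv_all = c(0.5, 0.5))
  s <- ppv_screen(significance_gate(meta_analyze(r$a, r$b)))
  expect_true(s$significant)
  expect_false(s$candidate)
  expect_match(s$rationale, "protective")
})

test_that("raising the PPV threshold never adds candidates", {
  r <- meta_row(z_a = 8, z_b = 6, p_a = 1e-12, p_b = 1e-8,
                ppv_all = c(0.45, 0.35), ppv_60 = c(0.5, 0.4))
  m <- significance_gate(meta_analyze(r$a, r$b))
  cands <- vapply(c(0.1, 0.3, 0.36, 0.45, 0.6), function(pmin) {
    sum(ppv_screen(m, screen_thresholds(ppv_min = pmin))$candidate)
  }, numeric(1))
  expect_true(all(diff(cands) <= 0))
})

test_that("the report keeps the best-PPV association per gene and logs emptiness", {
  r1 <- meta_row(z_a = 8, z_b = 6, p_a = 1e-12, p_b = 1e-8,
                 ppv_all = c(0.4, 0.4))
  r2 <- meta_row(z_a = 9, z_b = 7, p_a = 1e-14, p_b = 1e-9,
                 ppv_all = c(0.6, 0.6))
  ra <- dplyr::bind_rows(r1$a, dplyr::mutate(r2$a, phecode = "401.1"))
  rb <- dplyr::bind_rows(r1$b, dplyr::mutate(r2$b, phecode = "401.1"))
  rep <- build_report(significance_gate(meta_analyze(ra, rb)))
  expect_equal(nrow(rep$candidates), 1L)
  expect_equal(rep$candidates$phecode, "401.1")
  expect_true(rep$candidates$candidate)

  # candidate implies significant
  expect_true(all(rep$screen$significant[rep$screen$candidate]))

  # no significant triples: empty candidates, informative log
  rnull <- meta_row(z_a = 1, z_b = 1, p_a = 0.3, p_b = 0.3)
  rep0 <- build_report(significance_gate(meta_analyze(rnull$a, rnull$b)))
  expect_equal(nrow(rep0$candidates), 0L)
  expect_true(length(rep0$log) > 0)
})
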