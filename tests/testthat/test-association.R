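test_that("contingency odds ratios match the direct formula", {
  b <- c(rep(1, 8), rep(0, 9992))
  y <- c(rep(1, 6), 0, 0, rep(1, 94), rep(0, 9898))
  ct <- contingency_stats(b, y)
  expect_equal(unlist(ct[, c("a", "b", "c", "d")], use.names = FALSE),
               c(6, 2, 94, 9898))
  expect_equal(round(ct$odds_ratio, 1), 315.9)

  # Haldane-Anscombe correction on a zero cell
  b <- c(rep(1, 5), rep(0, 9995))
  y <- c(rep(1, 5), rep(1, 95), rep(0, 9900))
  ct <- contingency_stats(b, y)
  expect_equal(ct$odds_ratio, (5.5 * 9900.5) / (0.5 * 95.5))

  # independence
  ct <- contingency_stats(rep(c(1, 1, 0, 0), each = 10),
                          rep(c(1, 0, 1, 0), each = 10))
  expect_equal(ct$odds_ratio, 1)
})

test_that("PPV is the carrier case fraction, undefined without carriers", {
  b <- c(rep(1, 8), rep(0, 4))
  y <- c(rep(1, 6), 0, 0, 1, 1, 0, 0)
  ages <- c(rep(70, 4), rep(45, 8))
  expect_equal(compute_ppv(b, y, ages)$ppv, 0.75)
  expect_equal(compute_ppv(rep(1, 4), rep(1, 4), rep(50, 4))$ppv, 1.0)

  s60 <- compute_ppv(c(0, 0, 1), c(1, 0, 1), ages = c(70, 80, 40),
                     stratum = "sixty_plus")
  expect_true(is.na(s60$ppv))
  expect_equal(s60$carriers, 0)

  # adding non-carriers never changes the PPV
  expect_equal(compute_ppv(c(b, 0, 0), c(y, 1, 0), c(ages, 50, 50))$ppv, 0.75)
})

test_that("the Firth burden test is finite and strong under separation", {
  set.seed(11)
  n <- 2000
  b <- c(rep(1, 10), rep(0, n - 10))
  y <- c(rep(1, 10), rbinom(n - 10, 1, 0.05))
  f <- fit_burden_test(b, y)
  expect_true(is.finite(f$beta))
  expect_gt(f$beta, 0)
  expect_lt(f$p, 1e-4)
  # exact conditional test agrees the association is extreme
  expect_lt(fisher.test(table(b, y))$p.value, 1e-4)
})

test_that("the burden test agrees with Fisher's exact in rank order", {
  set.seed(21)
  pf <- pe <- numeric(40)
  for (i in 1:40) {
    n <- 300
    b <- rbinom(n, 1, runif(1, 0.1, 0.5))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(b) == 0) b[1] <- 1
    pf[i] <- fit_burden_test(b, y)$p
    pe[i] <- fisher.test(table(factor(b, 0:1), factor(y, 0:1)))$p.value
  }
  expect_gt(cor(pf, pe, method = "spearman"), 0.99)
})

test_that("degenerate inputs are signalled, z and beta share sign", {
  expect_error(fit_burden_test(rep(0, 50), rbinom(50, 1, 0.5)), "carrier")
  expect_error(fit_burden_test(rbinom(50, 1, 0.2), rep(1, 50)),
               class = "ppvscreen_constant_phenotype")

  set.seed(31)
  for (i in 1:10) {
    n <- 500
    b <- rbinom(n, 1, 0.05); if (sum(b) == 0) b[1] <- 1
    y <- rbinom(n, 1, 0.3)
    f <- fit_burden_test(b, y)
    expect_equal(sign(f$z), sign(f$beta))
    expect_true(f$p > 0 && f$p <= 1)
  }
})

test_that("collinear covariates are dropped with a warning", {
  co <- assoc_cohort(800, seed = 41)
  covs <- cbind(co$covs, dup_age = co$covs[, "age"])
  b <- rbinom(800, 1, 0.05); b[1] <- 1
  w <- testthat::capture_warnings(f <- fit_burden_test(b, co$y, covs))
  expect_true(any(grepl("collinear", w)))
  expect_true(is.finite(f$p))
})

test_that("Wald and LRT give compatible answers on well-behaved data", {
  co <- assoc_cohort(2000, seed = 51)
  b <- rbinom(2000, 1, 0.1)
  f1 <- fit_burden_test(b, co$y, co$covs, method = "LRT")
  f2 <- fit_burden_test(b, co$y, co$covs, method = "Wald")
  expect_equal(f1$beta, f2$beta)
  expect_lt(abs(f1$z - f2$z), 0.2)
})

test_that("the cohort scan emits complete rows and respects sex restriction", {
  truth <- default_sim_truth(n_null = 2, n_causal = 1)
  sim <- generate_cohorts(
    sim_config(cohort_sizes = c(1500, 700), seed = 13), truth)
  co <- sim$cohorts[[1]]
  bm <- collapse_burden(co$variants, co$samples, model = "coding")
  pm <- suppressMessages(map_diagnoses(co$diagnoses, sim$phecode_map,
                                       co$samples))
  res <- suppressMessages(
    associate_cohort(bm, pm, co$samples,
                     phecodes = c("700.1", "401.1")))
  expect_true(all(res$carriers >= 1))
  expect_true(all(res$a + res$b == res$carriers))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(sign(res$z) == sign(res$beta) | res$z == 0))

  resf <- suppressMessages(
    associate_cohort(bm, pm, co$samples, phecodes = "401.1",
                     sex_specific = c("401.1" = "F")))
  n_female <- sum(co$samples$sex == "F")
  expect_true(all(resf$n == n_female))
})
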