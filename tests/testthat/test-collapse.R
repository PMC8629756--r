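test_that("consequence sets drive model membership of qualifying variants", {
  # damaging missense: coding yes, lof no
  v <- variant_fixture(consequence = "missense_variant", polyphen_score = 0.9,
                       sift_score = 0.01, local_af = 5e-4)
  expect_true(qualify_variants(v, "coding")$qualifying)
  expect_false(qualify_variants(v, "lof")$qualifying)

  # LoF consequence with no predictor scores qualifies under both models
  v <- variant_fixture(consequence = "stop_gained", polyphen_score = NA,
                       sift_score = NA, local_af = 2e-4,
                       gnomad = rep(2e-4, 5))
  expect_true(qualify_variants(v, "coding")$qualifying)
  expect_true(qualify_variants(v, "lof")$qualifying)

  # synonymous never qualifies
  v <- variant_fixture(consequence = "synonymous_variant",
                       polyphen_score = NA, sift_score = NA)
  expect_false(qualify_variants(v, "coding")$qualifying)
})

test_that("frequency rule requires rarity in every gnomAD population and locally", {
  v <- variant_fixture(gnomad = c(2e-3, 1e-4, 1e-4, 1e-4, 1e-4))
  expect_false(qualify_variants(v, "coding")$qualifying)

  v <- variant_fixture(local_af = 2e-3)
  expect_false(qualify_variants(v, "coding")$qualifying)

  # missing gnomAD population frequency is treated as absence of commonness
  v <- variant_fixture(gnomad = c(NA, NA, 1e-4, 1e-4, 1e-4))
  expect_true(qualify_variants(v, "coding")$qualifying)
})

test_that("benign-prediction rule excludes by either predictor by default", {
  v <- variant_fixture(polyphen_score = 0.10, sift_score = 0.01)
  expect_false(qualify_variants(v, "coding")$qualifying)

  v <- variant_fixture(polyphen_score = 0.9, sift_score = 0.5)
  expect_false(qualify_variants(v, "coding")$qualifying)

  # under the both-benign reading, one damaging predictor rescues the variant
  both <- screen_thresholds(benign_rule = "both")
  v <- variant_fixture(polyphen_score = 0.10, sift_score = 0.01)
  expect_true(qualify_variants(v, "coding", both)$qualifying)
  v <- variant_fixture(polyphen_score = 0.10, sift_score = 0.5)
  expect_false(qualify_variants(v, "coding", both)$qualifying)
})

test_that("unknown consequences and malformed frequencies are fatal", {
  expect_error(qualify_variants(variant_fixture(consequence = "nonsense_term")),
               "unknown consequence")
  expect_error(qualify_variants(variant_fixture(local_af = 1.5)),
               "\\[0, 1\\]")
})

test_that("CNV qualification follows QC, frequency and type rules", {
  expect_true(qualify_cnvs(cnv_fixture(), "coding")$qualifying)
  expect_true(qualify_cnvs(cnv_fixture(), "lof")$qualifying)

  dup <- cnv_fixture(cnv_type = "duplication")
  expect_true(qualify_cnvs(dup, "coding")$qualifying)
  expect_false(qualify_cnvs(dup, "lof")$qualifying)

  expect_false(qualify_cnvs(cnv_fixture(event_freq = 5e-3), "coding")$qualifying)
  expect_false(qualify_cnvs(cnv_fixture(qc_pass = FALSE), "coding")$qualifying)
  expect_false(qualify_cnvs(cnv_fixture(n_exons_overlapped = 0L), "lof")$qualifying)
  expect_error(qualify_cnvs(cnv_fixture(n_exons_overlapped = -1L), "lof"),
               "negative exon")
})

test_that("collapsing codes carriers 0/1 and integrates CNV-only evidence", {
  samples <- manifest_fixture()
  v <- dplyr::bind_rows(
    variant_fixture(gene_id = "GENE_A", carriers = "S1"),
    variant_fixture(variant_id = "chr1:200:A:G", gene_id = "GENE_A",
                    consequence = "synonymous_variant", polyphen_score = NA,
                    sift_score = NA, carriers = "S2"))
  cnv <- cnv_fixture(sample_id = "S3", gene_id = "GENE_B",
                     n_exons_overlapped = 1L)

  bm_cod <- collapse_burden(v, samples, cnvs = cnv, model = "coding")
  bm_lof <- collapse_burden(v, samples, cnvs = cnv, model = "lof")

  expect_equal(unname(bm_cod["S1", "GENE_A"]), 1L)
  expect_equal(unname(bm_lof["S1", "GENE_A"]), 0L)  # missense not LoF
  expect_equal(unname(bm_cod["S2", "GENE_A"]), 0L)  # synonymous only
  expect_equal(unname(carrier_counts(bm_lof)["GENE_B"]), 1L)  # CNV path

  # zero-carrier genes retained as all-zero columns
  v2 <- variant_fixture(gene_id = "GENE_C", local_af = 0.01)
  bm <- collapse_burden(dplyr::bind_rows(v, v2), samples, model = "coding")
  expect_true("GENE_C" %in% colnames(bm))
  expect_equal(unname(carrier_counts(bm)["GENE_C"]), 0L)
})

test_that("carriers outside the manifest are fatal and named", {
  v <- variant_fixture(carriers = "GHOST")
  expect_error(collapse_burden(v, manifest_fixture(), model = "coding"),
               "GHOST")
})

test_that("tightening the MAF cutoff never adds carriers", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    loose <- collapse_burden(inst$variants, inst$samples, cnvs = inst$cnvs,
                             model = "coding",
                             thresholds = list(maf_max = 0.005,
                                               cnv_freq_max = 0.005))
    tight <- collapse_burden(inst$variants, inst$samples, cnvs = inst$cnvs,
                             model = "coding")
    expect_true(all(carrier_counts(tight) <= carrier_counts(loose)[
      names(carrier_counts(tight))]))
  }
})

test_that("LoF carriers are a subset of coding carriers (deletion CNVs only)", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 100)
    dels <- dplyr::filter(inst$cnvs, cnv_type == "deletion")
    cod <- collapse_burden(inst$variants, inst$samples, cnvs = dels, "coding")
    lof <- collapse_burden(inst$variants, inst$samples, cnvs = dels, "lof")
    expect_true(all(unclass(lof) <= unclass(cod)))
  }
})

test_that("tidy() returns the long carrier view consistent with the matrix", {
  inst <- random_instance(7)
  bm <- collapse_burden(inst$variants, inst$samples, cnvs = inst$cnvs, "coding")
  long <- tidy(bm)
  expect_equal(nrow(long), sum(bm))
  expect_true(all(long$carrier == 1L))
})
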