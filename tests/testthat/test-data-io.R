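test_that("genotype TSV round-trips through write and read", {
  g <- random_genotypes(5, 4, populations = rep(c("A", "B"), c(2, 3)),
                        missing_rate = 0.1, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, "tsv")
  expect_equal(g2$codes, g$codes)
  expect_equal(as.character(g2$population), as.character(g$population))
})

test_that("PLINK RAW dialect is parsed with NA as missing", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE M1_A M2_G",
               "F1 I1 0 0 1 -9 2 NA",
               "F2 I2 0 0 2 -9 0 1"), path)
  g <- read_genotypes(path, "plink_raw")
  expect_equal(unname(g$codes["I1", ]), c(2, NA))
  expect_equal(unname(g$codes["I2", ]), c(0, 1))
  expect_equal(colnames(g$codes), c("M1", "M2"))
  # FID doubles as the population label, overridable by a named vector
  expect_equal(as.character(g$population), c("F1", "F2"))
  g2 <- read_genotypes(path, "plink_raw",
                       populations = c(I1 = "pop1", I2 = "pop1"))
  expect_equal(as.character(g2$population), c("pop1", "pop1"))
})

test_that("malformed inputs are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tM1", "S1\t0"), path)
  expect_error(read_genotypes(path, "tsv"), "header")
  codes <- matrix(0:1, 2, 2, dimnames = list(c("S1", "S1"), c("M1", "M2")))
  expect_error(genotype_matrix(codes, c("A", "A")), "duplicate sample")
  codes2 <- matrix(c(0, 3), 1, 2, dimnames = list("S1", c("M1", "M2")))
  expect_error(genotype_matrix(codes2, "A"), "codes")
})

test_that("MAF filter removes markers strictly below threshold", {
  codes <- cbind(m_keep = c(0, 0, 0, 0, 0, 1),   # MAF 1/12 ~ 0.083
                 m_mono = rep(0, 6),              # MAF 0
                 m_high = c(1, 1, 2, 0, 1, 2))
  g <- genotype_matrix(codes, rep("A", 6))
  res <- qc_filter_maf(g, 0.05)
  expect_setequal(res$report$kept, c("m_keep", "m_high"))
  expect_equal(res$report$removed_maf, "m_mono")

  # boundary: MAF exactly at the threshold survives (strict inequality)
  codes_b <- cbind(m_edge = c(1, rep(0, 9)))      # MAF 1/20 = 0.05
  gb <- genotype_matrix(codes_b, rep("A", 10))
  expect_equal(qc_filter_maf(gb, 0.05)$report$kept, "m_edge")
})

test_that("missingness filter removes markers strictly above the cap", {
  codes <- cbind(m_bad = c(rep(NA, 2), rep(1, 8)),   # rate 0.20
                 m_edge = c(NA, rep(1, 9)),           # rate 0.10 exactly
                 m_ok = rep(c(0, 1), 5))
  g <- genotype_matrix(codes, rep("A", 10))
  res <- qc_filter_missing(g, 0.10)
  expect_setequal(res$report$kept, c("m_edge", "m_ok"))
  expect_equal(res$report$removed_missing, "m_bad")
})

test_that("near-duplicate filter drops identical and complementary columns", {
  set.seed(2)
  base <- sample(0:2, 40, replace = TRUE)
  near <- base
  near[1:4] <- (base[1:4] + 1) %% 3    # 90% identity
  codes <- cbind(m1 = base, m2 = base, m3 = 2 - base, m4 = near)
  g <- genotype_matrix(codes, rep("A", 40))
  res <- qc_filter_near_duplicates(g, agreement = 0.95)
  expect_setequal(res$report$removed_duplicate, c("m2", "m3"))
  expect_true("m4" %in% res$report$kept)  # 90% < 95%: kept

  # pairs with too few joint observations are never declared duplicates
  codes2 <- cbind(m1 = c(base[1:5], rep(NA, 35)),
                  m2 = c(base[1:5], rep(NA, 35)))
  g2 <- genotype_matrix(codes2, rep("A", 40))
  res2 <- qc_filter_near_duplicates(g2, agreement = 0.95, min_joint = 10)
  expect_length(res2$report$removed_duplicate, 0)
})

test_that("panel harmonization intersects surviving marker sets", {
  gA <- random_genotypes(4, 3, seed = 3)
  gB <- random_genotypes(4, 3, seed = 4)
  colnames(gA$codes) <- c("m1", "m2", "m3")
  colnames(gB$codes) <- c("m2", "m3", "m4")
  res <- harmonize_panels(list(A = gA, B = gB))
  expect_equal(colnames(res$genotypes$A$codes), c("m2", "m3"))
  expect_equal(colnames(res$genotypes$B$codes), c("m2", "m3"))
  expect_equal(res$reports$A$removed_cross_population, "m1")

  # identical kept sets: unchanged
  res2 <- harmonize_panels(list(A = gA, B = gA))
  expect_equal(colnames(res2$genotypes$A$codes), colnames(gA$codes))

  colnames(gB$codes) <- c("m4", "m5", "m6")
  expect_error(harmonize_panels(list(A = gA, B = gB)), "no marker")
})

test_that("mean imputation fills missing cells within population", {
  codes <- cbind(m1 = c(0, 2, NA, 1, 1, NA), m2 = c(1, 1, 1, NA, 0, 2))
  g <- genotype_matrix(codes, rep(c("A", "B"), each = 3))
  x <- impute_missing_to_mean(g)
  expect_equal(unname(x[3, "m1"]), 1.0)   # mean of (0, 2) within A
  expect_equal(unname(x[4, "m2"]), 1.0)   # mean of (0, 2) within B
  expect_false(anyNA(x))
  # a marker entirely missing within one population cannot be imputed
  codes_bad <- cbind(m1 = c(1, 1, NA), m2 = c(NA, NA, NA))
  expect_error(impute_missing_to_mean(
    genotype_matrix(codes_bad, rep("B", 3))), "entirely missing")
  # complete data passes through unchanged
  g2 <- random_genotypes(4, 3, seed = 5)
  expect_equal(impute_missing_to_mean(g2), g2$codes, ignore_attr = TRUE)
})

test_that("QC filters are idempotent and reports partition the input", {
  g <- random_genotypes(30, 25, missing_rate = 0.08, seed = 6)
  once <- qc_filter_maf(g, 0.1)
  twice <- qc_filter_maf(once$genotypes, 0.1)
  expect_equal(twice$report$kept, once$report$kept)
  expect_length(twice$report$removed_maf, 0)

  res <- qc_pipeline(list(A = g), maf = 0.1, max_missing = 0.1,
                     agreement = 0.9)
  rep <- res$reports$A
  all_markers <- c(rep$kept, rep$removed_maf, rep$removed_missing,
                   rep$removed_duplicate, rep$removed_cross_population)
  expect_setequal(all_markers, colnames(g$codes))
  expect_length(all_markers, n_markers(g))
})
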