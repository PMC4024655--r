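# The synthetic two-population generator: structural invariants, moment
# checks against the generative model, panel construction and splits.

desk_cfg <- function(...) {
  sim_config(n_per_population = c(80, 120), n_train = c(60, 90),
             m_markers = 120, n_qtl = 8, qtl_pool_stride = 4, ...)
}

test_that("simulated studies satisfy their structural invariants", {
  cfg <- desk_cfg(rho = 0.5)
  d <- simulate_study_data(cfg, seed = 7)

  for (g in d$genotypes) {
    expect_false(anyNA(g$codes))
    f <- allele_frequency(g)
    expect_true(all(pmin(f, 1 - f) >= cfg$maf_min))
  }

  # TBV recomputed from genotypes and effects is exact
  for (k in 1:2) {
    g <- d$genotypes[[k]]
    tbv <- drop(g$codes[, d$truth$qtl_indices] %*% d$truth$alpha[, k])
    expect_identical(unname(d$truth$tbv[[k]]), unname(tbv))
  }

  # heritability 0.5 makes the residual variance equal the genetic variance
  expect_identical(d$truth$sigma2_e, d$truth$sigma2_a)

  # pure function of (cfg, seed)
  d2 <- simulate_study_data(cfg, seed = 7)
  expect_identical(d$genotypes[[1]]$codes, d2$genotypes[[1]]$codes)
  expect_identical(d$phenotypes$value, d2$phenotypes$value)
  expect_identical(d$split, d2$split)
})

test_that("latent AR(1) coefficient controls adjacent-marker correlation", {
  set.seed(8)
  cfg0 <- sim_config(n_per_population = c(2000, 50), n_train = c(10, 10),
                     m_markers = 40, n_qtl = 2, qtl_pool_stride = 4,
                     ld_phi = 0, fst = 0)
  g0 <- simulate_genotypes(cfg0)$genotypes[[1]]
  r0 <- vapply(seq_len(39), function(j)
    cor(g0$codes[, j], g0$codes[, j + 1]), numeric(1))
  expect_lt(mean(abs(r0)), 0.05)

  set.seed(9)
  cfg1 <- sim_config(n_per_population = c(2000, 50), n_train = c(10, 10),
                     m_markers = 40, n_qtl = 2, qtl_pool_stride = 4,
                     ld_phi = 0.95, fst = 0)
  g1 <- simulate_genotypes(cfg1)$genotypes[[1]]
  r1 <- vapply(seq_len(39), function(j)
    cor(g1$codes[, j], g1$codes[, j + 1]), numeric(1))
  expect_gt(mean(r1), 0.3)
})

test_that("realized allele frequencies track their targets", {
  set.seed(10)
  cfg <- sim_config(n_per_population = c(1500, 1500), n_train = c(10, 10),
                    m_markers = 60, n_qtl = 2, qtl_pool_stride = 8,
                    fst = 0, ld_phi = 0.5)
  sim <- simulate_genotypes(cfg)
  for (k in 1:2) {
    f <- allele_frequency(sim$genotypes[[k]])
    p <- sim$freq[, k]
    se <- sqrt(p * (1 - p) / (2 * 1500))
    # per-marker realized frequency within 3 binomial SE of its target
    expect_gt(mean(abs(f - p) <= 3 * se), 0.95)
  }
  # F = 0: the two populations share the same target frequencies
  expect_identical(sim$freq[, 1], sim$freq[, 2])
})

test_that("QTL are drawn from the designated low-density pool", {
  cfg <- desk_cfg()
  set.seed(11)
  q <- select_qtl(cfg)
  expect_length(q, cfg$n_qtl)
  expect_false(anyDuplicated(q) > 0)
  expect_true(all((q - 1) %% cfg$qtl_pool_stride == 0))

  # whole pool when n_qtl equals the pool size
  cfg2 <- sim_config(n_per_population = c(10, 10), n_train = c(5, 5),
                     m_markers = 16, n_qtl = 4, qtl_pool_stride = 4)
  expect_equal(select_qtl(cfg2), c(1, 5, 9, 13))

  # different seeds give different sets (overwhelmingly)
  draws <- vapply(1:10, function(s) {
    set.seed(s); paste(select_qtl(cfg), collapse = ",")
  }, character(1))
  expect_gt(length(unique(draws)), 1)
})

test_that("QTL effects have unit variances and the requested correlation", {
  set.seed(12)
  a1 <- sample_qtl_effects(1e4, rho = 1)
  expect_equal(a1[, 1], a1[, 2], ignore_attr = TRUE)

  a0 <- sample_qtl_effects(1e4, rho = 0)
  expect_lt(abs(cor(a0[, 1], a0[, 2])), 0.05)
  expect_lt(abs(var(a0[, 1]) - 1), 3 * sqrt(2 / 1e4))
  expect_lt(abs(var(a0[, 2]) - 1), 3 * sqrt(2 / 1e4))

  a8 <- sample_qtl_effects(1e4, rho = 0.8)
  expect_lt(abs(cor(a8[, 1], a8[, 2]) - 0.8), 0.03)
})

test_that("genetic variance follows the frequency-weighted sum of squares", {
  expect_equal(compute_genetic_variance(0.5, 1), 0.5)
  expect_equal(compute_genetic_variance(c(0, 1), c(3, -2)), 0)
  set.seed(13)
  p <- runif(20, 0.05, 0.95)
  a <- matrix(rnorm(40), 20, 2)
  oracle <- 0
  for (j in 1:20) oracle <- oracle + 2 * p[j] * (1 - p[j]) * a[j, 2]^2
  expect_equal(compute_genetic_variance(p, a, k = 2), oracle,
               tolerance = 1e-12)
})

test_that("phenotypes add independent noise at the stated variance", {
  cfg <- sim_config(n_per_population = c(2000, 50), n_train = c(10, 10),
                    m_markers = 60, n_qtl = 6, qtl_pool_stride = 4)
  d <- simulate_study_data(cfg, seed = 14)
  ph <- d$phenotypes[d$phenotypes$population == "pop1", ]
  noise <- ph$value - d$truth$tbv[["pop1"]][ph$sample_id]
  s2e <- d$truth$sigma2_e[["pop1"]]
  expect_lt(abs(var(noise) - s2e), 3 * s2e * sqrt(2 / 2000))
  expect_lt(abs(cor(noise, d$truth$tbv[["pop1"]][ph$sample_id])), 0.07)
})

test_that("panel construction thins and handles QTL columns", {
  g <- random_genotypes(5, 8, seed = 15)
  cfg2 <- desk_cfg(thin_factor = 2)
  panel <- build_panel(g, qtl = integer(0), cfg2)
  expect_equal(colnames(panel$codes), colnames(g$codes)[c(1, 3, 5, 7)])

  g2 <- random_genotypes(5, 40, seed = 16)
  cfg1 <- desk_cfg(thin_factor = 1)
  panel2 <- build_panel(g2, qtl = c(3, 17, 25), cfg1)
  expect_equal(n_markers(panel2), 37)
  expect_false(any(colnames(g2$codes)[c(3, 17, 25)] %in%
                     colnames(panel2$codes)))

  cfgq <- desk_cfg(thin_factor = 4, include_qtl_in_panel = TRUE)
  panel3 <- build_panel(g2, qtl = c(3, 17, 25), cfgq)
  expect_true(all(colnames(g2$codes)[c(3, 17, 25)] %in%
                    colnames(panel3$codes)))
})

test_that("train/validation split respects sizes and is reproducible", {
  ids <- sprintf("S%03d", 1:30)
  pop <- rep(c("A", "B"), c(10, 20))
  set.seed(17)
  sp <- split_train_validation(ids, pop, n_train = c(7, 15))
  expect_length(sp$train, 22)
  expect_length(sp$validation, 8)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ids)

  set.seed(17)
  sp2 <- split_train_validation(ids, pop, n_train = c(7, 15))
  expect_identical(sp, sp2)

  expect_error(split_train_validation(ids, pop, n_train = c(11, 15)),
               "exceeds")
})
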