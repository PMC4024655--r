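# Full-conditional updates checked against closed forms and hand-computed
# values.

test_that("prior scale derivation inverts the scaled-inv-chisq mean", {
  expect_equal(derive_scale(1.0, 4), 0.5)
  expect_equal(derive_scale(2.0, 10), 1.6)
  expect_equal(derive_scale(0, 4), 0)
  expect_error(derive_scale(1, 2), "exceed 2")
})

# state with prescribed x'x and x'y* per population: one sample per unit of
# design, mu fixed at 0
state_from_sufficient <- function(xcols, ys, w, sigma2_a, sigma2_e) {
  X <- lapply(xcols, function(x) matrix(x, ncol = 1))
  prior <- prior_spec(s2_a = 1, s2_e = 1)
  mcmc_state(X, ys, prior, w = w, sigma2_a = sigma2_a,
             sigma2_e = sigma2_e, mu = rep(0, length(X)))
}

test_that("exclusion odds match the hand-evaluated closed form", {
  # one population, w = 0.5, x'x = 2, x'y* = 2, unit variances:
  # q = sqrt(3) * exp(-2/3)
  st <- state_from_sufficient(list(c(1, 1)), list(c(1, 1)),
                              w = 0.5, sigma2_a = 1, sigma2_e = 1)
  q <- exp(inclusion_log_odds(st, 1))
  expect_equal(q, sqrt(3) * exp(-2 / 3), tolerance = 1e-12)
  expect_equal(inclusion_probability(st, 1), 1 / (1 + q), tolerance = 1e-12)
  expect_equal(inclusion_probability(st, 1), 0.52932, tolerance = 1e-4)
})

test_that("vanishing slab variance recovers the prior odds", {
  # sigma2_a -> 0: q -> w / (1 - w), inclusion prob -> 1 - w
  st <- state_from_sufficient(list(c(1, 1)), list(c(3, -1)),
                              w = 0.3, sigma2_a = 1e-14, sigma2_e = 1)
  expect_equal(inclusion_probability(st, 1), 0.7, tolerance = 1e-6)
})

test_that("zero marker-residual covariance caps inclusion at 1 - w", {
  # two populations, x'y* = 0, x'x = 1, unit variances, w = 0.5:
  # q = sqrt(2) * sqrt(2) = 2, inclusion prob = 1/3
  st <- state_from_sufficient(list(1, 1), list(0, 0),
                              w = 0.5, sigma2_a = 1, sigma2_e = 1)
  expect_equal(exp(inclusion_log_odds(st, 1)), 2, tolerance = 1e-12)
  expect_equal(inclusion_probability(st, 1), 1 / 3, tolerance = 1e-12)

  # with no evidence the determinant factor only ever reduces inclusion
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(6)
    st2 <- state_from_sufficient(list(x), list(rep(0, 6)),
                                 w = 0.4, sigma2_a = runif(1, 0.1, 5),
                                 sigma2_e = runif(1, 0.1, 5))
    expect_lte(inclusion_probability(st2, 1), 1 - 0.4 + 1e-12)
  }
})

test_that("joint indicator/effect update keeps residuals consistent", {
  d <- tiny_two_pop_data()
  prior <- prior_spec(s2_a = 0.5, s2_e = 1)
  st <- mcmc_state(d$X, d$y, prior)

  # forced exclusion zeroes effects and restores the no-effect residuals
  st1 <- update_indicator_and_effects(st, 1, force_gamma = 1)
  expect_true(all(st1$effects[1, ] != 0))
  st0 <- update_indicator_and_effects(st1, 1, force_gamma = 0)
  expect_equal(st0$effects[1, ], c(0, 0))
  for (k in 1:2)
    expect_equal(st0$residuals[[k]], d$y[[k]] - st0$mu[k])

  # random sweeps maintain the residual identity
  set.seed(99)
  for (sweep in 1:20)
    for (j in 1:st$m) st <- update_indicator_and_effects(st, j)
  expect_lt(residual_error(st), 1e-10)

  # degenerate slab: as sighat2 -> 0 the draw concentrates at muhat
  st_det <- mcmc_state(d$X, d$y, prior, sigma2_a = 1e8, sigma2_e = 1e-12,
                       mu = c(0, 0))
  sm <- mtgp:::slab_moments(st_det, 1)
  st_d <- update_indicator_and_effects(st_det, 1, force_gamma = 1)
  expect_equal(st_d$effects[1, ], sm$muhat, tolerance = 1e-4)
})

test_that("w draws match the stated Beta moments", {
  gamma <- c(rep(1, 3), rep(0, 7))   # m = 10, sum gamma = 3
  set.seed(1)
  draws <- sample_w(gamma, form = "conjugate_plus_one", n = 1e5)
  # Beta(8, 4): mean 2/3
  mu <- 8 / 12
  se <- sqrt(8 * 4 / (12^2 * 13) / 1e5)
  expect_lt(abs(mean(draws) - mu), 3 * se)

  draws0 <- sample_w(integer(10), form = "conjugate_plus_one", n = 1e5)
  mu0 <- 11 / 12
  se0 <- sqrt(11 * 1 / (12^2 * 13) / 1e5)
  expect_lt(abs(mean(draws0) - mu0), 3 * se0)

  # printed form Beta(7, 3): mean 0.7
  draws_p <- sample_w(gamma, form = "as_printed", n = 1e5)
  se_p <- sqrt(7 * 3 / (10^2 * 11) / 1e5)
  expect_lt(abs(mean(draws_p) - 0.7), 3 * se_p)
  # and it stays proper at the boundary sum(gamma) = 0
  expect_true(all(is.finite(sample_w(integer(5), form = "as_printed",
                                     n = 100))))
})

test_that("variance draws match scaled-inv-chisq moments", {
  # sigma2_a: v_a = 4, s2_a = 0.5, two included effects with sum a^2 = 1
  # -> scaled-inv-chisq(6, 0.5), mean 0.75
  st <- mcmc_state(list(matrix(1, 6, 2)), list(rep(0, 6)),
                   prior_spec(s2_a = 0.5, s2_e = 1, v_a = 4, v_e = 10),
                   mu = 0)
  st$gamma <- c(1L, 1L)
  st$effects <- matrix(c(sqrt(0.5), sqrt(0.5)), 2, 1)
  set.seed(2)
  draws <- sample_sigma2_a(st, 1, n = 1e5)
  mu_a <- 6 * 0.5 / 4
  var_a <- 2 * 6^2 * 0.5^2 / (4^2 * 2)
  expect_lt(abs(mean(draws) - mu_a), 3 * sqrt(var_a / 1e5))

  # sigma2_e with zero residuals, n = 10, v_e = 10, s2_e = 1
  # -> scaled-inv-chisq(20, 0.5), mean 20 * 0.5 / 18
  st2 <- mcmc_state(list(matrix(1, 10, 1)), list(rep(0, 10)),
                    prior_spec(s2_a = 1, s2_e = 1, v_a = 4, v_e = 10),
                    mu = 0)
  expect_equal(st2$residuals[[1]], rep(0, 10))
  draws_e <- sample_sigma2_e(st2, 1, n = 1e5)
  mu_e <- 20 * 0.5 / 18
  var_e <- 2 * 20^2 * 0.5^2 / (18^2 * 16)
  expect_lt(abs(mean(draws_e) - mu_e), 3 * sqrt(var_e / 1e5))
})

test_that("intercept draws match their normal conditional", {
  # y - X a constant at 5, n = 25, sigma2_e = 1 -> N(5, 0.04)
  st <- mcmc_state(list(matrix(0, 25, 1)), list(rep(5, 25)),
                   prior_spec(s2_a = 1, s2_e = 1), sigma2_e = 1, mu = 0)
  set.seed(3)
  draws <- replicate(2e4, sample_mu(st, 1)$mu[1])
  expect_lt(abs(mean(draws) - 5), 3 * 0.2 / sqrt(2e4))
  expect_lt(abs(var(draws) - 0.04), 3 * sqrt(2 * 0.04^2 / 2e4))

  # zero-mean residuals: centered at the current mu, and the residual
  # identity survives the update
  st2 <- mcmc_state(list(matrix(0, 25, 1)), list(rnorm(25)),
                    prior_spec(s2_a = 1, s2_e = 1), sigma2_e = 1e-12)
  mu_before <- st2$mu[1] + mean(st2$residuals[[1]])
  st2u <- sample_mu(st2, 1)
  expect_equal(st2u$mu[1], mu_before, tolerance = 1e-5)
  expect_lt(residual_error(st2u), 1e-10)
})
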