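#' Gibbs sampler state for the multi-task model
#'
#' Holds every unknown of the sampler — per-population intercepts `mu`,
#' SNP effects (markers x populations), the shared inclusion indicators
#' `gamma`, the exclusion probability `w`, per-population variance
#' components — plus the maintained residual vectors
#' `e_k = y_k - mu_k - X_k a_k` and the precomputed marker sums of squares
#' `x'x` per population.  The functions operating on a state implement the
#' individual full-conditional updates; the fast chain runner
#' ([run_multi_task()]) performs the same updates in compiled code.
#'
#' @param X list of per-population complete (numeric) genotype matrices that
#'   share one marker order.
#' @param y list of per-population phenotype vectors.
#' @param prior a [prior_spec()].
#' @param w initial exclusion probability in (0, 1).
#' @param sigma2_a,sigma2_e optional initial variances per population;
#'   defaults are the prior means.
#' @param mu optional initial intercepts; default is each population's
#'   phenotype mean.
#' @return An object of class `mcmc_state`.
#' @export
mcmc_state <- function(X, y, prior, w = 0.5, sigma2_a = NULL,
                       sigma2_e = NULL, mu = NULL) {
  if (!is.list(X)) X <- list(X)
  if (!is.list(y)) y <- list(y)
  stopifnot(length(X) == length(y), w > 0, w < 1)
  c_pop <- length(X)
  m <- ncol(X[[1]])
  for (k in seq_len(c_pop)) {
    stopifnot(is.matrix(X[[k]]), ncol(X[[k]]) == m,
              nrow(X[[k]]) == length(y[[k]]))
    if (anyNA(X[[k]])) stop("genotype matrices must be complete; impute first")
  }
  pr <- expand_prior(prior, c_pop)
  sigma2_a <- if (is.null(sigma2_a)) pr$s2_a * pr$v_a / (pr$v_a - 2)
              else rep_len(sigma2_a, c_pop)
  sigma2_e <- if (is.null(sigma2_e)) pr$s2_e * pr$v_e / (pr$v_e - 2)
              else rep_len(sigma2_e, c_pop)
  mu <- if (is.null(mu)) vapply(y, mean, numeric(1)) else rep_len(mu, c_pop)
  stopifnot(all(sigma2_a > 0), all(sigma2_e > 0))
  residuals <- lapply(seq_len(c_pop), function(k) y[[k]] - mu[k])
  xtx <- vapply(X, function(Xk) colSums(Xk^2), numeric(m))
  structure(list(X = X, y = y, prior = pr, n_pop = c_pop, m = m,
                 mu = mu, effects = matrix(0, m, c_pop),
                 gamma = integer(m), w = w,
                 sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 residuals = residuals, xtx = matrix(xtx, m, c_pop)),
            class = "mcmc_state")
}

# slab posterior pieces for marker j: x'y*, muhat, sighat2 per population
slab_moments <- function(state, j) {
  c_pop <- state$n_pop
  xy <- muhat <- sighat2 <- numeric(c_pop)
  for (k in seq_len(c_pop)) {
    xjk <- state$X[[k]][, j]
    # x'y* recovered from the maintained residuals: y* adds back marker j's
    # own current contribution
    xy[k] <- sum(xjk * state$residuals[[k]]) +
      state$xtx[j, k] * state$effects[j, k]
    denom <- state$xtx[j, k] + state$sigma2_e[k] / state$sigma2_a[k]
    muhat[k] <- xy[k] / denom
    sighat2[k] <- state$sigma2_e[k] / denom
  }
  list(xy = xy, muhat = muhat, sighat2 = sighat2)
}

#' Log posterior odds of excluding a marker
#'
#' Computes `log q_j`, the log ratio of the conditional posterior mass on
#' \eqn{\gamma_j = 0} versus \eqn{\gamma_j = 1}, pooling evidence over all
#' populations with the per-population effect integrated out:
#' \deqn{\log q_j = \log\frac{w}{1-w}
#'   + \tfrac12\sum_k \log\!\big(x'_{jk}x_{jk}\,\sigma^2_{ak}/\sigma^2_{ek}+1\big)
#'   - \tfrac12\sum_k \hat\mu^2_{ajk}/\hat\sigma^2_{ajk}.}
#' The indicator is then Bernoulli with inclusion probability
#' `1/(1 + q_j)`.  Everything is evaluated in log space; the product over
#' populations would overflow otherwise.
#'
#' @param state an [mcmc_state()].
#' @param j marker index.
#' @return `log q_j` (a scalar).
#' @export
inclusion_log_odds <- function(state, j) {
  if (any(state$sigma2_a <= 0) || any(state$sigma2_e <= 0))
    stop("variances must be positive")
  sm <- slab_moments(state, j)
  log(state$w) - log1p(-state$w) +
    0.5 * sum(log1p(state$xtx[j, ] * state$sigma2_a / state$sigma2_e)) -
    0.5 * sum(sm$muhat^2 / sm$sighat2)
}

#' Marker inclusion probability
#'
#' @inheritParams inclusion_log_odds
#' @return `1 / (1 + q_j)` computed stably from [inclusion_log_odds()].
#' @export
inclusion_probability <- function(state, j) {
  stats::plogis(-inclusion_log_odds(state, j))
}

#' Jointly update a marker's indicator and its effects
#'
#' Draws \eqn{\gamma_j} from its marginal conditional (effects integrated
#' out), then the per-population effects: zero when excluded, otherwise
#' independent draws from \eqn{N(\hat\mu_{ajk}, \hat\sigma^2_{ajk})}.
#' Residuals are updated in place by
#' \eqn{e_k \leftarrow e_k - x_{jk}(a^{new}_{jk} - a^{old}_{jk})}.
#'
#' @param state an [mcmc_state()].
#' @param j marker index.
#' @param force_gamma optional 0/1 to force the indicator (used for testing
#'   the conditional effect draw); default samples it.
#' @return The mutated state.
#' @export
update_indicator_and_effects <- function(state, j, force_gamma = NULL) {
  sm <- slab_moments(state, j)
  g_new <- if (is.null(force_gamma)) {
    as.integer(stats::runif(1) < inclusion_probability(state, j))
  } else as.integer(force_gamma)
  a_old <- state$effects[j, ]
  a_new <- if (g_new == 1L) {
    stats::rnorm(state$n_pop, mean = sm$muhat, sd = sqrt(sm$sighat2))
  } else rep(0, state$n_pop)
  for (k in seq_len(state$n_pop)) {
    if (a_new[k] != a_old[k])
      state$residuals[[k]] <- state$residuals[[k]] -
        state$X[[k]][, j] * (a_new[k] - a_old[k])
  }
  state$effects[j, ] <- a_new
  state$gamma[j] <- g_new
  state
}

#' Sample the exclusion probability w
#'
#' Under the Uniform(0, 1) prior the full conditional of `w` given the
#' indicators is `Beta(m - sum(gamma) + 1, sum(gamma) + 1)`
#' (`form = "conjugate_plus_one"`, the default).  The alternative
#' `form = "as_printed"` draws `Beta(m - sum(gamma), sum(gamma))` with both
#' parameters floored at 1e-8 so the density stays proper when every marker
#' is included or excluded.
#'
#' @param gamma integer 0/1 indicator vector.
#' @param m marker count (defaults to `length(gamma)`).
#' @param form which Beta parameterization to use.
#' @param n number of draws.
#' @return Numeric vector of draws in (0, 1).
#' @export
sample_w <- function(gamma, m = length(gamma),
                     form = c("conjugate_plus_one", "as_printed"), n = 1) {
  form <- match.arg(form)
  sg <- sum(gamma)
  stopifnot(sg >= 0, sg <= m)
  if (form == "conjugate_plus_one") {
    stats::rbeta(n, m - sg + 1, sg + 1)
  } else {
    stats::rbeta(n, max(m - sg, 1e-8), max(sg, 1e-8))
  }
}

#' Sample the SNP-effect variance of one population
#'
#' Full conditional: scaled inverse chi-square with degrees of freedom
#' `v_a + sum(gamma)` and scale
#' `(v_a s2_a + sum_j gamma_j a_jk^2) / (v_a + sum(gamma))`.  Only included
#' markers contribute to the sum of squares (excluded effects are exactly
#' zero by the spike constraint).
#'
#' @param state an [mcmc_state()].
#' @param k population index.
#' @param n number of draws.
#' @return Numeric vector of variance draws.
#' @export
sample_sigma2_a <- function(state, k, n = 1) {
  pr <- state$prior
  sg <- sum(state$gamma)
  ssa <- sum(state$effects[, k]^2)
  df <- pr$v_a[k] + sg
  scale <- (pr$v_a[k] * pr$s2_a[k] + ssa) / df
  rscaled_inv_chisq(n, df, scale)
}

#' Sample the residual variance of one population
#'
#' Full conditional: scaled inverse chi-square with degrees of freedom
#' `v_e + n_k` and scale `(v_e s2_e + e_k' e_k) / (v_e + n_k)`, using the
#' maintained residual vector.
#'
#' @inheritParams sample_sigma2_a
#' @return Numeric vector of variance draws.
#' @export
sample_sigma2_e <- function(state, k, n = 1) {
  pr <- state$prior
  ek <- state$residuals[[k]]
  df <- pr$v_e[k] + length(ek)
  scale <- (pr$v_e[k] * pr$s2_e[k] + sum(ek^2)) / df
  rscaled_inv_chisq(n, df, scale)
}

#' Sample a population intercept
#'
#' Full conditional: normal with mean `mean(y_k - X_k a_k)` and variance
#' `sigma2_ek / n_k`.  Expressed through the maintained residuals the mean is
#' `mu_k + mean(e_k)`; after the draw the residuals are shifted by
#' `-(mu_new - mu_old)`.
#'
#' @inheritParams sample_sigma2_a
#' @return The mutated state (`n` is not available here: the state must stay
#'   consistent after each draw).
#' @export
sample_mu <- function(state, k) {
  ek <- state$residuals[[k]]
  nk <- length(ek)
  mu_new <- stats::rnorm(1, mean = state$mu[k] + mean(ek),
                         sd = sqrt(state$sigma2_e[k] / nk))
  state$residuals[[k]] <- ek - (mu_new - state$mu[k])
  state$mu[k] <- mu_new
  state
}

#' Maximum residual bookkeeping error of a state
#'
#' Recomputes `y_k - mu_k - X_k a_k` from scratch and returns the largest
#' absolute deviation from the maintained residuals, scaled by
#' `1 + max |y|`.
#'
#' @param state an [mcmc_state()].
#' @return Non-negative scalar.
#' @export
residual_error <- function(state) {
  err <- 0
  for (k in seq_len(state$n_pop)) {
    r <- state$y[[k]] - state$mu[k] -
      drop(state$X[[k]] %*% state$effects[, k])
    err <- max(err, max(abs(r - state$residuals[[k]])) /
                 (1 + max(abs(state$y[[k]]))))
  }
  err
}
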