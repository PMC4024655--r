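# Shared fixtures and independent oracles used across test files.

# small random genotype matrix with optional missingness
random_genotypes <- function(n, m, populations = rep("A", n),
                             missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing_rate > 0)
    codes[stats::runif(n * m) < missing_rate] <- NA
  rownames(codes) <- sprintf("S%03d", seq_len(n))
  colnames(codes) <- sprintf("M%03d", seq_len(m))
  genotype_matrix(codes, populations)
}

# deterministic two-population training set used by chain tests
tiny_two_pop_data <- function(n1 = 6, n2 = 6, m = 3, seed = 11,
                              effect = c(1.2, 0.9)) {
  set.seed(seed)
  X <- lapply(c(n1, n2), function(nk) {
    x <- matrix(sample(0:2, nk * m, replace = TRUE), nk, m) * 1.0
    colnames(x) <- sprintf("M%03d", seq_len(m))
    rownames(x) <- NULL
    x
  })
  names(X) <- c("A", "B")
  y <- list(A = drop(X[[1]][, 1] * effect[1]) + rnorm(n1, 0, 1),
            B = drop(X[[2]][, 1] * effect[2]) + rnorm(n2, 0, 1))
  list(X = X, y = y)
}

# log multivariate normal density with mean 0 and covariance V (via Cholesky)
log_dmvnorm0 <- function(x, V) {
  L <- chol(V)
  z <- backsolve(L, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# Exact posterior inclusion probabilities for the spike-and-slab model with
# frozen w, variances and intercepts: enumerate every indicator
# configuration, integrating the effects analytically (the marginal
# likelihood of y_k under a configuration S is multivariate normal with
# covariance sigma2_a X_S X_S' + sigma2_e I).
enumerate_inclusion_probs <- function(X, y, w, sigma2_a, sigma2_e, mu = 0) {
  m <- ncol(X[[1]])
  configs <- as.matrix(expand.grid(rep(list(0:1), m)))
  logpost <- apply(configs, 1, function(g) {
    lp <- sum(g) * log(1 - w) + (m - sum(g)) * log(w)
    for (k in seq_along(X)) {
      yk <- y[[k]] - mu
      S <- which(g == 1)
      V <- diag(sigma2_e[k], length(yk))
      if (length(S) > 0) {
        Xs <- X[[k]][, S, drop = FALSE]
        V <- V + sigma2_a[k] * tcrossprod(Xs)
      }
      lp <- lp + log_dmvnorm0(yk, V)
    }
    lp
  })
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  drop(crossprod(configs, post))
}
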