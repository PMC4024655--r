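#' Scale parameter of a scaled inverse chi-square prior from its mean
#'
#' A scaled inverse chi-square variable with degrees of freedom `v` and scale
#' `S^2` has expectation `S^2 v / (v - 2)` (for `v > 2`).  Solving for the
#' scale that gives a desired prior mean `sigma2` yields
#' `S^2 = sigma2 (v - 2) / v`.  This is how prior scales are derived from
#' known (true or REML-estimated) variances.
#'
#' @param sigma2 target prior mean of the variance (>= 0).
#' @param v degrees of freedom (> 2).
#' @return The scale `S^2`.
#' @export
derive_scale <- function(sigma2, v) {
  if (any(v <= 2)) stop("degrees of freedom must exceed 2 to derive a scale")
  if (any(sigma2 < 0)) stop("variance must be non-negative")
  sigma2 * (v - 2) / v
}

#' Prior specification for the spike-and-slab samplers
#'
#' Both variance components get scaled inverse chi-square priors: the
#' SNP-effect variance \eqn{\sigma^2_{ak}} with degrees of freedom `v_a` and
#' scale `s2_a`, and the residual variance \eqn{\sigma^2_{ek}} with `v_e` and
#' `s2_e`.  Scales may differ by population (task); supply vectors of length
#' equal to the number of tasks, or scalars to be recycled.  The intercepts
#' get flat priors and the exclusion probability `w` a Uniform(0, 1) prior;
#' neither needs a parameter here.
#'
#' @param s2_a,s2_e positive scale factors per population.
#' @param v_a,v_e degrees of freedom, both > 2 (defaults 4 and 10).
#' @return An object of class `prior_spec`.
#' @seealso [derive_scale()] to obtain scales from known variances.
#' @export
prior_spec <- function(s2_a, s2_e, v_a = 4, v_e = 10) {
  if (any(v_a <= 2) || any(v_e <= 2))
    stop("degrees of freedom must exceed 2")
  if (any(s2_a <= 0) || any(s2_e <= 0))
    stop("prior scales must be positive")
  structure(list(v_a = v_a, s2_a = s2_a, v_e = v_e, s2_e = s2_e),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior_spec:\n")
  cat("  sigma2_a ~ scaled-inv-chisq(v =", x$v_a, ", S2 =",
      paste(signif(x$s2_a, 4), collapse = ", "), ")\n")
  cat("  sigma2_e ~ scaled-inv-chisq(v =", x$v_e, ", S2 =",
      paste(signif(x$s2_e, 4), collapse = ", "), ")\n")
  invisible(x)
}

# recycle per-task prior vectors to length n_task
expand_prior <- function(prior, n_task) {
  rec <- function(x) {
    if (length(x) == 1) rep(x, n_task)
    else if (length(x) == n_task) x
    else stop("prior vector length must be 1 or the number of populations")
  }
  list(v_a = rec(prior$v_a), s2_a = rec(prior$s2_a),
       v_e = rec(prior$v_e), s2_e = rec(prior$s2_e))
}

#' Draw from a scaled inverse chi-square distribution
#'
#' Parameterized so that the density is proportional to
#' \eqn{(\sigma^2)^{-(1 + v/2)} \exp(-v S^2 / (2\sigma^2))}; equivalently
#' `v * S^2 / rchisq(n, v)`.
#'
#' @param n number of draws.
#' @param v degrees of freedom.
#' @param scale the scale `S^2`.
#' @return Numeric vector of draws.
#' @export
rscaled_inv_chisq <- function(n, v, scale) {
  v * scale / stats::rchisq(n, df = v)
}
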