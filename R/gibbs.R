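#' Gibbs chain configuration
#'
#' @param n_iter total Gibbs cycles (default 50000).
#' @param burn_in cycles discarded before summarization (default 10000);
#'   must be smaller than `n_iter`.
#' @param thin stride between recorded post burn-in samples (default 1:
#'   every post burn-in sample is kept).
#' @param seed integer seed applied with [set.seed()] before the chain runs;
#'   `NULL` leaves the RNG stream untouched.
#' @param w_form posterior form for the exclusion probability `w`, see
#'   [sample_w()].
#' @param update_w,update_sigma_a,update_sigma_e,update_mu set `FALSE` to
#'   freeze a block at its initial value (used for conditional-distribution
#'   checks and fixed-variance runs).
#' @param w_init initial `w`.
#' @param sigma2_a_init,sigma2_e_init,mu_init optional initial values per
#'   population; defaults are the prior means and the per-population
#'   phenotype means.
#' @param shuffle_order permute the marker update order each sweep
#'   (default `FALSE`: ascending marker index, for reproducibility).
#' @param check_every recompute residuals from scratch every this many
#'   sweeps to audit the bookkeeping (0 disables; the final sweep is always
#'   audited when enabled).
#' @param keep_samples store every recorded draw of `gamma` and the effects
#'   (memory heavy; intended for small instances and diagnostics).
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 50000, burn_in = 10000, thin = 1,
                         seed = NULL,
                         w_form = c("conjugate_plus_one", "as_printed"),
                         update_w = TRUE, update_sigma_a = TRUE,
                         update_sigma_e = TRUE, update_mu = TRUE,
                         w_init = 0.5, sigma2_a_init = NULL,
                         sigma2_e_init = NULL, mu_init = NULL,
                         shuffle_order = FALSE, check_every = 500,
                         keep_samples = FALSE) {
  w_form <- match.arg(w_form)
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1,
            w_init > 0, w_init < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, w_form = w_form,
                 update_w = update_w, update_sigma_a = update_sigma_a,
                 update_sigma_e = update_sigma_e, update_mu = update_mu,
                 w_init = w_init, sigma2_a_init = sigma2_a_init,
                 sigma2_e_init = sigma2_e_init, mu_init = mu_init,
                 shuffle_order = shuffle_order,
                 check_every = as.integer(check_every),
                 keep_samples = keep_samples),
            class = "gibbs_config")
}

# normalize per-population input into stacked form for the compiled core
stack_populations <- function(X, y) {
  if (!is.list(X)) X <- list(X)
  if (!is.list(y)) y <- list(y)
  stopifnot(length(X) == length(y), length(X) >= 1)
  m <- ncol(X[[1]])
  markers <- colnames(X[[1]])
  for (k in seq_along(X)) {
    stopifnot(is.matrix(X[[k]]), nrow(X[[k]]) == length(y[[k]]))
    if (ncol(X[[k]]) != m)
      stop("populations must share one marker panel")
    if (!is.null(markers) && !is.null(colnames(X[[k]])) &&
        !identical(colnames(X[[k]]), markers))
      stop("populations must share one marker order")
    if (anyNA(X[[k]]) || anyNA(y[[k]]))
      stop("genotypes and phenotypes must be complete; impute first")
    if (length(y[[k]]) < 1) stop("every population needs at least one sample")
  }
  if (m < 1) stop("at least one marker is required")
  pops <- names(X)
  if (is.null(pops)) pops <- paste0("pop", seq_along(X))
  list(X = do.call(rbind, X), y = unlist(y, use.names = FALSE),
       pop = rep(seq_along(X) - 1L, vapply(y, length, integer(1))),
       n_pop = length(X), pop_names = pops, m = m, markers = markers)
}

run_core <- function(stacked, task_of_pop, n_task, prior, config, method) {
  pr <- expand_prior(prior, n_task)
  s2a0 <- if (is.null(config$sigma2_a_init))
    pr$s2_a * pr$v_a / (pr$v_a - 2) else rep_len(config$sigma2_a_init, n_task)
  s2e0 <- if (is.null(config$sigma2_e_init))
    pr$s2_e * pr$v_e / (pr$v_e - 2) else rep_len(config$sigma2_e_init, n_task)
  mu0 <- if (is.null(config$mu_init)) {
    vapply(split(stacked$y, stacked$pop), mean, numeric(1))
  } else rep_len(config$mu_init, stacked$n_pop)
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .gibbs_core(stacked$X, stacked$y, stacked$pop, stacked$n_pop,
                     as.integer(task_of_pop), as.integer(n_task),
                     pr$v_a, pr$s2_a, pr$v_e, pr$s2_e,
                     config$n_iter, config$burn_in, config$thin,
                     config$w_form == "conjugate_plus_one",
                     config$update_w, config$update_sigma_a,
                     config$update_sigma_e, config$update_mu,
                     config$shuffle_order,
                     config$w_init, s2a0, s2e0, mu0,
                     config$check_every, config$keep_samples)
  task_names <- if (n_task == stacked$n_pop) stacked$pop_names else "pooled"
  dimnames(res$effect_mean) <- list(stacked$markers, task_names)
  names(res$inclusion_prob) <- stacked$markers
  names(res$mu_mean) <- stacked$pop_names
  names(res$sigma2_a_mean) <- names(res$sigma2_e_mean) <- task_names
  colnames(res$trace) <- c("iteration", "n_included", "w",
                           paste0("sigma2_a.", task_names),
                           paste0("sigma2_e.", task_names),
                           paste0("mu.", stacked$pop_names))
  structure(c(res, list(method = method, populations = stacked$pop_names,
                        config = config, prior = prior)),
            class = "posterior_summary")
}

#' Fit the multi-task spike-and-slab model
#'
#' Runs the Gibbs sampler for the multi-task Bayesian learning model: each
#' population `k` has its own intercept, SNP effects `a_jk`, SNP-effect
#' variance and residual variance, but all populations share one vector of
#' latent inclusion indicators `gamma`, so evidence for a marker is pooled
#' across populations while its effect size can differ (even in sign)
#' between them.
#'
#' @param X named list of per-population complete genotype matrices
#'   (samples x markers, shared marker order), e.g. from
#'   [impute_missing_to_mean()]; a single matrix is treated as one
#'   population.
#' @param y list of per-population phenotype vectors matching `X`.
#' @param prior a [prior_spec()].
#' @param config a [gibbs_config()].
#' @return A `posterior_summary` with posterior means of the effects
#'   (markers x populations), inclusion probabilities, intercepts, `w`,
#'   variance components, the scalar trace, and the largest residual
#'   bookkeeping error observed.
#' @seealso [run_single_task()], [run_pooled()], [predict_gebv()]
#' @export
run_multi_task <- function(X, y, prior, config = gibbs_config()) {
  st <- stack_populations(X, y)
  run_core(st, task_of_pop = seq_len(st$n_pop) - 1L, n_task = st$n_pop,
           prior, config, method = "multi")
}

#' Fit the single-task spike-and-slab model to one population
#'
#' Standard stochastic search variable selection for a single reference
#' population: the multi-task model with `c = 1`.  With the same seed and
#' configuration it produces a chain identical to [run_multi_task()] on
#' one population.
#'
#' @param X complete genotype matrix for one population (or a list of
#'   length 1).
#' @param y phenotype vector.
#' @inheritParams run_multi_task
#' @return A `posterior_summary`.
#' @export
run_single_task <- function(X, y, prior, config = gibbs_config()) {
  st <- stack_populations(X, y)
  if (st$n_pop != 1) stop("single-task model takes exactly one population")
  run_core(st, task_of_pop = 0L, n_task = 1L, prior, config,
           method = "single")
}

#' Fit the simple data pooling model
#'
#' Stacks all populations into one training set.  Population origin enters
#' as a fixed effect (one intercept per population), while a single effect
#' vector, one inclusion indicator vector, and one pair of variance
#' components are shared by every sample regardless of origin.
#'
#' @inheritParams run_multi_task
#' @return A `posterior_summary` whose `effect_mean` has a single column.
#' @export
run_pooled <- function(X, y, prior, config = gibbs_config()) {
  st <- stack_populations(X, y)
  run_core(st, task_of_pop = rep(0L, st$n_pop), n_task = 1L, prior, config,
           method = "pooled")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior_summary (%s model): %d markers, %d population(s)\n",
              x$method, nrow(x$effect_mean), length(x$populations)))
  cat(sprintf("  %d recorded samples; mean w = %.3f; mean markers included = %.1f\n",
              x$n_samples_used, x$w_mean, mean(x$trace[, "n_included"])))
  cat("  sigma2_a:", paste(signif(x$sigma2_a_mean, 4), collapse = ", "),
      "; sigma2_e:", paste(signif(x$sigma2_e_mean, 4), collapse = ", "), "\n")
  cat(sprintf("  max residual bookkeeping error: %.2e\n",
              x$max_residual_error))
  invisible(x)
}

#' Write or read a posterior summary as TSV
#'
#' One row per marker and population with the posterior mean effect and the
#' inclusion probability.  Header comment lines (prefixed `#`) carry the
#' method, seed, mean `w`, intercepts and variance components.
#'
#' @param summary a `posterior_summary`.
#' @param path output file.
#' @return `path` invisibly; `read_posterior_summary` returns a data.frame
#'   with attributes `mu_mean`, `w_mean`, `method`.
#' @export
write_posterior_summary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    sprintf("# method: %s", summary$method),
    sprintf("# seed: %s", if (is.null(summary$config$seed)) "NA"
            else summary$config$seed),
    sprintf("# n_samples_used: %d", summary$n_samples_used),
    sprintf("# w_mean: %.10g", summary$w_mean),
    sprintf("# mu_mean: %s",
            paste(sprintf("%s=%.10g", names(summary$mu_mean),
                          summary$mu_mean), collapse = ",")),
    sprintf("# sigma2_a_mean: %s",
            paste(sprintf("%.10g", summary$sigma2_a_mean), collapse = ",")),
    sprintf("# sigma2_e_mean: %s",
            paste(sprintf("%.10g", summary$sigma2_e_mean), collapse = ",")))
  writeLines(meta, con)
  tasks <- colnames(summary$effect_mean)
  tab <- data.frame(
    marker_id = rep(rownames(summary$effect_mean), times = length(tasks)),
    population = rep(tasks, each = nrow(summary$effect_mean)),
    effect_mean = as.vector(summary$effect_mean),
    inclusion_prob = rep(summary$inclusion_prob, times = length(tasks)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_summary
#' @export
read_posterior_summary <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  grab <- function(key) sub(paste0("^# ", key, ": "), "",
                            grep(paste0("^# ", key, ":"), meta, value = TRUE))
  mu_raw <- strsplit(grab("mu_mean"), ",")[[1]]
  mu <- as.numeric(sub("^.*=", "", mu_raw))
  names(mu) <- sub("=.*$", "", mu_raw)
  attr(tab, "method") <- grab("method")
  attr(tab, "w_mean") <- as.numeric(grab("w_mean"))
  attr(tab, "mu_mean") <- mu
  tab
}
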