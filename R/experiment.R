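#' Configure a simulation experiment
#'
#' Bundles everything needed to reproduce the simulation study at a chosen
#' scale: a simulator configuration, a chain configuration, the methods to
#' compare and the number of replicates.  Replicate and chain seeds are
#' derived deterministically from `seed`, so the whole experiment is a pure
#' function of its configuration.
#'
#' @param sim a [sim_config()].
#' @param gibbs a [gibbs_config()]; its `seed` field is ignored (seeds are
#'   derived per replicate and method).
#' @param methods subset of `c("single", "pooled", "multi")`.
#' @param replicates number of simulation replicates (default 10).
#' @param prior_source `"true_variances"` derives the prior scales from
#'   each replicate's simulated variances via [derive_scale()];
#'   `"user_supplied"` uses `prior` as given for every replicate.
#' @param prior a [prior_spec()], required when
#'   `prior_source = "user_supplied"`.
#' @param v_a,v_e degrees of freedom used when deriving priors from true
#'   variances (defaults 4 and 10).
#' @param seed master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(), gibbs = gibbs_config(),
                              methods = c("single", "pooled", "multi"),
                              replicates = 10,
                              prior_source = c("true_variances",
                                               "user_supplied"),
                              prior = NULL, v_a = 4, v_e = 10, seed = 1) {
  prior_source <- match.arg(prior_source)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(replicates >= 1)
  if (prior_source == "user_supplied" && is.null(prior))
    stop("supply `prior` when prior_source = 'user_supplied'")
  structure(list(sim = sim, gibbs = gibbs, methods = methods,
                 replicates = as.integer(replicates),
                 prior_source = prior_source, prior = prior,
                 v_a = v_a, v_e = v_e, seed = as.integer(seed)),
            class = "experiment_config")
}

# priors for one replicate from its simulated true variances
replicate_priors <- function(data, cfg) {
  if (cfg$prior_source == "user_supplied")
    return(list(per_pop = cfg$prior, pooled = cfg$prior))
  s2a <- derive_scale(data$truth$sigma2_a, cfg$v_a)
  s2e <- derive_scale(data$truth$sigma2_e, cfg$v_e)
  n_tr <- cfg$sim$n_train
  wmean <- function(x) sum(x * n_tr) / sum(n_tr)
  list(per_pop = prior_spec(s2_a = s2a, s2_e = s2e,
                            v_a = cfg$v_a, v_e = cfg$v_e),
       pooled = prior_spec(s2_a = derive_scale(wmean(data$truth$sigma2_a),
                                               cfg$v_a),
                           s2_e = derive_scale(wmean(data$truth$sigma2_e),
                                               cfg$v_e),
                           v_a = cfg$v_a, v_e = cfg$v_e))
}

# fit one method on one replicate and evaluate on the validation split
fit_and_evaluate <- function(data, method, priors, gcfg, chain_seeds) {
  pops <- names(data$panel)
  train_g <- validation_g <- list()
  y_train <- list()
  pheno <- data$phenotypes
  for (p in pops) {
    g <- data$panel[[p]]
    ids <- rownames(g$codes)
    tr <- ids[ids %in% data$split$train]
    va <- ids[ids %in% data$split$validation]
    train_g[[p]] <- impute_missing_to_mean(subset_genotypes(g, samples = tr))
    validation_g[[p]] <- subset_genotypes(g, samples = va)
    y_train[[p]] <- pheno$value[match(tr, pheno$sample_id)]
  }
  tbv_all <- unlist(unname(data$truth$tbv))

  eval_one <- function(summary, g_val) {
    pred <- predict_gebv(summary, g_val)
    evaluate_predictions(pred, tbv_all)
  }

  if (method == "single") {
    res <- lapply(seq_along(pops), function(k) {
      p <- pops[k]
      gcfg$seed <- chain_seeds[k]
      pr <- priors$per_pop
      pr_k <- prior_spec(s2_a = rep_len(pr$s2_a, length(pops))[k],
                         s2_e = rep_len(pr$s2_e, length(pops))[k],
                         v_a = pr$v_a, v_e = pr$v_e)
      fit <- run_single_task(train_g[p], y_train[p], pr_k, gcfg)
      eval_one(fit, validation_g[[p]])
    })
    out <- do.call(rbind, res)
  } else if (method == "pooled") {
    gcfg$seed <- chain_seeds[1]
    fit <- run_pooled(train_g, y_train, priors$pooled, gcfg)
    g_val <- do.call(rbind, lapply(validation_g, function(g)
      data.frame(sample_id = rownames(g$codes),
                 population = as.character(g$population),
                 g$codes, check.names = FALSE)))
    gv <- genotype_matrix(as.matrix(g_val[, -(1:2)]), g_val$population)
    rownames(gv$codes) <- g_val$sample_id
    out <- eval_one(fit, gv)
  } else {
    gcfg$seed <- chain_seeds[1]
    fit <- run_multi_task(train_g, y_train, priors$per_pop, gcfg)
    g_val <- do.call(rbind, lapply(validation_g, function(g)
      data.frame(sample_id = rownames(g$codes),
                 population = as.character(g$population),
                 g$codes, check.names = FALSE)))
    gv <- genotype_matrix(as.matrix(g_val[, -(1:2)]), g_val$population)
    rownames(gv$codes) <- g_val$sample_id
    out <- eval_one(fit, gv)
  }
  out$method <- method
  out
}

#' Run a replicated simulation experiment
#'
#' Loops `simulate -> fit -> predict -> evaluate` over replicates and
#' methods and aggregates accuracy and slope per method and population
#' (mean and standard error over replicates), the simulation-study
#' analogue of a results table comparing single-task, pooling and
#' multi-task prediction.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print one line per replicate.
#' @return list with `summary` (aggregated data.frame from
#'   [replicate_summary()]), `replicates` (per-replicate results) and
#'   `config`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$replicates)
  chain_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   cfg$replicates * length(cfg$methods) * 4L),
                        nrow = cfg$replicates)
  detail <- list()
  for (r in seq_len(cfg$replicates)) {
    data <- simulate_study_data(cfg$sim, seed = rep_seeds[r])
    priors <- replicate_priors(data, cfg)
    for (mi in seq_along(cfg$methods)) {
      method <- cfg$methods[mi]
      seeds <- chain_seeds[r, ((mi - 1) * 4 + 1):(mi * 4)]
      res <- fit_and_evaluate(data, method, priors, cfg$gibbs, seeds)
      res$replicate <- r
      detail[[length(detail) + 1]] <- res
      if (verbose)
        message(sprintf("replicate %d, %s: %s", r, method,
                        paste(sprintf("%s r=%.3f b=%.3f", res$population,
                                      res$r, res$b), collapse = "; ")))
    }
  }
  detail <- do.call(rbind, detail)
  detail <- detail[, c("replicate", "method", "population", "r", "b", "n")]
  list(summary = replicate_summary(detail), replicates = detail,
       config = cfg)
}
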