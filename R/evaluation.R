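#' Predict genomic estimated breeding values
#'
#' The GEBV of a validation animal is the population mean plus the sum of
#' its genotype codes weighted by the posterior-mean marker effects:
#' `gebv_i = mu_k + sum_j x_ij * effect_mean[j, k]`.  The multi-task and
#' single-task models use the effect column of the animal's own
#' population; the pooled model uses its single shared effect column with
#' the population-specific intercept.
#'
#' @param summary a `posterior_summary` from [run_multi_task()],
#'   [run_single_task()] or [run_pooled()].
#' @param g validation genotypes: a [genotype_matrix()] (complete, or
#'   imputable via [impute_missing_to_mean()]) whose markers match the
#'   summary's markers exactly.
#' @return data.frame with columns `sample_id`, `population`, `gebv`.
#' @export
predict_gebv <- function(summary, g) {
  stopifnot(inherits(summary, "posterior_summary"),
            inherits(g, "genotype_matrix"))
  codes <- if (anyNA(g$codes)) impute_missing_to_mean(g) else g$codes
  eff <- summary$effect_mean
  if (!identical(colnames(codes), rownames(eff)))
    stop("validation markers do not match the fitted marker panel")
  pop <- as.character(g$population)
  levs <- unique(pop)
  if (!all(levs %in% names(summary$mu_mean)))
    stop("validation population(s) absent from the fitted model: ",
         paste(setdiff(levs, names(summary$mu_mean)), collapse = ", "))
  gebv <- numeric(nrow(codes))
  for (lev in levs) {
    rows <- pop == lev
    col <- if (summary$method == "pooled") 1L else {
      if (!lev %in% colnames(eff))
        stop("no effect column for population ", lev)
      match(lev, colnames(eff))
    }
    gebv[rows] <- summary$mu_mean[[lev]] +
      drop(codes[rows, , drop = FALSE] %*% eff[, col])
  }
  data.frame(sample_id = rownames(codes), population = pop, gebv = gebv,
             stringsAsFactors = FALSE)
}

#' Accuracy of genomic prediction
#'
#' Pearson correlation between GEBV and true breeding values,
#' `r(GEBV, TBV)`.
#'
#' @param gebv,tbv numeric vectors of equal length (n >= 3).
#' @return The correlation.
#' @export
accuracy_r <- function(gebv, tbv) {
  stopifnot(length(gebv) == length(tbv), length(gebv) >= 3)
  if (stats::sd(gebv) == 0 || stats::sd(tbv) == 0)
    stop("accuracy undefined: zero variance")
  stats::cor(gebv, tbv)
}

#' Dispersion slope of genomic prediction
#'
#' Regression coefficient of true breeding value on GEBV,
#' `b(TBV, GEBV) = cov(TBV, GEBV) / var(GEBV)`.  A slope below 1 means the
#' GEBV are over-dispersed (inflated): one extra unit of GEBV corresponds
#' to less than one unit of true merit.
#'
#' @inheritParams accuracy_r
#' @return The slope.
#' @export
slope_b <- function(gebv, tbv) {
  stopifnot(length(gebv) == length(tbv), length(gebv) >= 3)
  v <- stats::var(gebv)
  if (v == 0) stop("slope undefined: zero GEBV variance")
  stats::cov(tbv, gebv) / v
}

#' Evaluate predictions against true breeding values
#'
#' @param pred data.frame from [predict_gebv()].
#' @param tbv named numeric vector of true breeding values (names are
#'   sample ids) covering every predicted sample.
#' @return data.frame with one row per population: `population`, `r`, `b`,
#'   `n`.
#' @export
evaluate_predictions <- function(pred, tbv) {
  stopifnot(all(pred$sample_id %in% names(tbv)))
  out <- lapply(split(pred, pred$population), function(d) {
    tv <- tbv[d$sample_id]
    data.frame(population = d$population[1],
               r = accuracy_r(d$gebv, tv), b = slope_b(d$gebv, tv),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate evaluation results over replicates
#'
#' Computes the arithmetic mean and the standard error of the mean of the
#' accuracy `r` and the slope `b` across replicates, within each
#' combination of the grouping columns.
#'
#' @param results data.frame with numeric columns `r` and `b` and one row
#'   per replicate and cell.
#' @param by character vector of grouping column names present in
#'   `results` (default `c("method", "population")`; groups absent from
#'   the data are ignored).
#' @return data.frame with columns `by`, `r_mean`, `r_se`, `b_mean`,
#'   `b_se`, `n_replicates`.
#' @export
replicate_summary <- function(results, by = c("method", "population")) {
  by <- intersect(by, names(results))
  stopifnot(all(c("r", "b") %in% names(results)))
  key <- if (length(by)) interaction(results[by], drop = TRUE)
         else factor(rep(1, nrow(results)))
  out <- lapply(split(results, key), function(d) {
    if (nrow(d) < 2) stop("replicate_summary needs >= 2 replicates per cell")
    se <- function(x) stats::sd(x) / sqrt(length(x))
    cbind(d[1, by, drop = FALSE],
          data.frame(r_mean = mean(d$r), r_se = se(d$r),
                     b_mean = mean(d$b), b_se = se(d$b),
                     n_replicates = nrow(d)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
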