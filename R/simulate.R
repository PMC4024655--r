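#' Configuration for the two-population simulation study
#'
#' The simulator reproduces the statistical structure of a two-breed dairy
#' cattle genomic-prediction design: two populations of unequal size, SNP
#' panels with linkage disequilibrium and MAF at or above 0.05 in each
#' population, QTL drawn from a designated low-density subset of the panel,
#' allele substitution effects correlated between populations, and a trait
#' with heritability 0.5.
#'
#' Genotypes come from a Balding-Nichols / latent-Gaussian model: each
#' marker has an ancestral frequency drawn Uniform(0.1, 0.9); population
#' frequencies are Beta-distributed around it with divergence `fst`; each
#' haplotype is a stationary AR(1) Gaussian process over markers
#' (coefficient `ld_phi`) thresholded at the population frequency, so
#' adjacent markers are in LD; a genotype is the sum of two independent
#' haplotypes.  Markers whose realized MAF falls below `maf_min` in either
#' population have their frequencies redrawn.
#'
#' @param n_per_population samples per population (defaults 458 and 2298).
#' @param n_train training samples per population (defaults 393 and 2084;
#'   the remainder, 65 and 214, validates).
#' @param m_markers markers simulated before panel thinning (default 2000).
#' @param n_qtl number of causal loci (study values: 20 or 200).
#' @param rho correlation of QTL effects between the two populations
#'   (study values: 0.2 or 0.8).
#' @param fst Balding-Nichols divergence between populations (default 0.1).
#' @param ld_phi AR(1) coefficient of the latent haplotype process
#'   (default 0.95); 0 gives independent markers.
#' @param include_qtl_in_panel keep QTL genotypes in the prediction panel
#'   (default `FALSE`: QTL columns are removed, so markers tag QTL only
#'   through LD).
#' @param thin_factor keep every `thin_factor`-th marker in the panel
#'   (1, 2, 4 or 8, mimicking chip densities).
#' @param qtl_pool_stride QTL are drawn from every `qtl_pool_stride`-th
#'   marker, emulating a low-density subset of the full panel (default 8).
#' @param h2 trait heritability sigma2_a / (sigma2_a + sigma2_e)
#'   (default 0.5, giving sigma2_e = sigma2_a exactly).
#' @param maf_min minimum per-population MAF enforced in simulated panels.
#' @param population_names labels for the populations.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_population = c(458, 2298),
                       n_train = c(393, 2084),
                       m_markers = 2000, n_qtl = 20, rho = 0.2,
                       fst = 0.1, ld_phi = 0.95,
                       include_qtl_in_panel = FALSE, thin_factor = 1,
                       qtl_pool_stride = 8, h2 = 0.5, maf_min = 0.05,
                       population_names = NULL) {
  stopifnot(length(n_per_population) >= 1, all(n_per_population >= 2),
            length(n_train) == length(n_per_population),
            all(n_train >= 1), all(n_train < n_per_population),
            m_markers >= 1, n_qtl >= 1, abs(rho) <= 1,
            fst >= 0, fst < 1, ld_phi >= 0, ld_phi < 1,
            thin_factor %in% c(1, 2, 4, 8),
            qtl_pool_stride >= 1, h2 > 0, h2 < 1,
            maf_min >= 0, maf_min < 0.5)
  pool <- length(seq(1, m_markers, by = qtl_pool_stride))
  if (n_qtl > pool)
    stop("n_qtl exceeds the QTL pool size (", pool, " markers)")
  if (is.null(population_names))
    population_names <- paste0("pop", seq_along(n_per_population))
  structure(list(n_per_population = as.integer(n_per_population),
                 n_train = as.integer(n_train),
                 m_markers = as.integer(m_markers),
                 n_qtl = as.integer(n_qtl), rho = rho, fst = fst,
                 ld_phi = ld_phi,
                 include_qtl_in_panel = include_qtl_in_panel,
                 thin_factor = as.integer(thin_factor),
                 qtl_pool_stride = as.integer(qtl_pool_stride),
                 h2 = h2, maf_min = maf_min,
                 population_names = population_names),
            class = "sim_config")
}

# nh haplotypes x m markers of a stationary AR(1) latent Gaussian
ar1_latent <- function(nh, m, phi) {
  Z <- matrix(0, nh, m)
  Z[, 1] <- stats::rnorm(nh)
  if (m > 1) {
    s <- sqrt(1 - phi^2)
    for (j in 2:m) Z[, j] <- phi * Z[, j - 1] + s * stats::rnorm(nh)
  }
  Z
}

# Balding-Nichols population frequencies around ancestral p
balding_nichols <- function(p, fst) {
  if (fst == 0) return(p)
  lambda <- (1 - fst) / fst
  q <- stats::rbeta(length(p), p * lambda, (1 - p) * lambda)
  pmin(pmax(q, 1e-6), 1 - 1e-6)
}

#' Simulate linked two-population genotypes
#'
#' See [sim_config()] for the generative model.  Markers failing the
#' per-population MAF floor have their ancestral and population frequencies
#' redrawn (against the same latent haplotype process, so LD is preserved)
#' until every marker passes.
#'
#' @param cfg a [sim_config()].
#' @return A list with `genotypes` (named list of per-population
#'   [genotype_matrix()] objects, no missing values), `freq` (markers x
#'   populations matrix of target population frequencies) and
#'   `ancestral_freq`.
#' @export
simulate_genotypes <- function(cfg) {
  m <- cfg$m_markers
  c_pop <- length(cfg$n_per_population)
  Z <- lapply(cfg$n_per_population,
              function(nk) ar1_latent(2L * nk, m, cfg$ld_phi))
  p_anc <- stats::runif(m, 0.1, 0.9)
  freq <- vapply(seq_len(c_pop), function(k) balding_nichols(p_anc, cfg$fst),
                 numeric(m))
  freq <- matrix(freq, m, c_pop)

  threshold_cols <- function(k, cols) {
    thr <- stats::qnorm(freq[cols, k])
    Zk <- Z[[k]][, cols, drop = FALSE]
    H <- Zk < matrix(thr, nrow(Zk), length(cols), byrow = TRUE)
    odd <- seq(1, nrow(Zk), by = 2)
    H[odd, , drop = FALSE] + H[odd + 1, , drop = FALSE]
  }

  G <- lapply(seq_len(c_pop), function(k) threshold_cols(k, seq_len(m)))
  failing <- function() {
    bad <- rep(FALSE, m)
    for (k in seq_len(c_pop)) {
      f <- colMeans(G[[k]]) / 2
      bad <- bad | pmin(f, 1 - f) < cfg$maf_min
    }
    which(bad)
  }
  bad <- failing()
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > 1000)
      stop("could not satisfy the MAF floor after 1000 resampling rounds")
    p_anc[bad] <- stats::runif(length(bad), 0.1, 0.9)
    for (k in seq_len(c_pop))
      freq[bad, k] <- balding_nichols(p_anc[bad], cfg$fst)
    for (k in seq_len(c_pop))
      G[[k]][, bad] <- threshold_cols(k, bad)
    bad <- failing()
  }

  markers <- sprintf("M%05d", seq_len(m))
  genos <- lapply(seq_len(c_pop), function(k) {
    codes <- G[[k]]
    rownames(codes) <- sprintf("%s_%04d", cfg$population_names[k],
                               seq_len(nrow(codes)))
    colnames(codes) <- markers
    genotype_matrix(codes, rep(cfg$population_names[k], nrow(codes)))
  })
  names(genos) <- cfg$population_names
  rownames(freq) <- markers
  colnames(freq) <- cfg$population_names
  list(genotypes = genos, freq = freq, ancestral_freq = p_anc)
}

#' Draw QTL positions from the low-density marker pool
#'
#' QTL indices are sampled uniformly without replacement from every
#' `qtl_pool_stride`-th marker (the simulated analogue of drawing causal
#' loci from a low-density chip embedded in a denser panel).
#'
#' @param cfg a [sim_config()].
#' @return Sorted integer vector of `n_qtl` marker indices.
#' @export
select_qtl <- function(cfg) {
  pool <- seq(1L, cfg$m_markers, by = cfg$qtl_pool_stride)
  if (length(pool) < cfg$n_qtl) stop("QTL pool smaller than n_qtl")
  sort(sample(pool, cfg$n_qtl))
}

#' Sample correlated QTL effects for two populations
#'
#' Allele substitution effects of each QTL in the two populations are drawn
#' from a bivariate normal with mean zero, unit variances and correlation
#' `rho`; `rho = 1` gives exactly equal effects.
#'
#' @param n_qtl number of QTL.
#' @param rho effect correlation, in \[-1, 1\].
#' @return `n_qtl` x 2 matrix of effects.
#' @export
sample_qtl_effects <- function(n_qtl, rho) {
  stopifnot(abs(rho) <= 1)
  z1 <- stats::rnorm(n_qtl)
  z2 <- stats::rnorm(n_qtl)
  cbind(a1 = z1, a2 = rho * z1 + sqrt(max(0, 1 - rho^2)) * z2)
}

#' Additive genetic variance from QTL frequencies and effects
#'
#' Computes \eqn{\sigma^2_a = \sum_j 2 p_j (1 - p_j) \alpha_{jk}^2} for
#' population `k`, the additive variance the QTL would generate at
#' linkage equilibrium.
#'
#' @param freqs QTL allele frequencies in population `k`.
#' @param alpha QTL effect matrix (QTL x populations) or vector.
#' @param k population column of `alpha` to use.
#' @return Scalar variance.
#' @export
compute_genetic_variance <- function(freqs, alpha, k = 1) {
  stopifnot(all(freqs >= 0), all(freqs <= 1))
  a <- if (is.matrix(alpha)) alpha[, k] else alpha
  stopifnot(length(a) == length(freqs))
  sum(2 * freqs * (1 - freqs) * a^2)
}

#' Simulate phenotypes from true breeding values
#'
#' Adds independent normal residuals to the per-population true breeding
#' values: `y_i = a_i + e_i` with `e_i ~ N(0, sigma2_e[k])`, where
#' `sigma2_e` comes from `truth` (derived as
#' `sigma2_a * (1 - h2) / h2`, equal to `sigma2_a` at the default
#' heritability 0.5).
#'
#' @param genotypes named list of per-population [genotype_matrix()]
#'   objects holding the full (QTL-bearing) marker set.
#' @param truth a truth object from [simulate_study_data()] (fields
#'   `qtl_indices`, `alpha`, `sigma2_e` are used).
#' @return data.frame with columns `sample_id`, `population`, `value`.
#' @export
simulate_phenotypes <- function(genotypes, truth) {
  out <- lapply(seq_along(genotypes), function(k) {
    g <- genotypes[[k]]
    tbv <- drop(g$codes[, truth$qtl_indices, drop = FALSE] %*%
                  truth$alpha[, k])
    e <- stats::rnorm(length(tbv), 0, sqrt(truth$sigma2_e[k]))
    data.frame(sample_id = rownames(g$codes),
               population = as.character(g$population),
               value = tbv + e, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build a prediction panel from the simulated markers
#'
#' Thins the marker set to every `thin_factor`-th marker (anchored at the
#' first), then removes the QTL columns unless `include_qtl_in_panel` is
#' set, in which case any QTL dropped by thinning are appended so every
#' causal locus is genotyped.
#'
#' @param g a [genotype_matrix()] over the full simulated marker set.
#' @param qtl integer QTL indices into the full marker set.
#' @param cfg a [sim_config()] (`thin_factor`, `include_qtl_in_panel`).
#' @return A `genotype_matrix` restricted to the panel markers.
#' @export
build_panel <- function(g, qtl, cfg) {
  kept <- seq(1L, n_markers(g), by = cfg$thin_factor)
  if (cfg$include_qtl_in_panel) {
    kept <- c(kept, setdiff(qtl, kept))
  } else {
    kept <- setdiff(kept, qtl)
  }
  if (length(kept) == 0) stop("panel construction removed every marker")
  subset_genotypes(g, markers = kept)
}

#' Random training/validation split per population
#'
#' Draws the configured number of training samples uniformly within each
#' population; the remaining samples validate.  (A real study would split
#' by birth year; the simulator has no pedigree, so the split is random but
#' seed-reproducible.)
#'
#' @param sample_ids character vector of sample ids.
#' @param population per-sample population labels aligned with
#'   `sample_ids`.
#' @param n_train named or positional vector of training counts per
#'   population (in population-level order).
#' @return list with character vectors `train` and `validation`.
#' @export
split_train_validation <- function(sample_ids, population, n_train) {
  population <- factor(population)
  levs <- levels(population)
  stopifnot(length(n_train) == length(levs))
  train <- character(0)
  for (i in seq_along(levs)) {
    ids <- sample_ids[population == levs[i]]
    if (n_train[i] > length(ids))
      stop("training size exceeds population size for ", levs[i])
    train <- c(train, sample(ids, n_train[i]))
  }
  list(train = train, validation = setdiff(sample_ids, train))
}

#' Run the full simulation pipeline
#'
#' Generates genotypes, QTL, effects, true breeding values, variances,
#' phenotypes, the prediction panel and the training/validation split —
#' the complete inputs of one simulation replicate.  The per-population
#' additive genetic variance is computed from the realized QTL allele
#' frequencies through \eqn{\sum_j 2 p_j (1-p_j) \alpha_{jk}^2}, and the
#' residual variance as `sigma2_a * (1 - h2) / h2` (when every QTL effect
#' is zero the residual variance falls back to 1 so phenotypes remain
#' stochastic).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed; the pipeline is a pure function of
#'   `(cfg, seed)`.
#' @return An object of class `sim_study`: list with `genotypes` (full
#'   marker set per population), `panel` (panel-restricted genotypes per
#'   population), `phenotypes`, `truth` (QTL indices and ids, effect
#'   matrix, per-sample TBV, per-population `sigma2_a`/`sigma2_e`,
#'   realized QTL frequencies), `split` and `config`.
#' @export
simulate_study_data <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_genotypes(cfg)
  qtl <- select_qtl(cfg)
  alpha <- sample_qtl_effects(cfg$n_qtl, cfg$rho)
  c_pop <- length(sim$genotypes)

  realized <- vapply(sim$genotypes,
                     function(g) allele_frequency(g)[qtl],
                     numeric(cfg$n_qtl))
  realized <- matrix(realized, cfg$n_qtl, c_pop,
                     dimnames = list(NULL, names(sim$genotypes)))
  sigma2_a <- vapply(seq_len(c_pop), function(k)
    compute_genetic_variance(realized[, k], alpha, min(k, ncol(alpha))),
    numeric(1))
  sigma2_e <- ifelse(sigma2_a > 0, sigma2_a * (1 - cfg$h2) / cfg$h2, 1)

  tbv <- lapply(seq_len(c_pop), function(k) {
    g <- sim$genotypes[[k]]
    v <- drop(g$codes[, qtl, drop = FALSE] %*% alpha[, min(k, ncol(alpha))])
    names(v) <- rownames(g$codes)
    v
  })
  names(tbv) <- names(sim$genotypes)

  truth <- list(qtl_indices = qtl,
                qtl_markers = colnames(sim$genotypes[[1]]$codes)[qtl],
                alpha = alpha, tbv = tbv,
                sigma2_a = stats::setNames(sigma2_a, names(sim$genotypes)),
                sigma2_e = stats::setNames(sigma2_e, names(sim$genotypes)),
                qtl_freq = realized)

  phenotypes <- simulate_phenotypes(sim$genotypes, truth)
  panel <- lapply(sim$genotypes, build_panel, qtl = qtl, cfg = cfg)

  all_ids <- unlist(lapply(sim$genotypes, function(g) rownames(g$codes)),
                    use.names = FALSE)
  all_pop <- unlist(lapply(sim$genotypes,
                           function(g) as.character(g$population)),
                    use.names = FALSE)
  split <- split_train_validation(all_ids, factor(all_pop,
                                                  levels = cfg$population_names),
                                  cfg$n_train)

  structure(list(genotypes = sim$genotypes, panel = panel,
                 phenotypes = phenotypes, truth = truth, split = split,
                 freq = sim$freq, config = cfg),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("sim_study: %s samples, %d markers (%d in panel), %d QTL, rho=%.2f\n",
              paste(cfg$n_per_population, collapse = "+"), cfg$m_markers,
              n_markers(x$panel[[1]]), cfg$n_qtl, cfg$rho))
  cat(sprintf("  sigma2_a: %s; heritability %.2f\n",
              paste(signif(x$truth$sigma2_a, 4), collapse = ", "), cfg$h2))
  invisible(x)
}
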