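#' @name qc_filters
#' @title Marker quality-control filters
#'
#' @description
#' Marker-level QC mirroring common practice for SNP chips before
#' whole-genome regression: markers are dropped when the minor allele
#' frequency is too low, when too many genotypes are missing, or when a
#' nearby marker carries (almost) the same genotype column.  Each filter
#' returns the filtered matrix together with a `qc_report` recording which
#' markers were removed and why; the report fields partition the input
#' marker set.
#'
#' Thresholds are strict inequalities: a marker with MAF exactly at the
#' threshold, or a missing rate exactly at the cap, survives.
#'
#' @param g a [genotype_matrix()].
#' @return A list with elements `genotypes` (the filtered
#'   `genotype_matrix`) and `report` (a `qc_report`).
NULL

qc_report <- function(kept, removed_maf = character(), removed_missing = character(),
                      removed_duplicate = character(),
                      removed_cross_population = character()) {
  structure(list(kept = kept, removed_maf = removed_maf,
                 removed_missing = removed_missing,
                 removed_duplicate = removed_duplicate,
                 removed_cross_population = removed_cross_population),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", length(x$kept), "markers kept;",
      length(x$removed_maf), "failed MAF,",
      length(x$removed_missing), "failed missingness,",
      length(x$removed_duplicate), "near-duplicate,",
      length(x$removed_cross_population), "removed for cross-population",
      "consistency\n")
  invisible(x)
}

#' Per-marker allele frequency of the coded allele
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector of coded-allele frequencies over non-missing
#'   genotypes.
#' @export
allele_frequency <- function(g) {
  colMeans(g$codes, na.rm = TRUE) / 2
}

#' @describeIn qc_filters Remove markers with minor allele frequency
#'   strictly below `threshold`, computed over the non-missing genotypes of
#'   the matrix as passed in (so per population when called before
#'   harmonization).
#' @param threshold MAF cutoff in (0, 0.5].
#' @export
qc_filter_maf <- function(g, threshold = 0.05) {
  stopifnot(threshold > 0, threshold <= 0.5)
  p <- allele_frequency(g)
  maf <- pmin(p, 1 - p)
  drop <- maf < threshold | is.nan(maf)
  if (all(drop)) warning("MAF filter removed every marker")
  list(genotypes = subset_genotypes(g, markers = which(!drop)),
       report = qc_report(kept = colnames(g$codes)[!drop],
                          removed_maf = colnames(g$codes)[drop]))
}

#' @describeIn qc_filters Remove markers whose missing-genotype fraction
#'   strictly exceeds `max_rate`.
#' @param max_rate maximum tolerated missing fraction in \[0, 1\].
#' @export
qc_filter_missing <- function(g, max_rate = 0.10) {
  stopifnot(max_rate >= 0, max_rate <= 1)
  rate <- colMeans(is.na(g$codes))
  drop <- rate > max_rate
  list(genotypes = subset_genotypes(g, markers = which(!drop)),
       report = qc_report(kept = colnames(g$codes)[!drop],
                          removed_missing = colnames(g$codes)[drop]))
}

#' @describeIn qc_filters Remove the later marker of any pair whose genotype
#'   columns agree (identically, or as complements `g1 = 2 - g2`) on at least
#'   `agreement` of the samples non-missing at both loci.  Because
#'   high-agreement pairs arise from local linkage disequilibrium, only pairs
#'   within a sliding window of `window` adjacent markers are compared;
#'   `window = Inf` compares all pairs.  Pairs sharing fewer than
#'   `min_joint` jointly non-missing samples are never declared duplicates.
#' @param agreement minimum agreement fraction in (0, 1].
#' @param window number of adjacent markers scanned (default 100).
#' @param min_joint minimum jointly non-missing samples for a comparison.
#' @export
qc_filter_near_duplicates <- function(g, agreement = 0.95, window = 100,
                                      min_joint = 10) {
  stopifnot(agreement > 0, agreement <= 1)
  m <- n_markers(g)
  codes <- g$codes
  window <- min(window, m - 1)
  keep <- rep(TRUE, m)
  if (m >= 2 && window >= 1) {
    # agree[j, d]: agreement of marker j with marker j - d (NA when too few
    # joint observations)
    agree <- matrix(NA_real_, m, window)
    for (d in seq_len(window)) {
      left <- codes[, seq_len(m - d), drop = FALSE]
      right <- codes[, seq_len(m - d) + d, drop = FALSE]
      ok <- !is.na(left) & !is.na(right)
      njoint <- colSums(ok)
      same <- colSums(ok & (left == right))
      comp <- colSums(ok & (left == 2 - right))
      frac <- pmax(same, comp) / njoint
      frac[njoint < min_joint] <- NA_real_
      agree[seq_len(m - d) + d, d] <- frac
    }
    for (j in 2:m) {
      for (d in seq_len(min(window, j - 1))) {
        if (!keep[j - d]) next
        a <- agree[j, d]
        if (!is.na(a) && a >= agreement) { keep[j] <- FALSE; break }
      }
    }
  }
  list(genotypes = subset_genotypes(g, markers = which(keep)),
       report = qc_report(kept = colnames(codes)[keep],
                          removed_duplicate = colnames(codes)[!keep]))
}

#' Harmonize marker panels across populations
#'
#' After per-population QC, a marker dropped in one population must also be
#' dropped in the others so that all populations share one marker panel.
#' This keeps the intersection of the surviving marker sets, in the marker
#' order of the first population.
#'
#' @param gs named list of per-population [genotype_matrix()] objects
#'   (already QC-filtered).
#' @return A list with `genotypes` (list of reduced matrices sharing one
#'   marker order) and `reports` (per-population `qc_report`s whose
#'   `removed_cross_population` field lists markers dropped here).
#' @export
harmonize_panels <- function(gs) {
  stopifnot(length(gs) >= 1)
  kept_sets <- lapply(gs, function(g) colnames(g$codes))
  common <- Reduce(intersect, kept_sets)
  if (length(common) == 0) stop("no marker survives QC in every population")
  common <- kept_sets[[1]][kept_sets[[1]] %in% common]  # order of first panel
  out <- lapply(gs, function(g) subset_genotypes(g, markers = common))
  reports <- lapply(kept_sets, function(k)
    qc_report(kept = common, removed_cross_population = setdiff(k, common)))
  list(genotypes = out, reports = reports)
}

#' Run the full QC pipeline per population and harmonize
#'
#' Applies, in order: MAF filter, missingness filter, near-duplicate filter
#' (each within population), then cross-population harmonization.
#'
#' @param gs named list of per-population [genotype_matrix()] objects.
#' @param maf,max_missing,agreement,window filter parameters, see
#'   [qc_filters].
#' @return list with `genotypes` (harmonized list) and `reports`
#'   (per-population merged `qc_report`s).
#' @export
qc_pipeline <- function(gs, maf = 0.05, max_missing = 0.10,
                        agreement = 0.95, window = 100) {
  reports <- vector("list", length(gs))
  names(reports) <- names(gs)
  filtered <- gs
  for (i in seq_along(gs)) {
    s1 <- qc_filter_maf(filtered[[i]], maf)
    s2 <- qc_filter_missing(s1$genotypes, max_missing)
    s3 <- qc_filter_near_duplicates(s2$genotypes, agreement, window)
    filtered[[i]] <- s3$genotypes
    reports[[i]] <- qc_report(kept = s3$report$kept,
                              removed_maf = s1$report$removed_maf,
                              removed_missing = s2$report$removed_missing,
                              removed_duplicate = s3$report$removed_duplicate)
  }
  harm <- harmonize_panels(filtered)
  for (i in seq_along(reports)) {
    reports[[i]]$removed_cross_population <-
      harm$reports[[i]]$removed_cross_population
    reports[[i]]$kept <- harm$reports[[i]]$kept
  }
  list(genotypes = harm$genotypes, reports = reports)
}
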