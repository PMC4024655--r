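#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds additive genotype codes for a set of samples at a
#' set of SNP markers, together with a population label per sample.  Codes
#' count copies of an arbitrarily chosen reference allele, so every
#' non-missing cell is 0, 1 or 2; missing genotypes are `NA`.
#'
#' @param codes numeric matrix, samples in rows and markers in columns, with
#'   values in `{0, 1, 2, NA}`.  Row names are sample ids and column names are
#'   marker ids; defaults are generated when absent.
#' @param population character or factor vector of per-sample population
#'   labels.  Every level must label at least one sample.
#' @return An object of class `genotype_matrix` with elements `codes`
#'   (integer-valued matrix) and `population` (factor).
#' @seealso [read_genotypes()], [qc_filter_maf()], [impute_missing_to_mean()]
#' @export
genotype_matrix <- function(codes, population) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("S", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("M", seq_len(ncol(codes)))
  if (anyDuplicated(rownames(codes)))
    stop("duplicate sample ids in genotype matrix")
  if (anyDuplicated(colnames(codes)))
    stop("duplicate marker ids in genotype matrix")
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; first offending value: ",
         codes[which(bad)[1]])
  if (length(population) != nrow(codes))
    stop("population labels must match the number of samples")
  population <- factor(population)
  if (any(table(population) == 0))
    stop("every population label must name a nonempty sample subset")
  structure(list(codes = codes, population = population),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers, %d population(s)\n",
              nrow(x$codes), ncol(x$codes), nlevels(x$population)))
  tab <- table(x$population)
  cat("  samples per population:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$codes))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Number of samples and markers
#' @param g a `genotype_matrix`
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$codes)

#' @rdname n_samples
#' @export
n_markers <- function(g) ncol(g$codes)

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`
#' @param samples,markers index vectors (integer, logical or names); `NULL`
#'   keeps everything.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  codes <- g$codes
  population <- g$population
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(codes))
    codes <- codes[samples, , drop = FALSE]
    population <- droplevels(g$population[samples])
  }
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, colnames(codes))
    codes <- codes[, markers, drop = FALSE]
  }
  genotype_matrix(codes, population)
}

#' Read genotypes from a delimited file
#'
#' Two dialects are supported.  `"tsv"` is the package's native format: a
#' header row of marker ids, then one row per sample holding the sample id,
#' the population label and the genotype codes (`NA` for missing).
#' `"plink_raw"` is the additive-recode export of PLINK (`--recode A`): six
#' leading columns `FID IID PAT MAT SEX PHENOTYPE` followed by allele counts,
#' `NA` for missing.  RAW files carry no population column, so labels are
#' taken from `populations` when given (a vector named by sample id) and from
#' the family id (`FID`) otherwise.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"plink_raw"`.
#' @param populations optional named vector mapping sample ids to population
#'   labels (used by the `plink_raw` dialect).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw"),
                           populations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             na.strings = "NA")
    if (ncol(tab) < 3 ||
        !identical(tolower(names(tab)[1:2]), c("sample_id", "population")))
      stop("malformed genotype TSV header: expected sample_id, population, ",
           "then marker columns")
    codes <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(codes) <- as.character(tab[[1]])
    genotype_matrix(codes, tab[[2]])
  } else {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE, na.strings = "NA")
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(tab) < 7 || !identical(toupper(names(tab)[1:6]), lead))
      stop("malformed PLINK RAW header: expected ", paste(lead, collapse = " "))
    codes <- as.matrix(tab[, -(1:6), drop = FALSE])
    # strip the _A allele suffix PLINK appends to marker names
    colnames(codes) <- sub("_[ACGT0-9]+$", "", colnames(codes))
    ids <- as.character(tab$IID)
    rownames(codes) <- ids
    pop <- if (is.null(populations)) as.character(tab$FID)
           else {
             if (is.null(names(populations)))
               stop("`populations` must be named by sample id")
             unname(populations[ids])
           }
    if (anyNA(pop)) stop("population label missing for some samples")
    genotype_matrix(codes, pop)
  }
}

#' Write genotypes to the native TSV dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  tab <- data.frame(sample_id = rownames(g$codes),
                    population = as.character(g$population),
                    g$codes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read or write a phenotype table
#'
#' The phenotype table is a TSV with columns `sample_id`, `population`,
#' `value`; one record per sample, finite trait values.
#'
#' @param path file to read or write.
#' @return `read_phenotypes` returns a data.frame with those three columns.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "value")
  if (!all(need %in% names(tab)))
    stop("phenotype table must have columns ", paste(need, collapse = ", "))
  tab <- tab[, need]
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in phenotypes")
  if (any(!is.finite(tab$value))) stop("phenotype values must be finite")
  tab
}

#' @rdname read_phenotypes
#' @param pheno data.frame with columns `sample_id`, `population`, `value`.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno[, c("sample_id", "population", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker map
#'
#' @param path TSV with columns `marker_id`, `chrom`, `pos` (base pairs).
#' @return data.frame with one row per marker, non-negative positions.
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("marker map must have columns ", paste(need, collapse = ", "))
  tab <- tab[, need]
  if (anyDuplicated(tab$marker_id)) stop("duplicate marker ids in map")
  if (any(tab$pos < 0)) stop("positions must be non-negative")
  tab
}

#' Replace missing genotypes by within-population marker means
#'
#' The Gibbs samplers require a complete design matrix.  Each missing cell is
#' replaced by the mean non-missing code of that marker within the sample's
#' own population, leaving a real-valued matrix that is used for model fitting
#' only (it is never written back as integer codes).
#'
#' @param g a [genotype_matrix()].
#' @return A numeric matrix (samples x markers) with a `population` attribute
#'   carrying the factor of per-sample labels.
#' @export
impute_missing_to_mean <- function(g) {
  codes <- g$codes
  for (lev in levels(g$population)) {
    rows <- g$population == lev
    block <- codes[rows, , drop = FALSE]
    nmiss <- colSums(is.na(block))
    if (any(nmiss == nrow(block)))
      stop("marker(s) entirely missing within population ", lev, ": ",
           paste(colnames(block)[nmiss == nrow(block)], collapse = ", "))
    if (any(nmiss > 0)) {
      mns <- colMeans(block, na.rm = TRUE)
      idx <- which(is.na(block), arr.ind = TRUE)
      block[idx] <- mns[idx[, 2]]
      codes[rows, ] <- block
    }
  }
  attr(codes, "population") <- g$population
  codes
}

#' Split a genotype matrix by population
#'
#' @param g a [genotype_matrix()].
#' @return Named list of single-population `genotype_matrix` objects, in
#'   population-level order.
#' @export
split_by_population <- function(g) {
  out <- lapply(levels(g$population), function(lev)
    subset_genotypes(g, samples = which(g$population == lev)))
  names(out) <- levels(g$population)
  out
}
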