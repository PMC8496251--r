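# Shared data containers for the pipeline: genotype dosages, marker map,
# phenotypes, covariates.  All are thin, validated wrappers over base
# matrices / data frames so that downstream linear algebra stays plain.

#' Construct a genotype dosage matrix
#'
#' Dosages are expected alternate-allele fractions in \[0, 1\]:
#' 0 = homozygous reference, 0.5 = heterozygous, 1 = homozygous alternate.
#' Multi-founder populations are encoded as alternate-allele dosage at
#' biallelic markers.  Missing values are allowed on input and must be
#' resolved with [impute_missing_genotypes()] before kinship or scan
#' computations.
#'
#' @param values numeric matrix, individuals in rows, markers in columns.
#' @param individual_ids,marker_ids unique character ids; default taken from
#'   `dimnames(values)`.
#' @return A `genotype_matrix`: a numeric matrix with unique row and column
#'   names and class attribute.
#' @export
genotype_matrix <- function(values, individual_ids = rownames(values),
                            marker_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("genotype values must be numeric")
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(values)))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids")
  if (anyDuplicated(marker_ids)) stop("duplicated marker ids")
  if (length(individual_ids) != nrow(values) || length(marker_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  rng <- range(values, na.rm = TRUE)
  if (any(is.infinite(values))) stop("genotype dosages must be finite or NA")
  if (rng[1] < 0 || rng[2] > 1)
    stop("genotype dosages must lie in [0, 1]")
  dimnames(values) <- list(individual_ids, marker_ids)
  class(values) <- c("genotype_matrix", class(matrix()))
  values
}

#' Construct a marker map
#'
#' @param marker character marker ids, unique.
#' @param chromosome chromosome labels (autosome names and "X" allowed).
#' @param position_cM nonnegative centimorgan positions, nondecreasing within
#'   each chromosome.
#' @return A `marker_map` data frame with columns `marker`, `chromosome`,
#'   `position_cM`.
#' @export
marker_map <- function(marker, chromosome, position_cM) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  if (anyDuplicated(marker)) stop("duplicated marker ids in map")
  if (any(!is.finite(position_cM)) || any(position_cM < 0))
    stop("positions must be finite and nonnegative")
  for (ch in unique(chromosome)) {
    p <- position_cM[chromosome == ch]
    if (is.unsorted(p)) stop("positions must be nondecreasing within chromosome ", ch)
  }
  out <- data.frame(marker = marker, chromosome = chromosome,
                    position_cM = position_cM, stringsAsFactors = FALSE)
  class(out) <- c("marker_map", "data.frame")
  out
}

#' Construct a phenotype table
#'
#' Missing values are allowed and flagged; individuals with a missing
#' phenotype are dropped per-analysis downstream (not imputed).
#'
#' @param values numeric matrix, individuals in rows, traits in columns.
#' @param trait_names unique trait names (default column names).
#' @param individual_ids row ids.
#' @return A `phenotype_table` numeric matrix; attribute `has_missing` flags
#'   whether any value is NA.
#' @export
phenotype_table <- function(values, trait_names = colnames(values),
                            individual_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("phenotype values must be numeric")
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(values)))
  if (anyDuplicated(trait_names)) stop("duplicated trait names")
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(nrow(values)))
  dimnames(values) <- list(as.character(individual_ids), as.character(trait_names))
  attr(values, "has_missing") <- anyNA(values)
  class(values) <- c("phenotype_table", class(matrix()))
  values
}

#' Construct a covariate table
#'
#' Covariates (e.g. sex, cross direction `pgm`) enter every scan model.  No
#' missing values are allowed, and the columns must be of full rank jointly
#' with an intercept.
#'
#' @param values numeric matrix, individuals in rows.
#' @param names covariate names.
#' @param individual_ids row ids.
#' @return A `covariate_table` numeric matrix.
#' @export
covariate_table <- function(values, names = colnames(values),
                            individual_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("covariate values must be numeric")
  if (anyNA(values)) stop("covariates must not contain missing values")
  if (is.null(names)) names <- paste0("cov", seq_len(ncol(values)))
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(nrow(values)))
  dimnames(values) <- list(as.character(individual_ids), as.character(names))
  if (qr(cbind(1, values))$rank < ncol(values) + 1L)
    stop("covariates are collinear with the intercept or each other")
  class(values) <- c("covariate_table", class(matrix()))
  values
}

#' Mean-impute missing genotype dosages
#'
#' Each missing entry is replaced by the observed mean dosage of its marker.
#' Markers with no observed values are dropped with a warning.
#'
#' @param genotypes a [genotype_matrix()].
#' @return A `genotype_matrix` with no missing values; attribute
#'   `n_imputed` counts the filled entries.
#' @export
impute_missing_genotypes <- function(genotypes) {
  g <- unclass(genotypes)
  all_missing <- colSums(!is.na(g)) == 0L
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " all-missing marker(s): ",
            paste(colnames(g)[all_missing], collapse = ", "))
    g <- g[, !all_missing, drop = FALSE]
  }
  n_imp <- sum(is.na(g))
  if (n_imp > 0L) {
    means <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- means[idx[, 2L]]
  }
  out <- genotype_matrix(g)
  attr(out, "n_imputed") <- n_imp
  out
}
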