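# Realized-genotype kinship: K = G %*% t(G) / n over the marker set, with
# leave-one-chromosome-out (LOCO) and leave-two-chromosomes-out (LTCO)
# variants for scans.

new_kinship <- function(K, kind, omitted, n_used, denominator) {
  K <- (K + t(K)) / 2  # remove floating-point asymmetry
  structure(K, kind = kind, omitted_chromosomes = omitted,
            n_markers_used = n_used, denominator = denominator,
            class = c("kinship_matrix", class(matrix())))
}

kinship_denom <- function(n_used, n_total, denominator) {
  switch(denominator, used = n_used, total = n_total,
         stop("denominator must be 'used' or 'total'"))
}

#' Overall kinship matrix
#'
#' Computes `K = G %*% t(G) / n` from the dosage matrix, with `n` the number
#' of markers.  Dosages are used as-is (no centering or standardization), so
#' the result is guaranteed positive semidefinite.
#'
#' @param genotypes a [genotype_matrix()] with no missing values.
#' @param denominator `"used"` divides by the number of markers in the
#'   matrix; `"total"` is identical here but distinguishes the reduced
#'   variants (see [loco_kinship()]).
#' @return A `kinship_matrix` with attributes `kind`, `omitted_chromosomes`,
#'   `n_markers_used`.
#' @export
overall_kinship <- function(genotypes, denominator = c("used", "total")) {
  denominator <- match.arg(denominator)
  G <- unclass(genotypes)
  if (anyNA(G)) stop("genotypes contain missing values; impute first")
  if (ncol(G) == 0L) stop("no markers: kinship undefined")
  K <- tcrossprod(G) / kinship_denom(ncol(G), ncol(G), denominator)
  new_kinship(K, "overall", character(0), ncol(G), denominator)
}

markers_on <- function(map, genotypes, chromosomes) {
  if (!identical(map$marker, colnames(genotypes)))
    stop("marker map does not match genotype columns")
  map$chromosome %in% chromosomes
}

#' Leave-one-chromosome-out kinship
#'
#' Kinship computed with all markers on the given chromosome removed.  By
#' default the denominator is the number of markers actually used;
#' `denominator = "total"` divides by the full marker count instead
#' (the literal reduced-matrix formula, which shrinks the reduced matrices).
#'
#' @inheritParams overall_kinship
#' @param map a [marker_map()] aligned with the genotype columns.
#' @param chromosome chromosome label to omit.
#' @return A `kinship_matrix` with `kind = "loco"`.
#' @export
loco_kinship <- function(genotypes, map, chromosome,
                         denominator = c("used", "total")) {
  denominator <- match.arg(denominator)
  G <- unclass(genotypes)
  if (anyNA(G)) stop("genotypes contain missing values; impute first")
  drop <- markers_on(map, G, chromosome)
  if (all(drop)) stop("removing chromosome ", chromosome,
                      " leaves no markers for the kinship matrix")
  Gk <- G[, !drop, drop = FALSE]
  K <- tcrossprod(Gk) / kinship_denom(ncol(Gk), ncol(G), denominator)
  new_kinship(K, "loco", as.character(chromosome), ncol(Gk), denominator)
}

#' Leave-two-chromosomes-out kinship
#'
#' Kinship with the markers of both tested chromosomes removed, for pairwise
#' scans.  When both markers are on the same chromosome only that one
#' chromosome is left out: the result is then the [loco_kinship()] object
#' itself, bit-identical.
#'
#' @inheritParams loco_kinship
#' @param chrom_a,chrom_b chromosome labels of the two tested markers.
#' @return A `kinship_matrix` with `kind = "ltco"` (or `"loco"` when
#'   `chrom_a == chrom_b`).
#' @export
ltco_kinship <- function(genotypes, map, chrom_a, chrom_b,
                         denominator = c("used", "total")) {
  denominator <- match.arg(denominator)
  if (chrom_a == chrom_b)
    return(loco_kinship(genotypes, map, chrom_a, denominator))
  G <- unclass(genotypes)
  if (anyNA(G)) stop("genotypes contain missing values; impute first")
  drop <- markers_on(map, G, c(chrom_a, chrom_b))
  if (all(drop)) stop("removing chromosomes ", chrom_a, " and ", chrom_b,
                      " leaves no markers for the kinship matrix")
  Gk <- G[, !drop, drop = FALSE]
  K <- tcrossprod(Gk) / kinship_denom(ncol(Gk), ncol(G), denominator)
  new_kinship(K, "ltco", as.character(c(chrom_a, chrom_b)), ncol(Gk), denominator)
}
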