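# Delimited-text IO for population bundles.  All files are comma-delimited
# with a header row; the first column of genotype/phenotype/covariate files
# is the individual id; matrices are individuals-as-rows everywhere.

read_id_table <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop(what, " file must have an id column plus data columns")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated individual ids in ", what, " file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- d[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "")
      if (length(bad))
        stop("non-numeric value in ", what, " file at row ", bad[1L],
             ", column '", names(vals)[j], "': '", col[bad[1L]], "'")
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Read an aligned population bundle from delimited files
#'
#' Reads genotype dosages, marker map, phenotypes and (optionally)
#' covariates, and aligns all individual-level tables on the intersection of
#' individual ids, preserving the order of the genotype file.  Dropped ids
#' are reported with a warning and returned in the result.
#'
#' @param genotype_path,map_path,phenotype_path,covariate_path file paths;
#'   `covariate_path` may be `NULL`.
#' @return A list with elements `genotypes` ([genotype_matrix()]),
#'   `map` ([marker_map()]), `phenotypes` ([phenotype_table()]),
#'   `covariates` ([covariate_table()] or `NULL`) and `dropped_ids`.
#' @export
read_population_bundle <- function(genotype_path, map_path, phenotype_path,
                                   covariate_path = NULL) {
  g <- read_id_table(genotype_path, "genotype")
  p <- read_id_table(phenotype_path, "phenotype")
  cv <- if (!is.null(covariate_path)) read_id_table(covariate_path, "covariate")

  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  md <- read.csv(map_path, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(md)))
    stop("map file must have columns marker, chromosome, position_cM")
  map <- marker_map(md$marker, md$chromosome, md$position_cM)
  if (!identical(map$marker, colnames(g)))
    stop("map markers do not match genotype columns (same set and order required)")

  keep <- rownames(g)
  keep <- keep[keep %in% rownames(p)]
  if (!is.null(cv)) keep <- keep[keep %in% rownames(cv)]
  if (length(keep) == 0L)
    stop("no individual ids shared across genotype/phenotype/covariate files")
  all_ids <- unique(c(rownames(g), rownames(p), if (!is.null(cv)) rownames(cv)))
  dropped <- setdiff(all_ids, keep)
  if (length(dropped))
    warning("dropped ", length(dropped), " individual(s) absent from some file: ",
            paste(dropped, collapse = ", "))

  list(genotypes  = genotype_matrix(g[keep, , drop = FALSE]),
       map        = map,
       phenotypes = phenotype_table(p[keep, , drop = FALSE]),
       covariates = if (!is.null(cv)) covariate_table(cv[keep, , drop = FALSE]),
       dropped_ids = dropped)
}

write_id_table <- function(m, path) {
  d <- data.frame(id = rownames(m),
                  as.data.frame(unclass(m), check.names = FALSE),
                  check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Write a population bundle as delimited files
#'
#' Inverse of [read_population_bundle()]; round-trips are lossless to at
#' least 12 significant digits.
#'
#' @param bundle list with `genotypes`, `map`, `phenotypes`, optionally
#'   `covariates`.
#' @param prefix path prefix; files are written as `<prefix>_geno.csv`,
#'   `<prefix>_map.csv`, `<prefix>_pheno.csv`, `<prefix>_covar.csv`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_population_bundle <- function(bundle, prefix) {
  paths <- c(genotype  = paste0(prefix, "_geno.csv"),
             map       = paste0(prefix, "_map.csv"),
             phenotype = paste0(prefix, "_pheno.csv"))
  write_id_table(bundle$genotypes, paths[["genotype"]])
  write.csv(as.data.frame(unclass(bundle$map)), paths[["map"]],
            row.names = FALSE, quote = FALSE)
  write_id_table(bundle$phenotypes, paths[["phenotype"]])
  if (!is.null(bundle$covariates)) {
    paths[["covariate"]] <- paste0(prefix, "_covar.csv")
    write_id_table(bundle$covariates, paths[["covariate"]])
  }
  invisible(paths)
}
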