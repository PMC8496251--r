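# Population-structure diagnostics: community detection on the kinship
# network, FST from heterozygosity, trait correlation with the leading
# kinship principal component, and within-chromosome LD.

#' Convert a kinship matrix to a weighted undirected graph
#'
#' Nodes are individuals; edge weights are off-diagonal kinship values.
#' Self-relatedness (the diagonal) is removed, negative values are clipped
#' to 0, and zero-weight edges are dropped.
#'
#' @param kinship a symmetric `kinship_matrix` (or plain symmetric matrix).
#' @return An `igraph` weighted undirected graph.
#' @export
kinship_to_network <- function(kinship) {
  W <- unclass(kinship)
  if (max(abs(W - t(W))) > 1e-8) stop("kinship matrix is not symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W[W < 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(nrow(W))))
  g
}

#' Detect subpopulations by fast-greedy modularity clustering
#'
#' @param graph a weighted undirected graph from [kinship_to_network()].
#' @return A `subpopulation_assignment` list: `membership` (named integer
#'   labels), `n_communities`, `modularity`, and `degenerate` (TRUE when the
#'   graph is edgeless and every node is its own community).
#' @export
detect_subpopulations <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  if (igraph::ecount(graph) == 0L) {
    memb <- seq_len(igraph::vcount(graph))
    names(memb) <- igraph::V(graph)$name
    warning("edgeless kinship network: every individual is its own community")
    return(structure(list(membership = memb, n_communities = length(memb),
                          modularity = NA_real_, degenerate = TRUE),
                     class = "subpopulation_assignment"))
  }
  cl <- igraph::cluster_fast_greedy(graph, weights = igraph::E(graph)$weight)
  memb <- igraph::membership(cl)
  structure(list(membership = memb,
                 n_communities = length(unique(memb)),
                 modularity = max(cl$modularity),
                 degenerate = FALSE),
            class = "subpopulation_assignment")
}

expected_het <- function(p) 2 * p * (1 - p)

#' Fixation index from heterozygosity
#'
#' `FST = (pi_T - pi_S) / pi_T`, where `pi_T` is the summed expected
#' heterozygosity over loci using pooled allele frequencies and `pi_S` is
#' the average (size-weighted by default) of the per-subpopulation summed
#' heterozygosities.  Allele frequencies are estimated as mean dosage.
#'
#' @param genotypes a [genotype_matrix()] with no missing values.
#' @param assignment a `subpopulation_assignment` (or a vector of labels
#'   aligned with the genotype rows).
#' @param weighting `"size"` weights subpopulation heterozygosities by
#'   subpopulation size; `"equal"` averages them unweighted.
#' @param heterozygosity `"expected"` uses `2p(1-p)`; `"observed"` uses the
#'   fraction of heterozygous calls (dosage strictly between 0 and 1), which
#'   degenerates in inbred panels.
#' @return A `structure_metrics` list with `fst`, `pi_total`, `pi_sub_mean`,
#'   `n_communities`, `clipped` (TRUE when a negative ratio was clipped to
#'   0), `undefined` (TRUE when `pi_total` is 0).
#' @export
fst <- function(genotypes, assignment, weighting = c("size", "equal"),
                heterozygosity = c("expected", "observed")) {
  weighting <- match.arg(weighting)
  heterozygosity <- match.arg(heterozygosity)
  G <- unclass(genotypes)
  if (anyNA(G)) stop("genotypes contain missing values; impute first")
  labels <- if (inherits(assignment, "subpopulation_assignment"))
    assignment$membership else assignment
  if (length(labels) != nrow(G)) stop("assignment does not match individuals")

  het_sum <- function(M) {
    if (heterozygosity == "expected") sum(expected_het(colMeans(M)))
    else sum(colMeans(M > 1e-8 & M < 1 - 1e-8))
  }
  pi_total <- het_sum(G)
  f <- factor(labels)
  pis <- vapply(levels(f), function(l) het_sum(G[f == l, , drop = FALSE]), numeric(1))
  sizes <- as.numeric(table(f))
  pi_sub <- if (weighting == "size") sum(pis * sizes) / sum(sizes) else mean(pis)

  undefined <- pi_total <= 0
  val <- if (undefined) NA_real_ else (pi_total - pi_sub) / pi_total
  clipped <- isTRUE(val < 0)
  if (clipped) val <- 0
  if (undefined) warning("monomorphic genotypes: FST undefined")
  structure(list(fst = val, pi_total = pi_total, pi_sub_mean = pi_sub,
                 n_communities = nlevels(f), clipped = clipped,
                 undefined = undefined),
            class = "structure_metrics")
}

#' Leading kinship principal component and its trait correlations
#'
#' PC1 is the leading eigenvector of the double-centered kinship matrix; its
#' sign is fixed by making the largest-magnitude loading positive.  Used to
#' screen traits whose correlation with population structure is low.
#'
#' @param kinship a `kinship_matrix`.
#' @param phenotypes a [phenotype_table()] (rows aligned with kinship).
#' @return A list with `pc1` (named vector) and `correlations` (per-trait
#'   Pearson r; `NA` for constant traits, with a warning).
#' @export
trait_kinship_pc1_correlation <- function(kinship, phenotypes) {
  if (is.null(phenotypes)) stop("phenotypes required")
  K <- unclass(kinship)
  n <- nrow(K)
  if (n < 3L) stop("need at least 3 individuals")
  Kc <- scale(K, center = TRUE, scale = FALSE)
  Kc <- t(scale(t(Kc), center = TRUE, scale = FALSE))
  pc1 <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)$vectors[, 1L]
  if (pc1[which.max(abs(pc1))] < 0) pc1 <- -pc1
  names(pc1) <- rownames(K)
  Y <- unclass(phenotypes)
  r <- vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]; ok <- !is.na(y)
    if (sd(y[ok]) == 0) return(NA_real_)
    cor(pc1[ok], y[ok])
  }, numeric(1))
  names(r) <- colnames(Y)
  if (anyNA(r)) warning("constant trait(s): correlation undefined for ",
                        paste(names(r)[is.na(r)], collapse = ", "))
  list(pc1 = pc1, correlations = r)
}

#' Within-chromosome linkage disequilibrium summary
#'
#' Pools Pearson correlations between all pairs of markers on the same
#' chromosome, across chromosomes: a stand-in for LD.
#'
#' @param genotypes a [genotype_matrix()].
#' @param map a [marker_map()] aligned with the genotype columns.
#' @param probs quantiles reported in the summary.
#' @return A list with `r` (pooled pairwise correlations), `quantiles`,
#'   `mean_abs_r`, `n_pairs`, `n_skipped` (pairs skipped because a marker
#'   was monomorphic).
#' @export
ld_summary <- function(genotypes, map,
                       probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  G <- unclass(genotypes)
  if (!identical(map$marker, colnames(G)))
    stop("marker map does not match genotype columns")
  rs <- list(); skipped <- 0L
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    if (length(idx) < 2L) next
    sub <- G[, idx, drop = FALSE]
    poly <- apply(sub, 2L, sd) > 0
    n_mono <- sum(!poly)
    skipped <- skipped + n_mono * (length(idx) - 1L) - choose(n_mono, 2L)
    sub <- sub[, poly, drop = FALSE]
    if (ncol(sub) < 2L) next
    cm <- cor(sub)
    rs[[ch]] <- cm[upper.tri(cm)]
  }
  r <- unlist(rs, use.names = FALSE)
  if (is.null(r)) stop("no chromosome has 2 or more markers")
  list(r = r, quantiles = quantile(r, probs), mean_abs_r = mean(abs(r)),
       n_pairs = length(r), n_skipped = as.integer(skipped))
}
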