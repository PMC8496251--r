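test_that("kinship networks map weights and drop diagonal / negative edges", {
  K <- matrix(0.5, 3, 3); diag(K) <- 1
  g <- kinship_to_network(K)
  expect_equal(igraph::ecount(g), 3)
  expect_true(all(igraph::E(g)$weight == 0.5))

  g0 <- kinship_to_network(diag(4))
  expect_equal(igraph::ecount(g0), 0)

  K5 <- matrix(0.2, 5, 5); diag(K5) <- 1
  K5[1, 2] <- K5[2, 1] <- -0.1
  g5 <- kinship_to_network(K5)
  expect_equal(igraph::ecount(g5), choose(5, 2) - 1L)
  expect_false(igraph::are_adjacent(g5, 1, 2))
})

test_that("fast-greedy clustering recovers planted communities", {
  # two 5-cliques joined by one weak edge
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 0.1
  comm <- detect_subpopulations(kinship_to_network(A))
  expect_equal(comm$n_communities, 2)
  expect_equal(length(unique(comm$membership[1:5])), 1)
  expect_equal(length(unique(comm$membership[6:10])), 1)

  # complete uniform graph: no structure to find (modularity stays at zero;
  # the partition it returns is degenerate)
  Au <- matrix(1, 6, 6); diag(Au) <- 0
  cu <- detect_subpopulations(kinship_to_network(Au))
  expect_lt(abs(cu$modularity), 1e-8)
  expect_lte(cu$n_communities, 2)

  # edgeless graph: every node its own community, flagged
  expect_warning(ce <- detect_subpopulations(kinship_to_network(diag(4))),
                 "edgeless")
  expect_true(ce$degenerate)
  expect_equal(ce$n_communities, 4)
})

test_that("greedy communities match exhaustive modularity maximization on a planted toy", {
  # 9 nodes, 3 planted blocks; exhaustive search over all <=3-label partitions
  set.seed(31)
  A <- matrix(0.05, 9, 9)
  for (b in list(1:3, 4:6, 7:9)) A[b, b] <- 1
  diag(A) <- 0
  g <- kinship_to_network(A)
  comm <- detect_subpopulations(g)

  modularity_of <- function(memb) igraph::modularity(g, memb,
                                                     weights = igraph::E(g)$weight)
  best <- -Inf; best_m <- NULL
  grid <- expand.grid(rep(list(1:3), 9))
  for (r in seq_len(nrow(grid))) {
    m <- as.integer(grid[r, ])
    q <- modularity_of(m)
    if (q > best + 1e-12) { best <- q; best_m <- m }
  }
  expect_equal(comm$modularity, best, tolerance = 1e-8)
  expect_equal(length(unique(paste(comm$membership, best_m))), 3)  # same partition
})

test_that("FST follows the heterozygosity formula", {
  # hand case: two equal communities, one locus, p = 0.2 and 0.8
  G <- matrix(c(rep(0.2, 5), rep(0.8, 5)), ncol = 1)
  s <- fst(genotype_matrix(G), rep(c("a", "b"), each = 5))
  expect_equal(s$pi_total, 0.5, tolerance = 1e-12)
  expect_equal(s$pi_sub_mean, 0.32, tolerance = 1e-12)
  expect_equal(s$fst, 0.36, tolerance = 1e-12)

  # one community, or identical frequencies -> 0
  expect_equal(fst(genotype_matrix(G), rep("a", 10))$fst, 0)
  G2 <- rbind(G, G)
  expect_equal(fst(genotype_matrix(G2), rep(c("a", "b"), each = 10))$fst, 0,
               tolerance = 1e-12)

  # opposite fixation at every locus -> 1
  G3 <- matrix(c(rep(0, 4), rep(1, 4), rep(1, 4), rep(0, 4)), ncol = 2)
  expect_equal(fst(genotype_matrix(G3), rep(c("a", "b"), each = 4))$fst, 1)

  # invariance to relabeling and row order
  set.seed(32)
  G4 <- matrix(runif(40), 10, 4)
  lab <- rep(c("x", "y"), 5)
  f1 <- fst(genotype_matrix(G4), lab)$fst
  f2 <- fst(genotype_matrix(G4), c(y = "q", x = "r")[lab])$fst
  ord <- sample(10)
  f3 <- fst(genotype_matrix(G4[ord, ]), lab[ord])$fst
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(f1, f3, tolerance = 1e-12)

  expect_warning(fm <- fst(genotype_matrix(matrix(1, 4, 2)), rep("a", 4)),
                 "monomorphic")
  expect_true(fm$undefined)
})

test_that("replicated RIL panels are more structured than replicate-averaged ones", {
  ril <- small_ril()
  avg <- average_replicates(ril)
  f_rep <- {
    K <- overall_kinship(ril$genotypes)
    fst(ril$genotypes, detect_subpopulations(kinship_to_network(K)))$fst
  }
  f_avg <- {
    K <- overall_kinship(avg$genotypes)
    fst(avg$genotypes, detect_subpopulations(kinship_to_network(K)))$fst
  }
  expect_gt(f_rep, f_avg)
})

test_that("trait correlation with kinship PC1 matches a direct eigen oracle", {
  set.seed(33)
  G <- matrix(runif(8 * 12), 8, 12)
  K <- overall_kinship(genotype_matrix(G))
  # oracle: double-center, leading eigenvector, sign fixed
  Kc <- unclass(K)
  Kc <- Kc - outer(rowMeans(Kc), rep(1, 8)) - outer(rep(1, 8), colMeans(Kc)) +
    mean(Kc)
  pc <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)$vectors[, 1]
  if (pc[which.max(abs(pc))] < 0) pc <- -pc

  y <- cbind(t1 = pc,                             # r = 1
             t2 = pc - 2 * pc,                    # r = -1
             t3 = rnorm(8))
  res <- trait_kinship_pc1_correlation(K, phenotype_table(y))
  expect_equal(unname(res$pc1), pc, tolerance = 1e-8)
  expect_equal(unname(res$correlations["t1"]), 1, tolerance = 1e-8)
  expect_equal(unname(res$correlations["t2"]), -1, tolerance = 1e-8)
  expect_equal(unname(res$correlations["t3"]), cor(pc, y[, 3]), tolerance = 1e-8)

  # orthogonal trait: r = 0 within 1e-10
  yo <- residuals(lm(rnorm(8) ~ pc))
  ro <- trait_kinship_pc1_correlation(K, phenotype_table(cbind(o = yo)))
  expect_lt(abs(ro$correlations[["o"]]), 1e-10)

  expect_warning(rc <- trait_kinship_pc1_correlation(
    K, phenotype_table(cbind(const = rep(1, 8)))), "constant")
  expect_true(is.na(rc$correlations[["const"]]))
})

test_that("LD summaries pool within-chromosome correlations and order populations", {
  # duplicated marker columns give r = 1
  G <- matrix(runif(40), 10, 4)
  G[, 2] <- G[, 1]
  mp <- marker_map(paste0("m", 1:4), rep("1", 4), 0:3)
  colnames(G) <- mp$marker
  ld <- ld_summary(genotype_matrix(G), mp)
  expect_equal(max(ld$r), 1, tolerance = 1e-12)

  # independent markers: mean r ~ 0 within 3 SE
  set.seed(34)
  Gi <- matrix(rbinom(1000 * 10, 2, 0.5) / 2, 1000, 10)
  mpi <- marker_map(paste0("m", 1:10), rep("1", 10), 0:9)
  colnames(Gi) <- mpi$marker
  ldi <- ld_summary(genotype_matrix(Gi), mpi)
  expect_lt(abs(mean(ldi$r)), 3 / sqrt(1000))

  # F2 has higher within-chromosome LD than AIL at generation 50
  ms <- genetic_map_spec(c("1", "2"), c(100, 100), c(15, 15))
  f2 <- simulate_population(breeding_design("F2", n_individuals = 150), ms,
                            seed = 35)
  ail <- simulate_population(breeding_design("AIL", n_individuals = 150,
                                             n_intercross_generations = 50),
                             ms, seed = 35)
  expect_gt(median(ld_summary(f2$genotypes, f2$map)$r),
            median(ld_summary(ail$genotypes, ail$map)$r))
})
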