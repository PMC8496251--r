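# Shared fixtures, built in code.

# deterministic toy bundle: 5 individuals x 4 markers on 2 chromosomes
toy_bundle <- function() {
  g <- matrix(c(0, 0.5, 1, 0.5,
                1, 0.5, 0, 0,
                0.5, 0.5, 0.5, 1,
                0, 0, 1, 1,
                1, 1, 0, 0.5), nrow = 5, byrow = TRUE)
  rownames(g) <- paste0("m", 1:5)
  colnames(g) <- paste0("mk", 1:4)
  list(genotypes = genotype_matrix(g),
       map = marker_map(paste0("mk", 1:4), c("1", "1", "2", "2"),
                        c(0, 10, 0, 25)),
       phenotypes = phenotype_table(
         matrix(c(1.2, -0.3, 0.8, 2.1, -1.4,
                  0.4, 0.9, -0.2, 1.1, 0.5), ncol = 2,
                dimnames = list(paste0("m", 1:5), c("tA", "tB")))),
       covariates = covariate_table(
         matrix(c(0, 1, 0, 1, 1), ncol = 1,
                dimnames = list(paste0("m", 1:5), "sex"))))
}

# cached simulated populations (built once per test run)
sim_cache <- new.env(parent = emptyenv())

cached_pop <- function(key, builder) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- builder()
  sim_cache[[key]]
}

small_f2 <- function() cached_pop("f2", function() {
  ms <- genetic_map_spec(c("1", "2"), c(100, 100), c(20, 20))
  simulate_population(breeding_design("F2", n_individuals = 300), ms, seed = 101)
})

small_ril <- function() cached_pop("ril", function() {
  ms <- genetic_map_spec(as.character(1:6), rep(80, 6), rep(8, 6))
  simulate_population(breeding_design("RIL", n_lines = 30,
                                      replicates_per_line = 4), ms, seed = 102)
})
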