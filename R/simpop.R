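# Breeding-scheme population simulator.  Genomes are tracked as pairs of
# founder-label haplotypes over a marker map; meiosis drops Poisson
# crossovers (no interference, Haldane map function) uniformly in cM.
# Dosages are alternate-allele fractions at biallelic markers.

#' Specify a genetic map with equally spaced markers
#'
#' @param labels chromosome labels.
#' @param lengths_cM chromosome lengths in centimorgans (> 0 unless a
#'   degenerate zero-length chromosome is wanted for testing).
#' @param n_markers markers per chromosome (>= 1), equally spaced from 0 to
#'   the chromosome length.
#' @return A `genetic_map_spec` list with the chromosome table and the
#'   realized [marker_map()].
#' @export
genetic_map_spec <- function(labels, lengths_cM, n_markers) {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(lengths_cM),
            length(labels) == length(n_markers))
  if (any(lengths_cM < 0)) stop("chromosome lengths must be >= 0")
  if (any(n_markers < 1)) stop("each chromosome needs at least one marker")
  pos <- mk <- chr <- list()
  for (i in seq_along(labels)) {
    k <- n_markers[i]
    pos[[i]] <- if (k == 1L) 0 else seq(0, lengths_cM[i], length.out = k)
    mk[[i]] <- paste0("c", labels[i], "_m", seq_len(k))
    chr[[i]] <- rep(labels[i], k)
  }
  map <- marker_map(unlist(mk), unlist(chr), unlist(pos))
  structure(list(chromosomes = data.frame(label = labels,
                                          length_cM = as.numeric(lengths_cM),
                                          n_markers = as.integer(n_markers),
                                          stringsAsFactors = FALSE),
                 map = map),
            class = "genetic_map_spec")
}

# Internal per-chromosome structure: marker indices, positions, length.
chr_struct <- function(map, lengths = NULL) {
  labs <- unique(map$chromosome)
  lapply(labs, function(ch) {
    idx <- which(map$chromosome == ch)
    len <- if (!is.null(lengths) && ch %in% names(lengths)) lengths[[ch]]
           else max(map$position_cM[idx])
    list(label = ch, idx = idx, pos = map$position_cM[idx], len = len)
  })
}

resolve_map <- function(map) {
  if (inherits(map, "genetic_map_spec")) {
    lens <- setNames(map$chromosomes$length_cM, map$chromosomes$label)
    list(map = map$map, chrs = chr_struct(map$map, lens))
  } else {
    list(map = map, chrs = chr_struct(map))
  }
}

meiosis_gamete <- function(h1, h2, chrs) {
  g <- h1
  for (ch in chrs) {
    n_co <- rpois(1L, ch$len / 100)
    start <- rbinom(1L, 1L, 0.5)
    seg <- if (n_co == 0L) integer(length(ch$pos))
           else findInterval(ch$pos, sort(runif(n_co, 0, ch$len)))
    pick <- (start + seg) %% 2L
    i <- ch$idx
    g[i] <- ifelse(pick == 0L, h1[i], h2[i])
  }
  g
}

#' Simulate one meiosis
#'
#' Crossover counts per chromosome are Poisson with mean length/100 (no
#' interference; Haldane map function), crossover positions uniform in cM,
#' and the starting parental haplotype is chosen by a fair coin.
#'
#' @param parent_haplotypes list of two founder-label vectors over the map's
#'   markers.
#' @param map a [genetic_map_spec()] or [marker_map()].
#' @return The gamete as a founder-label vector.
#' @export
simulate_meiosis <- function(parent_haplotypes, map) {
  rm <- resolve_map(map)
  stopifnot(length(parent_haplotypes) == 2L,
            length(parent_haplotypes[[1L]]) == nrow(rm$map),
            length(parent_haplotypes[[2L]]) == nrow(rm$map))
  meiosis_gamete(parent_haplotypes[[1L]], parent_haplotypes[[2L]], rm$chrs)
}

#' Describe a breeding design
#'
#' Schemes mirror the classic mouse-cross designs: two-generation intercross
#' (`F2`), F1-by-parent backcross (`backcross`), recombinant inbred lines
#' with genomic replicates (`RIL`) or averaged over replicates (`RIL_NR`),
#' advanced intercross at generation g (`AIL`), and an 8-founder outbred
#' stock (`outbred8`).
#'
#' @param scheme one of `"F2"`, `"backcross"`, `"RIL"`, `"RIL_NR"`, `"AIL"`,
#'   `"outbred8"`.
#' @param n_individuals number of individuals (ignored for RIL/RIL_NR where
#'   it is `n_lines * replicates_per_line` and `n_lines`).
#' @param n_intercross_generations total filial generations for AIL
#'   (default 50, the study population's generation) and random-mating
#'   generations after the funnel for outbred8 (default 10).
#' @param n_inbreeding_generations sib-mating generations for RIL (default 20).
#' @param n_lines,replicates_per_line RIL panel size and genomic replicates.
#' @param generations_sampled outbred8 only: draw individuals from this many
#'   final generations (emulating a cohort spanning multiple generations).
#' @return A `breeding_design` list.
#' @export
breeding_design <- function(scheme = c("F2", "backcross", "RIL", "RIL_NR",
                                       "AIL", "outbred8"),
                            n_individuals = NULL,
                            n_intercross_generations = NULL,
                            n_inbreeding_generations = 20L,
                            n_lines = NULL, replicates_per_line = 1L,
                            generations_sampled = 1L) {
  scheme <- match.arg(scheme)
  d <- list(scheme = scheme,
            n_founders = if (scheme == "outbred8") 8L else 2L,
            n_inbreeding_generations = as.integer(n_inbreeding_generations),
            generations_sampled = as.integer(generations_sampled))
  if (scheme %in% c("RIL", "RIL_NR")) {
    if (is.null(n_lines) || n_lines < 1L) stop("RIL design needs n_lines >= 1")
    if (replicates_per_line < 1L) stop("replicates_per_line must be >= 1")
    if (d$n_inbreeding_generations < 1L) stop("need >= 1 inbreeding generation")
    d$n_lines <- as.integer(n_lines)
    d$replicates_per_line <- if (scheme == "RIL") as.integer(replicates_per_line) else 1L
    d$n_individuals <- d$n_lines * d$replicates_per_line
  } else {
    if (is.null(n_individuals) || n_individuals < 1L)
      stop("design needs n_individuals >= 1")
    d$n_individuals <- as.integer(n_individuals)
  }
  if (scheme == "AIL") {
    d$n_intercross_generations <-
      as.integer(if (is.null(n_intercross_generations)) 50L else n_intercross_generations)
    if (d$n_intercross_generations < 2L) stop("AIL needs >= 2 generations")
  }
  if (scheme == "outbred8") {
    d$n_intercross_generations <-
      as.integer(if (is.null(n_intercross_generations)) 10L else n_intercross_generations)
    if (d$n_intercross_generations < 1L) stop("outbred8 needs >= 1 generation")
    if (d$generations_sampled < 1L || d$generations_sampled > d$n_intercross_generations)
      stop("generations_sampled must be in [1, n_intercross_generations]")
  }
  structure(d, class = "breeding_design")
}

# one round of random-pair mating within a pool of haplotype pairs
random_mate <- function(H1, H2, n_off, chrs) {
  np <- nrow(H1)
  O1 <- matrix(0L, n_off, ncol(H1))
  O2 <- matrix(0L, n_off, ncol(H1))
  for (i in seq_len(n_off)) {
    pr <- if (np >= 2L) sample.int(np, 2L) else c(1L, 1L)
    O1[i, ] <- meiosis_gamete(H1[pr[1L], ], H2[pr[1L], ], chrs)
    O2[i, ] <- meiosis_gamete(H1[pr[2L], ], H2[pr[2L], ], chrs)
  }
  list(H1 = O1, H2 = O2)
}

#' Simulate a population's genotypes under a breeding design
#'
#' @param design a [breeding_design()].
#' @param map a [genetic_map_spec()] or [marker_map()].
#' @param seed integer seed; the result is bit-identical given the seed.
#' @return A `sim_population` list: `genotypes` ([genotype_matrix()] of
#'   dosages), `map`, `line` (RIL line labels or `NULL`), `generation`
#'   (outbred8 generation labels or `NULL`), founder-label haplotype
#'   matrices `H1`/`H2`, `founder_alleles` (outbred8), `design`, `seed`.
#' @export
simulate_population <- function(design, map, seed = 1L) {
  stopifnot(inherits(design, "breeding_design"))
  set.seed(seed)
  rm <- resolve_map(map)
  chrs <- rm$chrs
  m <- nrow(rm$map)
  n <- design$n_individuals
  line <- NULL; generation <- NULL; founder_alleles <- NULL

  f1 <- list(h1 = rep(0L, m), h2 = rep(1L, m))  # two-founder F1

  if (design$scheme == "F2") {
    H1 <- t(vapply(seq_len(n), function(i) meiosis_gamete(f1$h1, f1$h2, chrs), integer(m)))
    H2 <- t(vapply(seq_len(n), function(i) meiosis_gamete(f1$h1, f1$h2, chrs), integer(m)))
  } else if (design$scheme == "backcross") {
    H1 <- t(vapply(seq_len(n), function(i) meiosis_gamete(f1$h1, f1$h2, chrs), integer(m)))
    H2 <- matrix(0L, n, m)  # backcrossed to founder 0
  } else if (design$scheme %in% c("RIL", "RIL_NR")) {
    nl <- design$n_lines; reps <- design$replicates_per_line
    k <- design$n_inbreeding_generations
    L1 <- matrix(0L, nl, m); L2 <- matrix(0L, nl, m)
    for (l in seq_len(nl)) {
      p1 <- f1; p2 <- f1
      for (g in seq_len(k)) {
        c1 <- list(h1 = meiosis_gamete(p1$h1, p1$h2, chrs),
                   h2 = meiosis_gamete(p2$h1, p2$h2, chrs))
        c2 <- list(h1 = meiosis_gamete(p1$h1, p1$h2, chrs),
                   h2 = meiosis_gamete(p2$h1, p2$h2, chrs))
        p1 <- c1; p2 <- c2
      }
      L1[l, ] <- meiosis_gamete(p1$h1, p1$h2, chrs)
      L2[l, ] <- meiosis_gamete(p2$h1, p2$h2, chrs)
    }
    rows <- rep(seq_len(nl), each = reps)
    H1 <- L1[rows, , drop = FALSE]; H2 <- L2[rows, , drop = FALSE]
    line <- paste0("line_", sprintf("%03d", rows))
    n <- nl * reps
  } else if (design$scheme == "AIL") {
    g_total <- design$n_intercross_generations
    # F2 pool (generation 2) from F1 parents, then random-pair mating
    P <- list(H1 = t(vapply(seq_len(n), function(i) meiosis_gamete(f1$h1, f1$h2, chrs), integer(m))),
              H2 = t(vapply(seq_len(n), function(i) meiosis_gamete(f1$h1, f1$h2, chrs), integer(m))))
    if (g_total > 2L) for (g in 3L:g_total) P <- random_mate(P$H1, P$H2, n, chrs)
    H1 <- P$H1; H2 <- P$H2
  } else { # outbred8
    founder_alleles <- matrix(rbinom(8L * m, 1L, 0.5), nrow = 8L)
    # round-robin funnel: (0x1)(2x3)(4x5)(6x7) -> two 4-way -> 8-way G0 pool
    pool_n <- max(n, 50L)
    G0_1 <- matrix(0L, pool_n, m); G0_2 <- matrix(0L, pool_n, m)
    for (i in seq_len(pool_n)) {
      g1 <- lapply(list(c(0L, 1L), c(2L, 3L), c(4L, 5L), c(6L, 7L)),
                   function(fp) list(h1 = rep(fp[1L], m), h2 = rep(fp[2L], m)))
      g2a <- list(h1 = meiosis_gamete(g1[[1L]]$h1, g1[[1L]]$h2, chrs),
                  h2 = meiosis_gamete(g1[[2L]]$h1, g1[[2L]]$h2, chrs))
      g2b <- list(h1 = meiosis_gamete(g1[[3L]]$h1, g1[[3L]]$h2, chrs),
                  h2 = meiosis_gamete(g1[[4L]]$h1, g1[[4L]]$h2, chrs))
      G0_1[i, ] <- meiosis_gamete(g2a$h1, g2a$h2, chrs)
      G0_2[i, ] <- meiosis_gamete(g2b$h1, g2b$h2, chrs)
    }
    P <- list(H1 = G0_1, H2 = G0_2)
    gens <- vector("list", design$n_intercross_generations)
    for (g in seq_len(design$n_intercross_generations)) {
      P <- random_mate(P$H1, P$H2, pool_n, chrs)
      gens[[g]] <- P
    }
    gs <- design$generations_sampled
    take_gens <- seq(design$n_intercross_generations - gs + 1L,
                     design$n_intercross_generations)
    per <- diff(round(seq(0, n, length.out = gs + 1L)))
    H1 <- matrix(0L, 0L, m); H2 <- matrix(0L, 0L, m); generation <- integer(0)
    for (k in seq_along(take_gens)) {
      if (per[k] == 0L) next
      rows <- sample.int(pool_n, per[k], replace = per[k] > pool_n)
      H1 <- rbind(H1, gens[[take_gens[k]]]$H1[rows, , drop = FALSE])
      H2 <- rbind(H2, gens[[take_gens[k]]]$H2[rows, , drop = FALSE])
      generation <- c(generation, rep(take_gens[k], per[k]))
    }
  }

  # founder labels -> alternate-allele dosage
  if (design$scheme == "outbred8") {
    a1 <- matrix(founder_alleles[cbind(as.vector(H1) + 1L,
                                       rep(seq_len(m), each = nrow(H1)))],
                 nrow(H1), m)
    a2 <- matrix(founder_alleles[cbind(as.vector(H2) + 1L,
                                       rep(seq_len(m), each = nrow(H2)))],
                 nrow(H2), m)
    dos <- (a1 + a2) / 2
  } else {
    dos <- (H1 + H2) / 2
  }
  ids <- paste0("ind_", sprintf("%04d", seq_len(nrow(dos))))
  geno <- genotype_matrix(dos, ids, rm$map$marker)

  pop <- structure(list(genotypes = geno, map = rm$map, line = line,
                        generation = generation, H1 = H1, H2 = H2,
                        founder_alleles = founder_alleles,
                        design = design, seed = seed),
                   class = "sim_population")
  if (design$scheme == "RIL_NR") pop <- average_replicates(pop)
  pop
}

#' Average a RIL population over genomic replicates
#'
#' Collapses individuals sharing a line label to a single row by averaging
#' genotype (and, when present, phenotype) rows, yielding the
#' no-replicates version of the panel.
#'
#' @param pop a `sim_population` with line labels.
#' @return A `sim_population` with one individual per line.
#' @export
average_replicates <- function(pop) {
  if (is.null(pop$line)) stop("population has no line labels to average over")
  f <- factor(pop$line, levels = unique(pop$line))
  g <- unclass(pop$genotypes)
  ag <- apply(g, 2L, function(col) tapply(col, f, mean))
  ag <- matrix(ag, nrow = nlevels(f), dimnames = list(levels(f), colnames(g)))
  pop$genotypes <- genotype_matrix(ag)
  if (!is.null(pop$phenotypes)) {
    ph <- unclass(pop$phenotypes)
    ap <- apply(ph, 2L, function(col) tapply(col, f, mean))
    ap <- matrix(ap, nrow = nlevels(f), dimnames = list(levels(f), colnames(ph)))
    pop$phenotypes <- phenotype_table(ap)
  }
  idx <- match(levels(f), pop$line)
  pop$H1 <- pop$H1[idx, , drop = FALSE]
  pop$H2 <- pop$H2[idx, , drop = FALSE]
  pop$line <- NULL
  pop
}

#' Specify a trait's genetic architecture
#'
#' @param additive_qtl data frame with columns `marker` (column index into
#'   the genotype matrix) and `effect`, or `NULL`.
#' @param epistatic_pairs data frame with columns `i`, `j`, `effect`
#'   (interaction coefficient on the dosage product), or `NULL`.
#' @param polygenic_variance variance of the polygenic term, drawn with
#'   covariance `polygenic_variance * K / mean(diag(K))` from the realized
#'   overall kinship `K` (so it equals the average per-individual polygenic
#'   variance).
#' @param line_variance variance of a strain-level random effect shared
#'   within RIL line.
#' @param residual_variance iid residual variance.
#' @param n_traits number of traits (>= 2 for the CAPE stage).
#' @param trait_scales per-trait scaling of the fixed genetic effects
#'   (additive + epistatic), giving partial pleiotropy across traits.
#' @return A `trait_model` list.
#' @export
trait_model <- function(additive_qtl = NULL, epistatic_pairs = NULL,
                        polygenic_variance = 0, line_variance = 0,
                        residual_variance = 1, n_traits = 2L,
                        trait_scales = rep(1, n_traits)) {
  stopifnot(polygenic_variance >= 0, line_variance >= 0, residual_variance >= 0,
            n_traits >= 1L, length(trait_scales) == n_traits)
  structure(list(additive_qtl = additive_qtl, epistatic_pairs = epistatic_pairs,
                 polygenic_variance = polygenic_variance,
                 line_variance = line_variance,
                 residual_variance = residual_variance,
                 n_traits = as.integer(n_traits), trait_scales = trait_scales),
            class = "trait_model")
}

#' Simulate traits on a simulated population
#'
#' Phenotypes are the sum of additive QTL effects, epistatic (dosage
#' product) effects, a polygenic term drawn from the realized overall
#' kinship, a line-level random effect (RIL), and iid residual noise.  All
#' random draws are stored in the truth record so variance components can be
#' verified empirically.
#'
#' @param pop a `sim_population`.
#' @param model a [trait_model()].
#' @param seed integer seed.
#' @return The population with `phenotypes` ([phenotype_table()]) and a
#'   `truth` record (model, per-component draws, realized h2 per trait).
#' @export
simulate_traits <- function(pop, model, seed = 1L) {
  stopifnot(inherits(pop, "sim_population"), inherits(model, "trait_model"))
  set.seed(seed)
  G <- unclass(pop$genotypes)
  n <- nrow(G); m <- ncol(G)

  fixed <- numeric(n)
  if (!is.null(model$additive_qtl)) {
    q <- model$additive_qtl
    if (any(q$marker < 1L | q$marker > m)) stop("additive QTL marker index out of range")
    for (r in seq_len(nrow(q))) fixed <- fixed + q$effect[r] * G[, q$marker[r]]
  }
  if (!is.null(model$epistatic_pairs)) {
    e <- model$epistatic_pairs
    if (any(c(e$i, e$j) < 1L | c(e$i, e$j) > m)) stop("epistatic marker index out of range")
    for (r in seq_len(nrow(e))) fixed <- fixed + e$effect[r] * G[, e$i[r]] * G[, e$j[r]]
  }

  nt <- model$n_traits
  poly <- matrix(0, n, nt)
  poly_var_expected <- 0
  if (model$polygenic_variance > 0) {
    K <- tcrossprod(G) / m
    K <- K / mean(diag(K))
    eg <- eigen(K, symmetric = TRUE)
    sq <- sqrt(pmax(eg$values, 0))
    for (j in seq_len(nt))
      poly[, j] <- sqrt(model$polygenic_variance) * (eg$vectors %*% (sq * rnorm(n)))
    # expected *centered* sample variance of the polygenic draw: the
    # uncentered kinship has a large near-constant eigendirection that
    # shifts all individuals jointly and is absorbed by the intercept
    # downstream, so it does not contribute to trait variance
    poly_var_expected <- model$polygenic_variance *
      (sum(diag(K)) - sum(K) / n) / (n - 1)
  }
  line_eff <- matrix(0, n, nt)
  if (model$line_variance > 0 && !is.null(pop$line)) {
    f <- factor(pop$line)
    for (j in seq_len(nt))
      line_eff[, j] <- rnorm(nlevels(f), 0, sqrt(model$line_variance))[as.integer(f)]
  }
  resid <- matrix(rnorm(n * nt, 0, sqrt(model$residual_variance)), n, nt)

  Y <- outer(fixed, model$trait_scales) + poly + line_eff + resid
  colnames(Y) <- paste0("trait", seq_len(nt))
  rownames(Y) <- rownames(G)
  pop$phenotypes <- phenotype_table(Y)
  pop$truth <- list(model = model, fixed = fixed, polygenic = poly,
                    line_effects = line_eff, residuals = resid,
                    polygenic_var_expected = poly_var_expected,
                    h2 = vapply(seq_len(nt), function(j) {
                      vg <- var(model$trait_scales[j] * fixed + poly[, j] + line_eff[, j])
                      vg / (vg + var(resid[, j]))
                    }, numeric(1)))
  pop
}

#' Extract a data bundle from a simulated population
#'
#' @param pop a `sim_population` with phenotypes.
#' @return A list with `genotypes`, `map`, `phenotypes`, `covariates = NULL`,
#'   suitable for the scan and survey stages.
#' @export
as_bundle <- function(pop) {
  list(genotypes = pop$genotypes, map = pop$map,
       phenotypes = pop$phenotypes, covariates = NULL)
}
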