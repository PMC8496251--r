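test_that("lambda maps p-values through chi-square quantiles as defined", {
  # exact uniform grid: lambda = 1 to high precision
  N <- 4999
  expect_lt(abs(lambda_inflation(seq_len(N) / (N + 1)) - 1), 1e-3)
  # median p maps exactly onto the denominator
  expect_equal(lambda_inflation(rep(0.5, 11)), 1, tolerance = 1e-12)
  # chi-square statistics scaled by 1.5 give lambda ~ 1.5
  set.seed(71)
  x <- rchisq(10000, 1) * 1.5
  p <- pchisq(x, 1, lower.tail = FALSE)
  expect_lt(abs(lambda_inflation(p) - 1.5), 0.075)
  # printed-constant denominator
  expect_equal(lambda_inflation(rep(0.5, 5), denominator = "printed"),
               qchisq(0.5, 1) / 0.456, tolerance = 1e-12)
  # mean-based variant: mean of chi-square quantiles over the theoretical mean 1
  expect_equal(lambda_inflation(c(0.2, 0.8), center = "mean"),
               mean(qchisq(c(0.2, 0.8), 1, lower.tail = FALSE)),
               tolerance = 1e-12)
  expect_error(lambda_inflation(numeric(0)), "empty")
  expect_warning(lz <- lambda_inflation(c(0, 0.5, 0.7)), "clamped")
  expect_true(is.finite(lz))
})

test_that("qq data pairs sorted observations with uniform plotting positions", {
  set.seed(72)
  p <- runif(500)
  qd <- qq_data(p)
  expect_equal(nrow(qd), 500)
  expect_false(is.unsorted(qd$theoretical))
  expect_false(is.unsorted(qd$observed))
  # null curve hugs y = x (tails are the noisiest quantiles)
  expect_lt(median(abs(qd$observed - qd$theoretical)), 0.05)
  expect_lt(max(abs(qd$observed - qd$theoretical)), 1)
  # duplicating every value leaves the curve unchanged
  qd2 <- qq_data(c(p, p))
  expect_equal(qd2$observed[seq(1, 1000, 2)], qd$observed, tolerance = 1e-12)
  # an inflated set sits above the line exactly where lambda > 1
  pi_ <- pchisq(rchisq(2000, 1) * 2, 1, lower.tail = FALSE)
  qi <- qq_data(pi_)
  expect_gt(lambda_inflation(pi_), 1)
  expect_gt(mean(qi$observed - qi$theoretical), 0)
})

test_that("monte-carlo cross-validation is deterministic and degenerates to a direct run", {
  f2 <- small_f2()
  f2 <- simulate_traits(f2, trait_model(polygenic_variance = 1,
                                        residual_variance = 1, n_traits = 2),
                        seed = 73)
  m1 <- monte_carlo_cv(f2, corrections = c("none", "overall"),
                       classes = "main", n_trials = 3, seed = 74)
  m2 <- monte_carlo_cv(f2, corrections = c("none", "overall"),
                       classes = "main", n_trials = 3, seed = 74)
  expect_identical(m1$trials, m2$trials)
  expect_equal(nrow(m1$trials), 6)
  expect_true(all(m1$trials$lambda > 0))

  # 100% sampling, single trial: equals a direct scan of the full bundle
  m3 <- monte_carlo_cv(f2, corrections = "none", classes = "main",
                       n_trials = 1, subsample = 1, seed = 75)
  sc <- marker_scan(f2$phenotypes, f2$genotypes, map = f2$map,
                    correction = "none")
  expect_equal(m3$trials$lambda, lambda_inflation(sc$p[!is.na(sc$p)]),
               tolerance = 1e-12)
})

test_that("interaction statistics stay closer to the null than main effects under structure", {
  f2 <- small_f2()
  f2 <- simulate_traits(f2, trait_model(polygenic_variance = 1,
                                        residual_variance = 1, n_traits = 2),
                        seed = 76)
  m <- monte_carlo_cv(f2, corrections = "none",
                      classes = c("main", "interaction"), n_trials = 3,
                      n_keep = 12, seed = 77)
  lam_main <- m$summary$mean_lambda[m$summary$class == "main"]
  lam_int <- m$summary$mean_lambda[m$summary$class == "interaction"]
  expect_gt(lam_main, 1.3)
  expect_lt(abs(lam_int - 1), abs(lam_main - 1))
})

test_that("CAPE statistics are calibrated against their permutation null on null traits", {
  ms <- genetic_map_spec(as.character(1:6), rep(80, 6), rep(6, 6))
  pop <- simulate_population(breeding_design("F2", n_individuals = 200), ms,
                             seed = 78)
  set.seed(79)
  mk <- colnames(pop$genotypes)
  G <- unclass(pop$genotypes)
  pairs <- data.frame(marker1 = sample(mk, 40, TRUE),
                      marker2 = sample(mk, 40, TRUE))
  pairs <- pairs[pairs$marker1 != pairs$marker2, ]
  r <- vapply(seq_len(nrow(pairs)), function(i)
    cor(G[, pairs$marker1[i]], G[, pairs$marker2[i]]), numeric(1))
  pairs <- pairs[abs(r) <= 0.5, ]
  pooled <- unlist(lapply(1:6, function(k) {
    nul <- simulate_traits(pop, trait_model(residual_variance = 1,
                                            n_traits = 2), seed = 80 + k)
    ps <- pair_scan(nul$phenotypes, pop$genotypes, pairs)
    cr <- cape_scan(ps)
    perm <- permutation_null(nul$phenotypes, pop$genotypes,
                             statistic = "cape", pairs = pairs,
                             target_size = 1200, seed = 90 + k)
    cr <- cape_pvalues(cr, perm)
    c(cr$p12, cr$p21)
  }))
  pooled <- pooled[!is.na(pooled)]
  expect_gt(length(pooled), 100)
  lam <- lambda_inflation(pooled)
  expect_gt(lam, 0.8)
  expect_lt(lam, 1.2)
})

test_that("the survey orchestrates populations, survives failures, and reruns identically", {
  ms <- genetic_map_spec(c("1", "2"), c(100, 100), c(10, 10))
  p1 <- simulate_traits(
    simulate_population(breeding_design("F2", n_individuals = 120), ms, seed = 81),
    trait_model(polygenic_variance = 1, residual_variance = 1, n_traits = 2),
    seed = 82)
  p2 <- simulate_traits(
    simulate_population(breeding_design("backcross", n_individuals = 120), ms,
                        seed = 83),
    trait_model(additive_qtl = data.frame(marker = 4, effect = 0.4),
                residual_variance = 1, n_traits = 2), seed = 84)
  broken <- p2; broken$phenotypes <- NULL

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  expect_warning(
    rep1 <- run_survey(list(f2 = p1, bc = p2, bad = broken),
                       corrections = c("none", "overall"), classes = "main",
                       n_trials = 2, seed = 85, out_dir = d1),
    "failed")
  expect_equal(rep1$failed, "bad")
  expect_equal(nrow(rep1$lambda_table), 4)       # 2 populations x 2 corrections
  expect_true(all(c("lambda_table.csv", "structure_metrics.csv",
                    "ld_summary.csv", "run_log.txt") %in% list.files(d1)))
  expect_warning(
    run_survey(list(f2 = p1, bc = p2, bad = broken),
               corrections = c("none", "overall"), classes = "main",
               n_trials = 2, seed = 85, out_dir = d2),
    "failed")
  for (f in c("lambda_table.csv", "lambda_trials.csv",
              "structure_metrics.csv", "ld_summary.csv", "run_log.txt"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
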