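test_that("the delta reparametrization solves the 2x2 system", {
  expect_equal(reparameterize(diag(2), c(0, 0))$delta, c(0, 0))
  expect_equal(reparameterize(diag(2), c(0.2, 0.4))$delta, c(0.2, 0.4))
  # hand-solved case
  rp <- reparameterize(matrix(c(2, 1, 1, 3), 2, 2), c(1, 1))
  expect_equal(rp$delta, c(0.4, 0.2), tolerance = 1e-12)
  expect_false(rp$degenerate)
  # singular and ill-conditioned matrices flag degeneracy
  expect_true(reparameterize(matrix(c(1, 1, 1, 1), 2), c(1, 0))$degenerate)
  expect_true(reparameterize(matrix(c(1, 1, 1, 1 + 1e-12), 2), c(1, 0))$degenerate)
  expect_true(reparameterize(matrix(c(NA, 1, 1, 2), 2), c(1, 0))$degenerate)
})

test_that("delta and influence coefficients are mutually consistent", {
  expect_equal(deltas_to_influence(0, 0)[c("m12", "m21")],
               list(m12 = 0, m21 = 0))
  mi <- deltas_to_influence(0.2, 0.4)
  expect_equal(mi$m12, 1 / 7, tolerance = 1e-12)
  expect_equal(mi$m21, 1 / 3, tolerance = 1e-12)
  expect_true(deltas_to_influence(0.5, -1)$degenerate)
  expect_true(deltas_to_influence(-1, 0.5)$degenerate)

  # inversion identity and round trip on random non-degenerate configurations
  set.seed(61)
  worst_solve <- worst_round <- 0
  for (i in 1:300) {
    B <- matrix(rnorm(4), 2, 2)
    ci <- rnorm(2)
    rp <- reparameterize(B, ci)
    if (rp$degenerate) next
    worst_solve <- max(worst_solve, max(abs(B %*% rp$delta - ci)))
    mi <- deltas_to_influence(rp$delta[1], rp$delta[2])
    if (mi$degenerate) next
    worst_round <- max(worst_round,
                       abs(mi$m12 * (1 + rp$delta[2]) - rp$delta[1]),
                       abs(mi$m21 * (1 + rp$delta[1]) - rp$delta[2]))
  }
  expect_lt(worst_solve, 1e-10)
  expect_lt(worst_round, 1e-10)

  # linearity: scaling beta_int scales delta; m follows its defining relations
  B <- matrix(c(1.2, 0.3, -0.4, 0.9), 2, 2)
  ci <- c(0.15, -0.08)
  d1 <- reparameterize(B, ci)$delta
  d3 <- reparameterize(B, 3 * ci)$delta
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
  m3 <- deltas_to_influence(d3[1], d3[2])
  expect_equal(m3$m12, d3[1] / (1 + d3[2]), tolerance = 1e-12)
})

test_that("second-order error propagation matches independent derivative and MC oracles", {
  B <- matrix(c(1, 0.2, 0.3, 0.8), 2, 2)
  ci <- c(0.15, 0.1)
  S1 <- matrix(c(4e-4, 5e-5, 2e-5, 5e-5, 4e-4, 3e-5, 2e-5, 3e-5, 9e-4), 3, 3)
  S2 <- matrix(c(5e-4, 4e-5, 1e-5, 4e-5, 6e-4, 2e-5, 1e-5, 2e-5, 8e-4), 3, 3)

  # zero covariance: zero propagated variance
  z <- propagate_errors(matrix(0, 3, 3), matrix(0, 3, 3), B, ci)
  expect_equal(z$var_m12, 0)
  expect_equal(z$var_m21, 0)

  # analytic gradient/Hessian against numeric differentiation
  skip_if_not_installed("pracma")
  f12 <- function(th) {
    Bm <- matrix(c(th[1], th[4], th[2], th[5]), 2, 2)
    d <- solve(Bm, c(th[3], th[6]))
    d[1] / (1 + d[2])
  }
  th0 <- c(B[1, 1], B[1, 2], ci[1], B[2, 1], B[2, 2], ci[2])
  S <- matrix(0, 6, 6); S[1:3, 1:3] <- S1; S[4:6, 4:6] <- S2
  g <- pracma::grad(f12, th0)
  H <- pracma::hessian(f12, th0)
  HS <- H %*% S
  var_ref <- drop(t(g) %*% S %*% g) + 0.5 * sum(HS * t(HS))
  pe <- propagate_errors(S1, S2, B, ci)
  expect_equal(pe$var_m12, var_ref, tolerance = 1e-6)

  # tiny diagonal covariance: second order within 5% of first-order delta method
  St <- diag(rep(1e-6, 3))
  pt_ <- propagate_errors(St, St, B, ci)
  Sd <- diag(rep(1e-6, 6))
  first <- drop(t(g) %*% Sd %*% g)
  expect_lt(abs(pt_$var_m12 - first) / first, 0.05)

  # Monte-Carlo oracle (40k draws here; the acceptance check uses 200k)
  set.seed(62)
  nmc <- 40000
  th1 <- matrix(rnorm(nmc * 3), nmc) %*% chol(S1)
  th2 <- matrix(rnorm(nmc * 3), nmc) %*% chol(S2)
  b11 <- B[1, 1] + th1[, 1]; b21 <- B[1, 2] + th1[, 2]; b121 <- ci[1] + th1[, 3]
  b12 <- B[2, 1] + th2[, 1]; b22 <- B[2, 2] + th2[, 2]; b122 <- ci[2] + th2[, 3]
  det <- b11 * b22 - b21 * b12
  d1 <- (b22 * b121 - b21 * b122) / det
  d2 <- (-b12 * b121 + b11 * b122) / det
  expect_lt(abs(pe$var_m12 / var(d1 / (1 + d2)) - 1), 0.1)
  expect_lt(abs(pe$var_m21 / var(d2 / (1 + d1)) - 1), 0.1)

  expect_error(propagate_errors(matrix(rnorm(9), 3), S2, B, ci), "symmetric")
  expect_error(propagate_errors(diag(c(1, 1, -1)), S2, B, ci),
               "positive semidefinite")
})

test_that("cape_scan satisfies the inversion identity pair by pair", {
  set.seed(63)
  n <- 150
  G <- matrix(rbinom(n * 8, 2, 0.5) / 2, n, 8, dimnames = list(NULL, paste0("m", 1:8)))
  geno <- genotype_matrix(G)
  y1 <- 0.5 * G[, 1] + 0.4 * G[, 5] + 0.3 * G[, 1] * G[, 5] + rnorm(n, 0, 0.5)
  y2 <- 0.3 * G[, 1] + 0.6 * G[, 5] + 0.2 * G[, 1] * G[, 5] + rnorm(n, 0, 0.5)
  ph <- phenotype_table(cbind(t1 = y1, t2 = y2))
  pairs <- data.frame(marker1 = c("m1", "m2"), marker2 = c("m5", "m7"))
  ps <- pair_scan(ph, geno, pairs)
  cr <- cape_scan(ps)
  for (i in which(!cr$degenerate)) {
    B <- matrix(ps$coef[i, , 1:2], 2, 2)
    ci <- ps$coef[i, , 3]
    expect_lt(max(abs(B %*% c(cr$delta1[i], cr$delta2[i]) - ci)), 1e-10)
    expect_lt(abs(cr$m12[i] * (1 + cr$delta2[i]) - cr$delta1[i]), 1e-10)
  }
  expect_true(all(is.finite(cr$stat12[!cr$degenerate])))

  # CAPE needs exactly two traits
  ps3 <- pair_scan(phenotype_table(cbind(a = y1, b = y2, c = rev(y1))), geno, pairs)
  expect_error(cape_scan(ps3), "exactly 2 traits")
})

test_that("a planted directed interaction stands out from random pairs", {
  # marker 1 modulates marker 2 with influence m12 = 0.7, m21 = 0, so the
  # interaction coefficients are consistent across both traits
  # (beta12^j = m12 * beta1^j); replicated over independent trait draws
  ms <- genetic_map_spec(c("1", "2", "3"), c(80, 80, 80), c(6, 6, 6))
  pop <- simulate_population(breeding_design("F2", n_individuals = 400), ms,
                             seed = 65)
  G <- unclass(pop$genotypes)
  x1 <- G[, 3]; x2 <- G[, 10]
  mk <- colnames(G)
  pairs <- rbind(data.frame(marker1 = mk[3], marker2 = mk[10]),
                 data.frame(marker1 = mk[c(1, 5, 7, 13, 2)],
                            marker2 = mk[c(8, 14, 16, 17, 12)]))
  planted <- random_p <- numeric(0)
  for (k in 1:6) {
    set.seed(700 + k)
    y1 <- 1.2 * x1 + 0.6 * x2 + 0.7 * 1.2 * x1 * x2 + rnorm(400, 0, 0.4)
    y2 <- 0.6 * x1 + 1.2 * x2 + 0.7 * 0.6 * x1 * x2 + rnorm(400, 0, 0.4)
    ph <- phenotype_table(cbind(t1 = y1, t2 = y2),
                          individual_ids = rownames(G))
    ps <- pair_scan(ph, pop$genotypes, pairs)
    cr <- cape_scan(ps)
    null <- permutation_null(ph, pop$genotypes, statistic = "cape",
                             pairs = pairs, target_size = 1200, seed = 66 + k)
    cr <- cape_pvalues(cr, null)
    planted <- c(planted, min(cr$p12[1], cr$p21[1]))
    random_p <- c(random_p, cr$p12[-1], cr$p21[-1])
  }
  random_p <- random_p[!is.na(random_p)]
  expect_lt(median(planted), quantile(random_p, 0.05))
  expect_lt(median(planted), 0.05)
})
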