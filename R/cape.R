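# Combined Analysis of Pleiotropy and Epistasis (CAPE): reparametrize the
# pairwise regression coefficients of two traits into directed influence
# coefficients.  The delta terms solve
#   [b1^1 b2^1; b1^2 b2^2] %*% delta = (b12^1, b12^2)
# and translate into marker-to-marker influences via
#   delta1 = m12 (1 + delta2),  delta2 = m21 (1 + delta1).
# Variances are propagated through the nonlinear map by a second-order
# Taylor expansion in the six regression coefficients.

#' Reparametrize pairwise coefficients into delta terms
#'
#' Solves the 2x2 linear system `beta_matrix %*% delta = beta_int`, where
#' row j of `beta_matrix` holds the two main-effect coefficients of trait j
#' and `beta_int` the two interaction coefficients.
#'
#' @param beta_matrix 2x2 matrix `[b1^1 b2^1; b1^2 b2^2]`.
#' @param beta_int length-2 vector `(b12^1, b12^2)`.
#' @param condition_max condition-number threshold above which the pair is
#'   flagged degenerate (default 1e8).
#' @return List with `delta` (length 2; `NA` when degenerate) and
#'   `degenerate`.
#' @export
reparameterize <- function(beta_matrix, beta_int, condition_max = 1e8) {
  B <- matrix(as.numeric(beta_matrix), 2L, 2L)
  ci <- as.numeric(beta_int)
  if (anyNA(B) || anyNA(ci) || any(!is.finite(B)) || any(!is.finite(ci)))
    return(list(delta = c(NA_real_, NA_real_), degenerate = TRUE))
  sv <- svd(B, nu = 0, nv = 0)$d
  if (sv[2L] == 0 || sv[1L] / sv[2L] >= condition_max)
    return(list(delta = c(NA_real_, NA_real_), degenerate = TRUE))
  list(delta = as.numeric(solve(B, ci)), degenerate = FALSE)
}

#' Translate delta terms into directed influence coefficients
#'
#' `m12 = delta1 / (1 + delta2)` measures how marker 1 enhances or
#' suppresses the activity of marker 2, and symmetrically for `m21`.
#'
#' @param delta1,delta2 delta terms from [reparameterize()].
#' @param tol denominators within `tol` of zero flag the pair degenerate.
#' @return List with `m12`, `m21`, `degenerate`.
#' @export
deltas_to_influence <- function(delta1, delta2, tol = 1e-8) {
  if (anyNA(c(delta1, delta2)) ||
      abs(1 + delta2) < tol || abs(1 + delta1) < tol)
    return(list(m12 = NA_real_, m21 = NA_real_, degenerate = TRUE))
  list(m12 = delta1 / (1 + delta2), m21 = delta2 / (1 + delta1),
       degenerate = FALSE)
}

# Analytic first and second derivatives of delta and m with respect to the
# six regression coefficients theta = (b1^1, b2^1, b12^1, b1^2, b2^2, b12^2).
cape_derivatives <- function(B, ci) {
  delta <- solve(B, ci)
  E <- function(i, j) { M <- matrix(0, 2, 2); M[i, j] <- 1; M }
  dB <- list(E(1, 1), E(1, 2), matrix(0, 2, 2),
             E(2, 1), E(2, 2), matrix(0, 2, 2))
  dc <- list(c(0, 0), c(0, 0), c(1, 0), c(0, 0), c(0, 0), c(0, 1))
  d1 <- lapply(1:6, function(k) solve(B, dc[[k]] - dB[[k]] %*% delta))
  d2 <- array(0, c(6, 6, 2))
  for (k in 1:6) for (l in k:6) {
    v <- -solve(B, dB[[k]] %*% d1[[l]] + dB[[l]] %*% d1[[k]])
    d2[k, l, ] <- v
    d2[l, k, ] <- v
  }
  list(delta = delta, d1 = d1, d2 = d2)
}

# gradient (6) and Hessian (6x6) of m = f(delta) through the chain rule
m_grad_hess <- function(der, a, Hm) {
  g <- vapply(1:6, function(k) sum(a * der$d1[[k]]), numeric(1))
  H <- matrix(0, 6, 6)
  for (k in 1:6) for (l in k:6) {
    H[k, l] <- sum(a * der$d2[k, l, ]) +
      drop(t(der$d1[[k]]) %*% Hm %*% der$d1[[l]])
    H[l, k] <- H[k, l]
  }
  list(g = g, H = H)
}

#' Propagate regression-coefficient errors to the influence coefficients
#'
#' Second-order Taylor expansion of `m12` and `m21` as functions of the six
#' beta inputs: `Var(m) = g' S g + tr((H S)^2) / 2` with the mean shift
#' `tr(H S) / 2`, where `S` is block-diagonal over the two traits'
#' coefficient covariance blocks (the regressions share genotypes but have
#' independent residuals).
#'
#' @param Sigma1,Sigma2 3x3 symmetric PSD covariance blocks of
#'   `(b1, b2, b12)` from the trait-1 and trait-2 regressions.
#' @param beta_matrix,beta_int as in [reparameterize()].
#' @param condition_max,tol degeneracy thresholds.
#' @return List with `var_m12`, `var_m21`, `mean_shift_m12`,
#'   `mean_shift_m21`, `degenerate`.
#' @export
propagate_errors <- function(Sigma1, Sigma2, beta_matrix, beta_int,
                             condition_max = 1e8, tol = 1e-8) {
  check_psd <- function(S, lab) {
    S <- as.matrix(S)
    if (max(abs(S - t(S))) > 1e-8) stop(lab, " is not symmetric")
    if (min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
        < -1e-8) stop(lab, " is not positive semidefinite")
    (S + t(S)) / 2
  }
  Sigma1 <- check_psd(Sigma1, "Sigma1")
  Sigma2 <- check_psd(Sigma2, "Sigma2")

  rp <- reparameterize(beta_matrix, beta_int, condition_max)
  if (rp$degenerate)
    return(list(var_m12 = NA_real_, var_m21 = NA_real_,
                mean_shift_m12 = NA_real_, mean_shift_m21 = NA_real_,
                degenerate = TRUE))
  d <- rp$delta
  if (abs(1 + d[2L]) < tol || abs(1 + d[1L]) < tol)
    return(list(var_m12 = NA_real_, var_m21 = NA_real_,
                mean_shift_m12 = NA_real_, mean_shift_m21 = NA_real_,
                degenerate = TRUE))

  B <- matrix(as.numeric(beta_matrix), 2L, 2L)
  der <- cape_derivatives(B, as.numeric(beta_int))
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- Sigma1
  S[4:6, 4:6] <- Sigma2

  # m12 = d1/(1+d2)
  gh12 <- m_grad_hess(der,
                      a = c(1 / (1 + d[2L]), -d[1L] / (1 + d[2L])^2),
                      Hm = matrix(c(0, -1 / (1 + d[2L])^2,
                                    -1 / (1 + d[2L])^2,
                                    2 * d[1L] / (1 + d[2L])^3), 2, 2))
  # m21 = d2/(1+d1)
  gh21 <- m_grad_hess(der,
                      a = c(-d[2L] / (1 + d[1L])^2, 1 / (1 + d[1L])),
                      Hm = matrix(c(2 * d[2L] / (1 + d[1L])^3,
                                    -1 / (1 + d[1L])^2,
                                    -1 / (1 + d[1L])^2, 0), 2, 2))
  second <- function(gh) {
    HS <- gh$H %*% S
    list(var = drop(t(gh$g) %*% S %*% gh$g) + 0.5 * sum(HS * t(HS)),
         shift = 0.5 * sum(diag(HS)))
  }
  s12 <- second(gh12); s21 <- second(gh21)
  list(var_m12 = s12$var, var_m21 = s21$var,
       mean_shift_m12 = s12$shift, mean_shift_m21 = s21$shift,
       degenerate = FALSE)
}

#' Run CAPE reparametrization over a pairwise scan of two traits
#'
#' For every non-degenerate marker pair: solve for the delta terms,
#' translate to directed influences `m12`, `m21`, propagate coefficient
#' covariances, and standardize (`m / SE`).  The inversion identity
#' `beta_matrix %*% delta = beta_int` and the delta/m round trip hold to
#' numerical precision for every non-degenerate pair.
#'
#' @param pair_result a `pair_scan_result` over exactly 2 traits.
#' @param condition_max,tol degeneracy thresholds, see [reparameterize()]
#'   and [deltas_to_influence()].
#' @return A `cape_result` data frame: per pair delta1, delta2, m12, m21,
#'   propagated variances, standardized statistics `stat12`, `stat21`, and
#'   a degeneracy flag.
#' @export
cape_scan <- function(pair_result, condition_max = 1e8, tol = 1e-8) {
  stopifnot(inherits(pair_result, "pair_scan_result"))
  if (length(pair_result$traits) != 2L)
    stop("CAPE requires exactly 2 traits (got ", length(pair_result$traits), ")")
  np <- nrow(pair_result$pairs)
  out <- data.frame(pair_result$pairs,
                    delta1 = NA_real_, delta2 = NA_real_,
                    m12 = NA_real_, m21 = NA_real_,
                    var_m12 = NA_real_, var_m21 = NA_real_,
                    stat12 = NA_real_, stat21 = NA_real_,
                    degenerate = TRUE)
  for (i in seq_len(np)) {
    B <- matrix(pair_result$coef[i, , 1:2], 2L, 2L)  # rows traits: [b1^1 b2^1; b1^2 b2^2]
    ci <- pair_result$coef[i, , 3L]
    if (anyNA(B) || anyNA(ci)) next
    rp <- reparameterize(B, ci, condition_max)
    if (rp$degenerate) next
    mi <- deltas_to_influence(rp$delta[1L], rp$delta[2L], tol)
    if (mi$degenerate) next
    pe <- propagate_errors(pair_result$vcov[i, 1L, , ],
                           pair_result$vcov[i, 2L, , ],
                           B, ci, condition_max, tol)
    if (pe$degenerate || pe$var_m12 <= 0 || pe$var_m21 <= 0) next
    out$delta1[i] <- rp$delta[1L]; out$delta2[i] <- rp$delta[2L]
    out$m12[i] <- mi$m12; out$m21[i] <- mi$m21
    out$var_m12[i] <- pe$var_m12; out$var_m21[i] <- pe$var_m21
    out$stat12[i] <- mi$m12 / sqrt(pe$var_m12)
    out$stat21[i] <- mi$m21 / sqrt(pe$var_m21)
    out$degenerate[i] <- FALSE
  }
  class(out) <- c("cape_result", "data.frame")
  out
}

#' Empirical p-values for directed influence coefficients
#'
#' @param cape_result a [cape_scan()] result.
#' @param null a [permutation_null()] of standardized m magnitudes
#'   (statistic kind `"cape"`).
#' @return The `cape_result` with columns `p12`, `p21` added.
#' @export
cape_pvalues <- function(cape_result, null) {
  if (!inherits(null, "permutation_null") || null$kind != "cape")
    stop("null must be a permutation null of CAPE statistics")
  cape_result$p12 <- ifelse(is.na(cape_result$stat12), NA_real_,
                            empirical_p(cape_result$stat12, null))
  cape_result$p21 <- ifelse(is.na(cape_result$stat21), NA_real_,
                            empirical_p(cape_result$stat21, null))
  cape_result
}
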