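# EMMA-style mixed-model correction.  The phenotype covariance is modeled
# as sigma^2 * (h*K + (1-h)*I); K is eigendecomposed once, the mixing
# parameter h is profiled on a 1-D grid (fixed effects and variance have
# closed forms in the rotated basis), and phenotype/design columns are
# rotated so downstream scans reduce to ordinary least squares.

#' Spectral decomposition of a kinship matrix
#'
#' @param kinship a symmetric positive semidefinite `kinship_matrix`.
#'   Eigenvalues in (-1e-8, 0) are clipped to 0; more negative values are
#'   treated as upstream corruption and are fatal.
#' @return A `kinship_eigen` list with nonincreasing `values`, orthonormal
#'   `vectors`, and `mean_diag` (average self-kinship, used to normalize the
#'   mixing-parameter scale).
#' @export
eigen_kinship <- function(kinship) {
  K <- unclass(kinship)
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-8)
    stop("kinship matrix must be symmetric")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("kinship matrix is not positive semidefinite (min eigenvalue ",
         format(min(eg$values)), ")")
  eg$values <- pmax(eg$values, 0)
  structure(list(values = eg$values, vectors = eg$vectors,
                 mean_diag = mean(diag(K))),
            class = "kinship_eigen")
}

#' Profile the variance mixing parameter on a grid
#'
#' Fits `y = X beta + g + e` with `cov(g + e) = sigma^2 (h K* + (1-h) I)` by
#' maximum likelihood (REML optional), where `K*` is the kinship scaled to
#' unit mean diagonal so that `h` is interpretable as the fraction of
#' residual variance attributable to kinship (heritability under the
#' polygenic model).  For each grid value of `h` the fixed effects and
#' variance have closed forms in the eigenbasis; the grid argmax is
#' returned, ties broken toward smaller `h`.
#'
#' @param phenotype numeric vector without missing values.
#' @param design design matrix including the intercept (and covariates).
#' @param kinship_eigen a [eigen_kinship()] decomposition.
#' @param grid candidate `h` values in `[0, 1)`.
#' @param reml use restricted maximum likelihood instead of ML.
#' @return An `lmm_fit` list: `h`, `grid`, `loglik` (profile), `weights`
#'   (`1/(h lambda_i + 1-h)`, strictly positive), `beta`, `sigma2`,
#'   and the decomposition needed by [rotate()].
#' @export
fit_mixing_parameter <- function(phenotype, design, kinship_eigen,
                                 grid = seq(0, 0.99, by = 0.01),
                                 reml = FALSE) {
  stopifnot(inherits(kinship_eigen, "kinship_eigen"))
  y <- as.numeric(phenotype)
  X <- as.matrix(design)
  n <- length(y)
  if (anyNA(y)) stop("phenotype contains missing values")
  if (nrow(X) != n || nrow(kinship_eigen$vectors) != n)
    stop("dimension mismatch between phenotype, design, and kinship")
  if (any(grid < 0 | grid >= 1)) stop("grid must lie in [0, 1)")
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("design matrix is singular; columns: ", paste(colnames(X), collapse = ", "))

  U <- kinship_eigen$vectors
  lam <- kinship_eigen$values / mean(kinship_eigen$values)  # unit mean diagonal
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)

  ll <- numeric(length(grid))
  fits <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    h <- grid[k]
    d <- h * lam + (1 - h)
    sw <- 1 / sqrt(d)
    fit <- lm.fit(Xr * sw, yr * sw)
    if (fit$rank < p)
      stop("rotated design is singular at h = ", h,
           "; columns: ", paste(colnames(X), collapse = ", "))
    rss <- sum(fit$residuals^2)
    if (reml) {
      XtWX <- crossprod(Xr * sw)
      XtX <- crossprod(X)
      s2 <- rss / (n - p)
      ll[k] <- -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) + sum(log(d)) +
                         determinant(XtWX)$modulus - determinant(XtX)$modulus)
    } else {
      s2 <- rss / n
      ll[k] <- -0.5 * (n * (log(2 * pi) + log(s2) + 1) + sum(log(d)))
    }
    fits[[k]] <- list(beta = fit$coefficients, sigma2 = s2, d = d)
  }
  best <- which.max(ll)
  structure(list(h = grid[best], grid = grid, loglik = as.numeric(ll),
                 weights = 1 / fits[[best]]$d, d = fits[[best]]$d,
                 beta = fits[[best]]$beta, sigma2 = fits[[best]]$sigma2,
                 vectors = U, eigenvalues = lam, reml = reml),
            class = "lmm_fit")
}

#' Rotate phenotype and design columns into the fitted error basis
#'
#' Applies `W^(1/2) U'` with `W = diag(1/(h lambda_i + 1-h))`, after which
#' the model residuals are exchangeable and ordinary least squares applies.
#' At `h = 0` this is an orthonormal change of basis that leaves all OLS
#' statistics unchanged.
#'
#' @param phenotype numeric vector (or matrix of columns to rotate).
#' @param design matrix of design columns to rotate (may be `NULL`).
#' @param fit an [fit_mixing_parameter()] result from the same kinship
#'   decomposition.
#' @return A list with rotated `phenotype` and `design`.
#' @export
rotate <- function(phenotype, design, fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  sw <- sqrt(fit$weights)
  rot <- function(M) {
    M <- as.matrix(M)
    if (nrow(M) != nrow(fit$vectors)) stop("dimension mismatch in rotation")
    out <- crossprod(fit$vectors, M) * sw
    dimnames(out) <- dimnames(M)
    out
  }
  list(phenotype = if (is.null(dim(phenotype))) drop(rot(phenotype)) else rot(phenotype),
       design = if (!is.null(design)) rot(design))
}
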