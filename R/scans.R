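# Single-locus and pairwise marker regressions on (optionally rotated)
# data, marker selection for pair tests, and pooled permutation nulls.

# OLS with coefficient covariance.  df_mode "n-1" matches the t reference
# used throughout (df = n - 1); "residual" is the conventional n - p.
ols_detail <- function(X, y, df_mode = "n-1") {
  fit <- lm.fit(X, y)
  p <- ncol(X)
  if (fit$rank < p) return(NULL)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv <- chol2inv(R)
  ip <- order(fit$qr$pivot)
  XtXinv <- XtXinv[ip, ip, drop = FALSE]
  rss <- sum(fit$residuals^2)
  dfv <- if (df_mode == "n-1") length(y) - 1L else length(y) - p
  sigma2 <- rss / dfv
  se <- sqrt(sigma2 * diag(XtXinv))
  coef <- fit$coefficients
  tstat <- coef / se
  list(coef = coef, se = se, tstat = tstat,
       p = 2 * pt(-abs(tstat), dfv), df = dfv,
       vcov = sigma2 * XtXinv, sigma2 = sigma2)
}

# Shared rotation helper: fit the LMM null model for one trait and rotate
# the base design plus extra columns.  correction "none" passes through.
# Eigendecompositions are cached across traits via `cache` (same kinship
# and row set recur for every trait).
rotation_context <- function(y, X0, extra, kinship, grid, reml,
                             cache = NULL, cache_key = NULL) {
  if (is.null(kinship))
    return(list(y = y, X0 = X0, extra = extra, h = NA_real_))
  eig <- NULL
  if (!is.null(cache) && !is.null(cache_key))
    eig <- cache[[cache_key]]
  if (is.null(eig)) {
    eig <- eigen_kinship(kinship)
    if (!is.null(cache) && !is.null(cache_key)) cache[[cache_key]] <- eig
  }
  fit <- fit_mixing_parameter(y, X0, eig, grid = grid, reml = reml)
  rr <- rotate(y, cbind(X0, extra), fit)
  k0 <- ncol(X0)
  list(y = rr$phenotype, X0 = rr$design[, seq_len(k0), drop = FALSE],
       extra = rr$design[, -seq_len(k0), drop = FALSE], h = fit$h)
}

rows_key <- function(ok) paste(which(!ok), collapse = ",")

resolve_traits <- function(phenotypes, traits = NULL) {
  Y <- as.matrix(phenotypes)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(ncol(Y)))
  if (!is.null(traits)) Y <- Y[, traits, drop = FALSE]
  Y
}

#' Single-locus marker scan
#'
#' Fits `y = b0 + covariates + marker + e` for every marker and trait, on
#' data rotated by the requested kinship correction.  P-values use a t
#' distribution with `n - 1` degrees of freedom by default (`df =
#' "residual"` uses the conventional residual degrees of freedom).
#' Individuals with a missing value for a trait are dropped for that trait
#' only; kinship and rotation are then computed on the retained rows.
#'
#' @param phenotypes a [phenotype_table()] or matrix.
#' @param genotypes a [genotype_matrix()] with no missing values.
#' @param map a [marker_map()]; required for `correction = "loco"`.
#' @param covariates optional [covariate_table()].
#' @param correction `"none"`, `"loco"` (leave-one-chromosome-out kinship
#'   per tested chromosome), or `"overall"`.
#' @param traits optional subset of trait names.
#' @param grid,reml passed to [fit_mixing_parameter()].
#' @param df `"n-1"` (default) or `"residual"`.
#' @param denominator kinship denominator convention, see [loco_kinship()].
#' @return A `scan_result` data frame with one row per marker x trait:
#'   effect estimate, standard error, t statistic, p-value, intercept and
#'   covariate estimates, and the fitted mixing parameter `h`.  Monomorphic
#'   markers yield `NA` statistics and are counted in attribute
#'   `n_monomorphic`.
#' @export
marker_scan <- function(phenotypes, genotypes, map = NULL, covariates = NULL,
                        correction = c("none", "loco", "overall"),
                        traits = NULL, grid = seq(0, 0.99, by = 0.01),
                        df = c("n-1", "residual"), reml = FALSE,
                        denominator = c("used", "total")) {
  correction <- match.arg(correction)
  df <- match.arg(df)
  denominator <- match.arg(denominator)
  G <- unclass(genotypes)
  Y <- resolve_traits(phenotypes, traits)
  if (correction == "loco" && is.null(map))
    stop("correction = 'loco' needs a marker map")
  chrom <- if (!is.null(map)) map$chromosome[match(colnames(G), map$marker)]
           else rep(NA_character_, ncol(G))

  rows <- list(); n_mono <- 0L
  eig_cache <- new.env(parent = emptyenv())
  for (tr in colnames(Y)) {
    ok <- !is.na(Y[, tr])
    y <- Y[ok, tr]
    Gs <- G[ok, , drop = FALSE]
    X0 <- cbind(`(Intercept)` = rep(1, sum(ok)),
                if (!is.null(covariates)) unclass(covariates)[ok, , drop = FALSE])
    gsub <- genotype_matrix(Gs)

    groups <- switch(correction,
      none    = list(list(markers = colnames(G), kinship = NULL)),
      overall = list(list(markers = colnames(G),
                          kinship = overall_kinship(gsub, denominator))),
      loco    = lapply(unique(chrom), function(ch) list(
                  markers = colnames(G)[chrom == ch],
                  kinship = loco_kinship(gsub, map, ch, denominator))))

    for (gi in seq_along(groups)) {
      grp <- groups[[gi]]
      mk <- grp$markers
      ctx <- rotation_context(y, X0, Gs[, mk, drop = FALSE], grp$kinship,
                              grid, reml, cache = eig_cache,
                              cache_key = paste0(rows_key(ok), "|", gi))
      for (j in seq_along(mk)) {
        raw <- Gs[, mk[j]]
        if (sd(raw) == 0) {
          n_mono <- n_mono + 1L
          od <- NULL
        } else {
          X <- cbind(ctx$X0, marker = ctx$extra[, j])
          od <- ols_detail(X, ctx$y, df)
        }
        k <- ncol(X0)
        rows[[length(rows) + 1L]] <- data.frame(
          marker = mk[j], chromosome = chrom[match(mk[j], colnames(G))],
          trait = tr,
          beta = if (is.null(od)) NA_real_ else od$coef[k + 1L],
          se = if (is.null(od)) NA_real_ else od$se[k + 1L],
          tstat = if (is.null(od)) NA_real_ else od$tstat[k + 1L],
          p = if (is.null(od)) NA_real_ else od$p[k + 1L],
          beta0 = if (is.null(od)) NA_real_ else od$coef[1L],
          h = ctx$h, stringsAsFactors = FALSE)
        if (!is.null(covariates)) {
          cv <- if (is.null(od)) rep(NA_real_, ncol(covariates))
                else od$coef[1L + seq_len(ncol(covariates))]
          for (ci in seq_len(ncol(covariates)))
            rows[[length(rows)]][[paste0("beta_", colnames(covariates)[ci])]] <- cv[ci]
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$trait, colnames(Y)),
                   match(out$marker, colnames(G))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_monomorphic") <- n_mono
  attr(out, "correction") <- correction
  attr(out, "df") <- df
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Select markers with strong main effects for pairwise testing
#'
#' Markers are ranked by their best (minimum) main-effect p-value across the
#' scanned traits; the top `n_keep` are retained and all their pairs formed,
#' excluding pairs whose genotype correlation exceeds the collinearity
#' guard (which protects the CAPE matrix inversion).
#'
#' @param scan a `scan_result` from [marker_scan()] covering >= 2 traits.
#' @param genotypes the [genotype_matrix()] used for the scan.
#' @param n_keep number of markers to keep (>= 2).
#' @param collinearity_r_max pairs with `|r|` above this are not tested.
#' @return A `pair_selection` list: `markers`, `pairs` (data frame with
#'   `marker1`, `marker2`), `excluded` (pairs dropped by the guard, with r).
#' @export
select_markers_for_pairs <- function(scan, genotypes, n_keep,
                                     collinearity_r_max = 0.5) {
  if (n_keep < 2L) stop("n_keep must be >= 2")
  if (length(unique(scan$trait)) < 2L)
    stop("marker selection requires a scan over at least 2 traits")
  best <- tapply(scan$p, scan$marker, function(p)
    if (all(is.na(p))) Inf else min(p, na.rm = TRUE))
  best <- best[is.finite(best)]
  kept <- names(sort(best))[seq_len(min(n_keep, length(best)))]
  kept <- colnames(genotypes)[colnames(genotypes) %in% kept]  # genome order
  if (length(kept) < 2L) stop("fewer than 2 informative markers to pair")
  cmb <- t(combn(kept, 2L))
  G <- unclass(genotypes)
  r <- vapply(seq_len(nrow(cmb)), function(i)
    cor(G[, cmb[i, 1L]], G[, cmb[i, 2L]]), numeric(1))
  ok <- abs(r) <= collinearity_r_max
  structure(list(markers = kept,
                 pairs = data.frame(marker1 = cmb[ok, 1L], marker2 = cmb[ok, 2L],
                                    stringsAsFactors = FALSE),
                 excluded = data.frame(marker1 = cmb[!ok, 1L],
                                       marker2 = cmb[!ok, 2L], r = r[!ok],
                                       stringsAsFactors = FALSE)),
            class = "pair_selection")
}

#' Pairwise marker scan with interaction term
#'
#' Fits `y = b0 + covariates + x1 + x2 + x1*x2 + e` per marker pair and
#' trait.  The dosage product is formed in the original space and rotated
#' with the rest of the design.  The full coefficient covariance block for
#' `(x1, x2, x1*x2)` is retained for the CAPE stage.  For `correction =
#' "ltco"` the kinship omits the two tested chromosomes (one when equal).
#'
#' @inheritParams marker_scan
#' @param pairs a `pair_selection` or data frame with `marker1`, `marker2`.
#' @param correction `"none"`, `"ltco"`, or `"overall"`.
#' @return A `pair_scan_result` list: `table` (per pair x trait statistics),
#'   `coef` (pairs x traits x 3 array of `(b1, b2, b12)`), `vcov` (pairs x
#'   traits x 3 x 3), `pairs`, `traits`.  Collinear pairs are flagged
#'   degenerate, not fatal.
#' @export
pair_scan <- function(phenotypes, genotypes, pairs, map = NULL,
                      covariates = NULL,
                      correction = c("none", "ltco", "overall"),
                      traits = NULL, grid = seq(0, 0.99, by = 0.01),
                      df = c("n-1", "residual"), reml = FALSE,
                      denominator = c("used", "total")) {
  correction <- match.arg(correction)
  df <- match.arg(df)
  denominator <- match.arg(denominator)
  if (inherits(pairs, "pair_selection")) pairs <- pairs$pairs
  if (nrow(pairs) == 0L) stop("empty pair list")
  G <- unclass(genotypes)
  Y <- resolve_traits(phenotypes, traits)
  if (correction == "ltco" && is.null(map))
    stop("correction = 'ltco' needs a marker map")
  chrom <- if (!is.null(map)) map$chromosome[match(colnames(G), map$marker)]

  np <- nrow(pairs); nt <- ncol(Y)
  coef_arr <- array(NA_real_, c(np, nt, 3L),
                    dimnames = list(NULL, colnames(Y), c("b1", "b2", "b12")))
  vcov_arr <- array(NA_real_, c(np, nt, 3L, 3L))
  rows <- list()
  eig_cache <- new.env(parent = emptyenv())

  pair_key <- if (correction == "ltco") {
    vapply(seq_len(np), function(i) {
      cc <- sort(c(chrom[match(pairs$marker1[i], colnames(G))],
                   chrom[match(pairs$marker2[i], colnames(G))]))
      paste(cc, collapse = "|")
    }, character(1))
  } else rep("all", np)

  for (tr_i in seq_len(nt)) {
    tr <- colnames(Y)[tr_i]
    ok <- !is.na(Y[, tr])
    y <- Y[ok, tr]
    Gs <- G[ok, , drop = FALSE]
    X0 <- cbind(`(Intercept)` = rep(1, sum(ok)),
                if (!is.null(covariates)) unclass(covariates)[ok, , drop = FALSE])
    gsub <- genotype_matrix(Gs)

    for (key in unique(pair_key)) {
      pidx <- which(pair_key == key)
      kin <- switch(correction,
        none = NULL,
        overall = overall_kinship(gsub, denominator),
        ltco = {
          cc <- strsplit(key, "|", fixed = TRUE)[[1L]]
          if (length(cc) == 1L || cc[1L] == cc[2L])
            loco_kinship(gsub, map, cc[1L], denominator)
          else ltco_kinship(gsub, map, cc[1L], cc[2L], denominator)
        })
      x1 <- Gs[, pairs$marker1[pidx], drop = FALSE]
      x2 <- Gs[, pairs$marker2[pidx], drop = FALSE]
      extra <- cbind(x1, x2, x1 * x2)
      ctx <- rotation_context(y, X0, extra, kin, grid, reml,
                              cache = eig_cache,
                              cache_key = paste0(rows_key(ok), "|", key))
      k <- length(pidx); kc <- ncol(X0)
      for (q in seq_along(pidx)) {
        i <- pidx[q]
        X <- cbind(ctx$X0,
                   x1 = ctx$extra[, q], x2 = ctx$extra[, k + q],
                   x12 = ctx$extra[, 2L * k + q])
        od <- ols_detail(X, ctx$y, df)
        deg <- is.null(od)
        if (!deg) {
          sel <- kc + 1:3
          coef_arr[i, tr_i, ] <- od$coef[sel]
          vcov_arr[i, tr_i, , ] <- od$vcov[sel, sel]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          pair = i, marker1 = pairs$marker1[i], marker2 = pairs$marker2[i],
          trait = tr,
          beta1 = if (deg) NA_real_ else od$coef[kc + 1L],
          beta2 = if (deg) NA_real_ else od$coef[kc + 2L],
          beta12 = if (deg) NA_real_ else od$coef[kc + 3L],
          se12 = if (deg) NA_real_ else od$se[kc + 3L],
          t12 = if (deg) NA_real_ else od$tstat[kc + 3L],
          p12 = if (deg) NA_real_ else od$p[kc + 3L],
          h = ctx$h, degenerate = deg, stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, rows)
  table <- table[order(match(table$trait, colnames(Y)), table$pair), ,
                 drop = FALSE]
  rownames(table) <- NULL
  structure(list(table = table, coef = coef_arr, vcov = vcov_arr,
                 pairs = pairs, traits = colnames(Y),
                 correction = correction, df = df),
            class = "pair_scan_result")
}

#' Pooled permutation null distribution
#'
#' Phenotype rows are permuted jointly across traits (covariates stay with
#' the genotype rows), the requested scan statistic is recomputed, and
#' statistic magnitudes are pooled over permutations until the target size
#' is reached.  Deterministic given the seed.
#'
#' @inheritParams pair_scan
#' @param statistic `"main"` (single-locus |t|), `"interaction"`
#'   (pairwise |t| of the product term), or `"cape"` (standardized |m|
#'   influence statistics; requires exactly 2 traits).
#' @param pairs pair list, required for `"interaction"` and `"cape"`.
#' @param target_size minimum pooled null size (>= 1000 at study scale;
#'   smaller values are allowed for toy examples).
#' @param pool_directions for `"cape"`: pool m12 and m21 into one null
#'   (default) or keep the first direction only.
#' @param seed integer seed.
#' @param ... passed to [marker_scan()] / [pair_scan()] (e.g. `correction`,
#'   `map`, `covariates`).
#' @return A `permutation_null` list: `values` (pooled magnitudes), `kind`,
#'   `target_size`, `n_permutations`.
#' @export
permutation_null <- function(phenotypes, genotypes,
                             statistic = c("main", "interaction", "cape"),
                             pairs = NULL, target_size = 15000, seed = 1L,
                             pool_directions = TRUE, ...) {
  statistic <- match.arg(statistic)
  Y <- resolve_traits(phenotypes)
  n <- nrow(Y)
  if (n < 7L) warning("few individuals: permutations may not be distinct")
  if (statistic %in% c("interaction", "cape") && is.null(pairs))
    stop("pair statistics need a pair list")
  set.seed(seed)
  vals <- numeric(0); n_perm <- 0L
  while (length(vals) < target_size) {
    perm <- sample.int(n)
    Yp <- Y[perm, , drop = FALSE]
    rownames(Yp) <- rownames(Y)
    new <- switch(statistic,
      main = {
        sc <- marker_scan(Yp, genotypes, ...)
        abs(sc$tstat)
      },
      interaction = {
        ps <- pair_scan(Yp, genotypes, pairs, ...)
        abs(ps$table$t12)
      },
      cape = {
        ps <- pair_scan(Yp, genotypes, pairs, ...)
        cr <- cape_scan(ps)
        if (pool_directions) c(abs(cr$stat12), abs(cr$stat21))
        else abs(cr$stat12)
      })
    vals <- c(vals, new[is.finite(new)])
    n_perm <- n_perm + 1L
    if (n_perm > 10000L) stop("permutation null did not reach target size")
  }
  structure(list(values = vals, kind = statistic, target_size = target_size,
                 n_permutations = n_perm),
            class = "permutation_null")
}

#' Empirical p-value against a permutation null
#'
#' `p = (1 + #\{null >= |statistic|\}) / (1 + N)`; never exactly zero.
#'
#' @param statistic numeric vector of observed statistics.
#' @param null a [permutation_null()] (or numeric vector of null
#'   magnitudes).
#' @return Numeric vector of empirical p-values in `(0, 1]`.
#' @export
empirical_p <- function(statistic, null) {
  vals <- if (inherits(null, "permutation_null")) null$values else null
  if (length(vals) == 0L) stop("empty null distribution")
  srt <- sort(vals)
  N <- length(srt)
  n_ge <- N - findInterval(abs(statistic), srt, left.open = TRUE)
  (1 + n_ge) / (1 + N)
}
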