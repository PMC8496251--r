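# Genomic inflation factors, QQ data, and the survey orchestration:
# statistic classes (main, interaction, cape) x correction regimes
# (none, reduced, overall) x Monte-Carlo cross-validation trials.

#' Genomic inflation factor lambda
#'
#' Each p-value is mapped to the chi-square(1) quantile of `1 - p`; lambda
#' is the median of those quantiles divided by the chi-square(1) median.
#' The exact median 0.4549364 is the default denominator; `denominator =
#' "printed"` uses the conventionally printed rounded constant 0.456.
#' `center = "mean"`
#' instead divides the mean of the quantiles by the theoretical mean 1.
#'
#' @param p_values numeric vector of p-values in (0, 1]; zeros are clamped
#'   to the machine floor with a warning.
#' @param denominator `"exact"` or `"printed"`.
#' @param center `"median"` (default) or `"mean"`.
#' @return Scalar lambda (> 0).
#' @export
lambda_inflation <- function(p_values, denominator = c("exact", "printed"),
                             center = c("median", "mean")) {
  denominator <- match.arg(denominator)
  center <- match.arg(center)
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p > 1) || any(p < 0)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-values of 0 clamped to machine floor")
    p[p == 0] <- .Machine$double.xmin
  }
  q <- qchisq(p, df = 1, lower.tail = FALSE)
  if (center == "median") {
    den <- if (denominator == "exact") qchisq(0.5, df = 1, lower.tail = FALSE)
           else 0.456
    median(q) / den
  } else {
    mean(q) / 1
  }
}

#' Observed-vs-theoretical quantiles for a QQ plot
#'
#' @param p_values nonempty numeric vector of p-values.
#' @return A `qq_data` data frame with nondecreasing columns `theoretical`
#'   (`-log10` of uniform plotting positions `i/(N+1)`) and `observed`
#'   (sorted `-log10` p).
#' @export
qq_data <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p <= 0)) p[p <= 0] <- .Machine$double.xmin
  N <- length(p)
  # i-th smallest -log10 p pairs with the i-th smallest -log10 plotting
  # position; both columns ascend together
  out <- data.frame(theoretical = -log10((N:1) / (N + 1)),
                    observed = -log10(sort(p, decreasing = TRUE)))
  rownames(out) <- NULL
  class(out) <- c("qq_data", "data.frame")
  out
}

as_survey_bundle <- function(x) {
  if (inherits(x, "sim_population")) as_bundle(x) else x
}

# one full pipeline pass on a (sub)bundle for one correction regime;
# returns lambda per requested statistic class
pipeline_lambdas <- function(bundle, correction, classes, traits,
                             main_traits, n_keep, collinearity_r_max,
                             cape_null_size, grid, df, denominator,
                             perm_seed) {
  main_corr <- switch(correction, none = "none", reduced = "loco",
                      overall = "overall")
  pair_corr <- switch(correction, none = "none", reduced = "ltco",
                      overall = "overall")
  out <- c(main = NA_real_, interaction = NA_real_, cape = NA_real_)

  # main-effect survey scans all requested traits (the pair and CAPE
  # stages are restricted to the two selected traits)
  sc <- marker_scan(bundle$phenotypes, bundle$genotypes, map = bundle$map,
                    covariates = bundle$covariates, correction = main_corr,
                    traits = main_traits, grid = grid, df = df,
                    denominator = denominator)
  if ("main" %in% classes)
    out["main"] <- lambda_inflation(sc$p[!is.na(sc$p)])

  if (any(c("interaction", "cape") %in% classes)) {
    sc_sel <- sc[sc$trait %in% traits, , drop = FALSE]
    sel <- select_markers_for_pairs(sc_sel, bundle$genotypes, n_keep,
                                    collinearity_r_max)
    ps <- pair_scan(bundle$phenotypes, bundle$genotypes, sel,
                    map = bundle$map, covariates = bundle$covariates,
                    correction = pair_corr, traits = traits, grid = grid,
                    df = df, denominator = denominator)
    if ("interaction" %in% classes)
      out["interaction"] <- lambda_inflation(ps$table$p12[!is.na(ps$table$p12)])
    if ("cape" %in% classes) {
      cr <- cape_scan(ps)
      null <- permutation_null(bundle$phenotypes[, traits, drop = FALSE],
                               bundle$genotypes, statistic = "cape",
                               pairs = sel, target_size = cape_null_size,
                               seed = perm_seed, map = bundle$map,
                               covariates = bundle$covariates,
                               correction = pair_corr, grid = grid, df = df,
                               denominator = denominator)
      cr <- cape_pvalues(cr, null)
      pp <- c(cr$p12, cr$p21)
      out["cape"] <- lambda_inflation(pp[!is.na(pp)])
    }
  }
  out
}

#' Monte-Carlo cross-validated inflation factors
#'
#' Repeatedly subsamples individuals (80% without replacement, 10 trials by
#' default), runs the full scan pipeline under each correction regime, and
#' records lambda for each statistic class.
#'
#' @param bundle a population bundle (list with `genotypes`, `map`,
#'   `phenotypes`, optional `covariates`) or a `sim_population`.
#' @param traits two trait names used for the pair and CAPE stages;
#'   defaults to the first two traits.
#' @param main_traits traits scanned for the main-effect lambda (the
#'   survey scans all traits by default, mirroring a genome-wide screen
#'   across every phenotype).
#' @param corrections subset of `"none"`, `"reduced"` (LOCO/LTCO),
#'   `"overall"`.
#' @param classes subset of `"main"`, `"interaction"`, `"cape"`.
#' @param n_trials,subsample Monte-Carlo settings.
#' @param n_keep,collinearity_r_max marker selection for the pair stage.
#' @param cape_null_size pooled permutation-null size for CAPE p-values.
#' @param grid,df,denominator passed through to the scans.
#' @param seed integer seed; results are bit-identical given the seed.
#' @return An `inflation_result` list: `trials` (trial x correction x class
#'   lambda table), `summary` (mean and sd per cell), `config`.
#' @export
monte_carlo_cv <- function(bundle, traits = NULL, main_traits = NULL,
                           corrections = c("none", "reduced", "overall"),
                           classes = c("main", "interaction", "cape"),
                           n_trials = 10L, subsample = 0.8,
                           n_keep = 20L, collinearity_r_max = 0.5,
                           cape_null_size = 2000L,
                           grid = seq(0, 0.99, by = 0.01),
                           df = c("n-1", "residual"),
                           denominator = c("used", "total"), seed = 1L) {
  df <- match.arg(df)
  denominator <- match.arg(denominator)
  corrections <- match.arg(corrections, several.ok = TRUE)
  classes <- match.arg(classes, several.ok = TRUE)
  bundle <- as_survey_bundle(bundle)
  Y <- resolve_traits(bundle$phenotypes)
  if (is.null(traits)) traits <- colnames(Y)[1:2]
  if (is.null(main_traits)) main_traits <- colnames(Y)
  if (length(traits) < 2L) stop("need two traits for the pair and CAPE stages")
  n <- nrow(Y)
  ncov <- if (is.null(bundle$covariates)) 0L else ncol(bundle$covariates)

  set.seed(seed)
  trial_seeds <- sample.int(2^31 - 2, n_trials)
  rows <- list()
  for (t in seq_len(n_trials)) {
    set.seed(trial_seeds[t])
    n_sub <- max(2L, floor(subsample * n))
    if (n_sub < ncov + 3L) stop("subsample too small for the design")
    idx <- if (n_sub == n) seq_len(n) else sort(sample.int(n, n_sub))
    sub <- list(genotypes = genotype_matrix(unclass(bundle$genotypes)[idx, , drop = FALSE]),
                map = bundle$map,
                phenotypes = phenotype_table(unclass(bundle$phenotypes)[idx, , drop = FALSE]),
                covariates = if (!is.null(bundle$covariates))
                  covariate_table(unclass(bundle$covariates)[idx, , drop = FALSE]))
    for (corr in corrections) {
      lam <- pipeline_lambdas(sub, corr, classes, traits, main_traits,
                              n_keep, collinearity_r_max, cape_null_size,
                              grid, df, denominator,
                              perm_seed = (trial_seeds[t] + match(corr, corrections)) %% (2^31 - 2))
      for (cl in classes)
        rows[[length(rows) + 1L]] <- data.frame(
          trial = t, correction = corr, class = cl, lambda = lam[[cl]],
          stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  agg_mean <- aggregate(lambda ~ correction + class, trials, mean)
  agg_sd <- aggregate(lambda ~ correction + class, trials, sd)
  summary <- data.frame(agg_mean[, c("class", "correction")],
                        mean_lambda = agg_mean$lambda,
                        sd_lambda = agg_sd$lambda)
  summary <- summary[order(summary$class, summary$correction), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(trials = trials, summary = summary,
                 config = list(traits = traits, main_traits = main_traits,
                               corrections = corrections,
                               classes = classes, n_trials = n_trials,
                               subsample = subsample, n_keep = n_keep,
                               collinearity_r_max = collinearity_r_max,
                               cape_null_size = cape_null_size, df = df,
                               denominator = denominator, seed = seed)),
            class = "inflation_result")
}

#' Survey inflation and structure across populations
#'
#' For each population: structure metrics (kinship-network communities,
#' FST, trait correlations with kinship PC1, within-chromosome LD
#' quantiles), Monte-Carlo cross-validated lambda per statistic class and
#' correction regime, and QQ data from a full-sample main scan per
#' correction.  A failing population is marked failed and the survey
#' continues.  Outputs are plain delimited tables when `out_dir` is given;
#' reruns with the same configuration and seed are byte-identical.
#'
#' @param populations named list of bundles or `sim_population`s.
#' @inheritParams monte_carlo_cv
#' @param out_dir optional output directory.
#' @return A `survey_report` list: `lambda_table` (per population summary),
#'   `lambda_trials`, `structure_metrics`, `ld`, `qq` (per population x
#'   correction), `failed`, `config`.
#' @export
run_survey <- function(populations,
                       corrections = c("none", "reduced", "overall"),
                       classes = c("main", "interaction", "cape"),
                       traits = NULL, n_trials = 10L, subsample = 0.8,
                       n_keep = 20L, collinearity_r_max = 0.5,
                       cape_null_size = 2000L, seed = 1L, out_dir = NULL) {
  if (is.null(names(populations)) || any(names(populations) == ""))
    stop("populations must be a named list")
  set.seed(seed)
  pop_seeds <- sample.int(2^31 - 2, length(populations))
  lt <- list(); tr <- list(); sm <- list(); ld <- list(); qq <- list()
  failed <- character(0)
  for (i in seq_along(populations)) {
    nm <- names(populations)[i]
    res <- tryCatch({
      b <- as_survey_bundle(populations[[i]])
      K <- overall_kinship(b$genotypes)
      comm <- detect_subpopulations(kinship_to_network(K))
      fs <- fst(b$genotypes, comm)
      pc <- trait_kinship_pc1_correlation(K, b$phenotypes)
      lds <- ld_summary(b$genotypes, b$map)
      mcv <- monte_carlo_cv(b, traits = traits, corrections = corrections,
                            classes = classes, n_trials = n_trials,
                            subsample = subsample, n_keep = n_keep,
                            collinearity_r_max = collinearity_r_max,
                            cape_null_size = cape_null_size,
                            seed = pop_seeds[i])
      qd <- list()
      for (corr in corrections) {
        mc <- switch(corr, none = "none", reduced = "loco", overall = "overall")
        sc <- marker_scan(b$phenotypes, b$genotypes, map = b$map,
                          covariates = b$covariates, correction = mc,
                          traits = mcv$config$traits)
        qd[[corr]] <- qq_data(sc$p[!is.na(sc$p)])
      }
      list(fs = fs, comm = comm, pc = pc, lds = lds, mcv = mcv, qd = qd)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("population '", nm, "' failed: ", conditionMessage(res))
      failed <- c(failed, nm)
      next
    }
    lt[[nm]] <- data.frame(population = nm, res$mcv$summary,
                           stringsAsFactors = FALSE)
    tr[[nm]] <- data.frame(population = nm, res$mcv$trials,
                           stringsAsFactors = FALSE)
    sm[[nm]] <- data.frame(population = nm, fst = res$fs$fst,
                           pi_total = res$fs$pi_total,
                           pi_sub_mean = res$fs$pi_sub_mean,
                           n_communities = res$fs$n_communities,
                           modularity = res$comm$modularity,
                           max_abs_pc1_trait_r = max(abs(res$pc$correlations),
                                                     na.rm = TRUE),
                           stringsAsFactors = FALSE)
    ld[[nm]] <- data.frame(population = nm, t(res$lds$quantiles),
                           mean_abs_r = res$lds$mean_abs_r,
                           n_pairs = res$lds$n_pairs, check.names = FALSE,
                           stringsAsFactors = FALSE)
    qq[[nm]] <- res$qd
  }
  report <- structure(
    list(lambda_table = do.call(rbind, c(lt, list(make.row.names = FALSE))),
         lambda_trials = do.call(rbind, c(tr, list(make.row.names = FALSE))),
         structure_metrics = do.call(rbind, c(sm, list(make.row.names = FALSE))),
         ld = do.call(rbind, c(ld, list(make.row.names = FALSE))),
         qq = qq, failed = failed,
         config = list(corrections = corrections, classes = classes,
                       n_trials = n_trials, subsample = subsample,
                       n_keep = n_keep,
                       collinearity_r_max = collinearity_r_max,
                       cape_null_size = cape_null_size, seed = seed)),
    class = "survey_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "qq"), showWarnings = FALSE)
    write.csv(report$lambda_table, file.path(out_dir, "lambda_table.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(report$lambda_trials, file.path(out_dir, "lambda_trials.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(report$structure_metrics,
              file.path(out_dir, "structure_metrics.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(report$ld, file.path(out_dir, "ld_summary.csv"),
              row.names = FALSE, quote = FALSE)
    for (nm in names(report$qq)) for (corr in names(report$qq[[nm]]))
      write.csv(report$qq[[nm]][[corr]],
                file.path(out_dir, "qq", paste0(nm, "_", corr, ".csv")),
                row.names = FALSE, quote = FALSE)
    log <- c(paste0("epikin version: ", as.character(packageVersion("epikin"))),
             paste0("seed: ", seed),
             paste0("corrections: ", paste(corrections, collapse = ",")),
             paste0("classes: ", paste(classes, collapse = ",")),
             paste0("n_trials: ", n_trials),
             paste0("subsample: ", subsample),
             paste0("n_keep: ", n_keep),
             paste0("cape_null_size: ", cape_null_size),
             paste0("failed: ", if (length(failed)) paste(failed, collapse = ",") else "none"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  report
}
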