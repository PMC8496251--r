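---
title: "Kinship, epistasis, and test-statistic inflation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship, epistasis, and test-statistic inflation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epikin)
```

# The problem

Genetic association scans in experimental mouse populations are confounded
by relatedness. Individuals that share more of their genome than average —
because they are genomic replicates of a recombinant inbred (RI) line,
sibs from an intercross, or members of a structured outbred cohort — share
trait variance that a single-marker regression attributes to whichever
marker happens to segregate with the structure. The result is genomic
inflation: the bulk of the p-value distribution shifts toward zero and the
false-positive rate rises. `epikin` implements the machinery needed to
measure this inflation for three classes of test statistic (single-locus
main effects, pairwise epistatic interactions, and directed-influence
coefficients that combine two traits), to correct it with linear mixed
models under different kinship conventions, and to generate synthetic
populations with the breeding structure of the classic mouse designs so
that every claim can be tested end to end without external data.

# Kinship matrices

Relatedness is summarized by the realized genotype similarity
`K = G %*% t(G) / n`, with `G` the individuals-by-markers dosage matrix
(alternate-allele fraction in `[0, 1]`: 0, 0.5, 1 for homozygous reference,
heterozygous, homozygous alternate) and `n` the number of markers. Dosages
enter as-is — no centering or standardization — so `K` is automatically
positive semidefinite. Three variants are provided:

* `overall_kinship()` — all markers;
* `loco_kinship()` — leave-one-chromosome-out: markers on the tested
  chromosome are excluded, which preserves power at the tested locus while
  still correcting genome-wide structure;
* `ltco_kinship()` — leave-two-chromosomes-out, the natural extension for
  pairwise tests. When both tested markers share a chromosome only that one
  chromosome is dropped, and the result is identical to LOCO.

The denominator for the reduced matrices is, by default, the number of
markers actually used; `denominator = "total"` divides by the full marker
count instead, which shrinks the reduced matrices uniformly. Both are
supported because the shrunken variant is what a literal reading of the
reduced-matrix formula produces, and reproducibility of either convention
may be needed; the choice does not affect the mixed model fit (the mixing
parameter absorbs a global scale) but does affect raw kinship summaries.

Note that with a two-chromosome map, an LTCO request for a cross-chromosome
pair would empty the marker set and is fatal; pairwise LTCO corrections
need at least three chromosomes.

# The mixed-model correction

`fit_mixing_parameter()` implements the standard fast single-component
linear mixed model. The phenotype covariance is modeled as
`sigma^2 * (h*K + (1-h)*I)`. `K` is eigendecomposed once
(`eigen_kinship()`); for each candidate `h` on a one-dimensional grid
(default `seq(0, 0.99, by = 0.01)`), the fixed effects and `sigma^2` have
closed forms in the eigenbasis, so profiling `h` costs one weighted least
squares solve per grid point. The grid argmax is returned, with ties broken
toward smaller `h`; a property test verifies the grid optimum sits within
one step of a 0.001-resolution rerun. Full maximum likelihood is the
default; `reml = TRUE` switches the profile criterion to REML.

Two conventions matter:

* **Scale.** The eigenvalues are normalized to mean 1 (equivalent to
  scaling `K` to unit mean diagonal) before fitting, so `h` is
  interpretable as the fraction of residual variance attributable to
  kinship — the heritability of the polygenic component. Without this,
  `h` would depend on the arbitrary scale of `G %*% t(G) / n`.
* **Centering.** Because dosages are not centered, `K` has a large
  near-constant eigendirection (every pair of individuals shares a
  baseline similarity). That direction is absorbed by the intercept and
  carries essentially no trait variance; it is the reason the *sample*
  variance of a polygenic draw is smaller than its nominal variance (see
  the simulator section).

`rotate()` applies `W^(1/2) %*% t(U)` with `W = diag(1/(h*lambda + 1-h))`
to the phenotype and to every design column (including dosage-product
columns, which are formed in the original space and rotated as columns).
After rotation ordinary least squares applies, and at `h = 0` the map is
orthonormal, leaving every OLS statistic unchanged — a useful invariance
exercised by the tests.

# Scans and permutation nulls

`marker_scan()` regresses each trait on intercept + covariates + one
marker; `pair_scan()` adds a second marker and their dosage product, and
retains the 3x3 coefficient covariance block of `(x1, x2, x1*x2)` for the
reparametrization stage. P-values use a t reference with `n - 1` degrees of
freedom by default; the conventional residual degrees of freedom are
available via `df = "residual"`. At the sample sizes where these scans are
used the two differ negligibly, but the printed rule is kept as the default
so results are reproducible against analyses that used it.

Markers enter pairwise testing through `select_markers_for_pairs()`:
markers are ranked by their best main-effect p-value across the two traits
of interest, the top `n_keep` are retained, and any pair whose dosage
correlation exceeds `collinearity_r_max` (default 0.5) is excluded. The
guard exists for the benefit of the 2x2 matrix inversion in the
directed-influence stage, which amplifies noise when the two markers'
main-effect columns are nearly collinear.

`permutation_null()` permutes whole phenotype rows jointly across traits —
keeping the trait-trait correlation intact, which the two-trait
reparametrization requires — while covariates stay attached to the
genotype rows. Statistics from successive permutations are pooled until a
target size is reached (default 15,000 at desk scale; the pooled-null size
is a config value and can be raised to the millions used in full-scale
analyses). `empirical_p()` applies the add-one rule
`p = (1 + #{null >= |stat|}) / (1 + N)`, which never returns zero.

# Directed influence coefficients

For a marker pair tested against exactly two traits, the main-effect
matrix `B = [b1^1 b2^1; b1^2 b2^2]` and interaction vector
`c = (b12^1, b12^2)` are reparametrized by solving `B delta = c`
(`reparameterize()`), then translated into directed influences
`m12 = delta1/(1 + delta2)`, `m21 = delta2/(1 + delta1)`
(`deltas_to_influence()`). `m12` measures how the presence of marker 1
enhances or suppresses the effect of marker 2 consistently across both
traits; the asymmetry of `m12` and `m21` is what makes the interaction
directed.

Because the solve and the ratio are nonlinear in six estimated
coefficients, uncertainty is propagated by a second-order Taylor
expansion (`propagate_errors()`):
`Var(m) = g' S g + tr((H S)^2)/2`, with gradient `g` and Hessian `H`
computed analytically via matrix-derivative identities
(`d delta = B^{-1}(dc - dB delta)` and its second-order analogue), and `S` the
block-diagonal 6x6 covariance built from the two traits' regression blocks.
Treating the two traits' blocks as independent is a modeling choice — the
regressions share genotypes but have separate residuals — and is validated
against a 200,000-draw Monte-Carlo resampling oracle, which agrees with the
closed form to well under the 10% acceptance tolerance. Degenerate pairs
(ill-conditioned `B`, condition number above 1e8, or `|1 + delta|` below
1e-8) are flagged and reported, never silently dropped.

The standardized statistics `m/SE` have no analytic null — they are ratios
of correlated regression coefficients — so their p-values are empirical,
against a permutation null of the same statistic kind, with `m12` and
`m21` pooled into a single null by default.

# Inflation evaluation

`lambda_inflation()` maps each p-value to the chi-square(1) quantile of
`1 - p` and divides the median of those quantiles by the chi-square(1)
median. The exact median 0.4549364 is the default denominator; the
conventional rounded constant 0.456 is available via
`denominator = "printed"`, and a mean-based variant (mean of the quantiles
over the theoretical mean 1) via `center = "mean"`. The variants differ in
the third decimal at most but all are reproducible.

`monte_carlo_cv()` estimates the sampling variability of lambda by
repeated 80% subsampling of individuals (10 trials by default), running
the full pipeline — main scan, marker selection, pair scan, directed
influence, permutation null — for each correction regime (`none`,
`reduced` = LOCO/LTCO, `overall`) and recording lambda per statistic
class. Main-effect lambda pools scans over *all* traits in the bundle
(a genome-wide screen across a trait battery), while the pair and
directed-influence stages use the two designated traits. Main and
interaction lambdas are computed from the analytic t-based p-values: an
empirical p-value measured against its own pooled permutation null is
calibrated against that null by construction and would mask the very
inflation being measured. The directed-influence lambda necessarily uses
empirical p-values. `run_survey()` wraps this per population and adds the
structure screen (below), QQ exports, and a provenance log; reruns with
the same configuration and seed are byte-identical.

# Population-structure diagnostics

The kinship matrix is converted to a weighted network
(`kinship_to_network()`: diagonal removed, negative values clipped to
zero — modularity clustering assumes nonnegative weights) and partitioned
with fast-greedy modularity maximization (`detect_subpopulations()`).
`fst()` computes the fixation index `(pi_T - pi_S)/pi_T` from expected
heterozygosity `2p(1-p)` summed over loci, with pooled allele frequencies
for `pi_T` and a size-weighted average of subpopulation heterozygosities
for `pi_S` (unweighted averaging and an observed-heterozygote variant are
flags; expected heterozygosity is the default because inbred panels have
near-zero observed heterozygosity, which would degenerate the index).
`trait_kinship_pc1_correlation()` reports each trait's correlation with
the leading eigenvector of the double-centered kinship matrix — the screen
used to select traits that are least confounded with structure — with the
eigenvector's sign fixed by making its largest-magnitude loading positive.
`ld_summary()` pools Pearson correlations of all within-chromosome marker
pairs as a linkage-disequilibrium summary.

# The population simulator

`simulate_population()` builds genomes as pairs of founder-label
haplotypes over a marker map and drops Poisson crossovers (mean
length/100 per chromosome, positions uniform in cM, no interference —
the Haldane model) at each meiosis. This is the simplest recombination
model that produces the LD gradient the survey depends on: dense
single-generation LD in F2 and backcross, progressively decayed LD in
advanced intercross (AIL) and outbred genomes. Schemes:

* **F2 / backcross** — one or two recombinant generations from two inbred
  founders.
* **RIL** — per line, an F1 sib pair is sib-mated for
  `n_inbreeding_generations` (default 20) and a final genome is drawn;
  residual heterozygous calls (about 1% at the default) are kept as 0.5
  dosages rather than forced to homozygosity. Genomic replicates are exact
  row copies; `average_replicates()` (or the `RIL_NR` scheme) collapses
  them to one row per line.
* **AIL** — random-pair mating for `n_intercross_generations` (default 50,
  a commonly used late generation); heterozygosity stays near 0.5 up to
  drift, and adjacent-marker correlation falls with every generation (map
  expansion), both verified as properties.
* **outbred8** — eight founders crossed through a round-robin funnel, then
  random mating; an option samples individuals from the last few
  generations to emulate a cohort spanning generations. This is a
  structural emulation of an 8-founder outbred stock, not a calibrated
  model of any particular colony: founder alleles at each biallelic marker
  are assigned at random, and no funnel bookkeeping beyond the round-robin
  is performed.

`simulate_traits()` composes phenotypes as additive QTL effects +
dosage-product epistasis + a polygenic term + a line-level random effect
(RIL) + residual noise, and stores every draw in a truth record so
variance components can be audited. The polygenic term is drawn with
covariance `polygenic_variance * K/mean(diag(K))` from the realized
overall kinship — exactly the structure the mixed model assumes — so
mixing-parameter recovery is a clean parameter-recovery test; an
alternative many-small-QTL background can be emulated by passing many
weak `additive_qtl`. Because the uncentered kinship carries a
near-constant eigendirection, the *centered* sample variance of the
polygenic draw is smaller than the nominal `polygenic_variance`; the truth
record stores the model-implied expectation (`polygenic_var_expected`) so
tests compare like with like.

What the simulator does **not** emulate: genotyping error and missing-data
patterns of real arrays, sex chromosomes and dosage compensation,
crossover interference, mutation, real founder haplotype panels, and
selection during breeding. Calibration results on synthetic data therefore
speak to the statistical machinery under the stated covariance structures,
not to artifacts specific to real genotyping pipelines.

# Study conditions used in the end-to-end checks

The acceptance-level checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) run the survey on three synthetic populations
chosen once to emulate the designs where inflation contrasts are sharpest,
at sizes that keep the whole suite within minutes on one CPU:

* **F2, main effects** — n = 1000, two chromosomes of 100 cM with 50
  markers each, a battery of 16 polygenic traits at heritability 0.5.
  Dense LD plus polygenicity drives large uncorrected inflation; the
  overall-kinship correction restores lambda to about 1. The trait battery
  is deliberately wide because the median-based lambda estimated from 100
  highly correlated markers is noisy; pooling traits tightens it.
* **RIL with replicates, main effects** — a BXD-like panel: 55 lines, 8
  genomic replicates each (n = 440), 19 autosomes of 80 cM with 10 markers
  each, 8 traits sharing two additive QTL (effect 0.6 on chromosomes 3 and
  9) with per-trait effect scaling from 1 down to 0.3 and unit residual
  variance. Sparse mappable QTL — rather than a uniformly polygenic
  architecture — are used because lambda does not distinguish true linked
  signal from confounding: with genetic variance on every chromosome, even
  an exact generalized-least-squares correction leaves the median marker
  carrying real signal under LOCO, and lambda stays well above 1 at this
  sample size. With a sparse architecture the replicate-driven structure
  still inflates the uncorrected scan markedly while the LOCO-corrected
  scan returns to calibration, which is the contrast of interest.
* **Interaction calibration and type-I error** — n = 1000 F2 over ten
  80 cM chromosomes (10 markers each) with one moderate additive QTL
  (effect 0.3) per chromosome. Markers spread over many chromosomes keep
  main-effect-selected pairs predominantly cross-chromosome; with few
  chromosomes, selected pairs concentrate on same-chromosome QTL proxies,
  whose imperfect tagging leaks marginal signal into the product term and
  distorts the interaction statistic in either direction. Because pairs
  share markers, rejection indicators within one trait draw are strongly
  dependent; the type-I rate is pooled over eight independent trait draws
  on a fixed pair set of 2500 cross-chromosome pairs.

Numerical tolerances follow the same pattern throughout: algebraic
identities (kinship oracles, the delta inversion, round trips) are checked
to 1e-10 or better; stochastic calibration quantities are checked against
bands wide enough for their sampling variability at the stated sizes
(lambda within 0.05 of 1 on 10,000 uniform p-values; the mixing parameter
mean within 0.1 of truth over 50 replicates; rejection rates within three
binomial standard errors).

# Known limitations

* The single-component mixed model cannot represent a line-level random
  effect that is *independent* of genome-wide similarity: kinship predicts
  between-line covariance proportional to realized sharing, so iid strain
  effects are whitened only approximately. With one short chromosome left
  in, a LOCO matrix is a noisy estimate of the line structure and the
  residual miscalibration is visible; it shrinks as chromosomes are added.
* Lambda conflates true linked signal with confounding (by design — it
  summarizes the whole p-value distribution). Interpreting the corrected
  lambdas requires an architecture in which the median marker is null.
* Directed-influence statistics are ratios of estimated coefficients and
  are intrinsically noisy at a few hundred individuals; their permutation
  p-values are calibrated, but power for realistic effect sizes is modest.
* The permutation scheme permutes raw phenotypes and re-fits the rotation
  per permutation; an alternative that permutes rotated residuals is not
  implemented.
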