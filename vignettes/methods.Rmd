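---
title: "Models and methods: sex-biased selection, PGLS with Pagel's lambda, and phylogenetic imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosel)
```

## The scientific problem

Classical sexual-selection theory links three things: the asymmetry in
gametic investment between the sexes (anisogamy), the division of parental
care, and the strength of sexual selection, usually summarized per sex by
the opportunity for selection $I$, the opportunity for sexual selection
$I_s$, and the Bateman gradient $\beta_{ss}$. Comparative tests of these
links regress *between-sex contrasts* of the selection metrics on
life-history predictors across species, while correcting for shared
ancestry. This package implements that entire analysis chain — effect
sizes, phylogenetic regression, missing-data imputation, and a synthetic
data generator that provides ground truth for every stage.

## Per-species indices

For each sex we summarize reproductive success (RS) and mating success
(MS) by a mean, an SD and a sample size. The contrasts are:

* $\Delta I$ and $\Delta I_s$: the log coefficient-of-variation ratio
  $\mathrm{lnCVR} = \ln\frac{CV_m}{CV_f}$ of RS and MS respectively,
  positive when selection is more intense on males. Because
  $I = CV^2$, lnCVR is exactly half the log-ratio of the two
  opportunities, so it orders species identically. The small-sample
  correction $\frac{1}{2(n_m-1)} - \frac{1}{2(n_f-1)}$ is applied by
  default (`small_sample_correction = TRUE`); it cancels when sample
  sizes are equal.
* $\Delta\beta_{ss}$: Hedges' $d$ of the two Bateman gradients,
  $(\bar\beta_m - \bar\beta_f)/s_{pool} \cdot J$ with
  $J = 1 - 3/(4(n_m+n_f-2)-1)$. Exactly which summaries enter this
  contrast is not standardized in the literature; the package therefore
  exposes `hedges_d()` on per-sex (mean, SD, n) summaries and leaves the
  caller in control of what those summaries are.
* SSD: $\ln(\text{male size}/\text{female size})$, with lengths converted
  through the cubic weight–length law (the shape constant cancels, giving
  $3\ln$ of the length ratio).
* Gamete size bias: $\ln\frac{\text{male gamete}/\text{male mass}}
  {\text{female gamete}/\text{female mass}}$; gametic investment bias
  replaces the numerator by testis mass and the denominator by egg mass
  times clutch size. The algebra makes positive values male-biased
  relative investment; the package documents and follows the algebraic
  sign convention.
* Parental-care score: 0 (female-only) to 4 (male-only) on the five-level
  scale; the interior bins split male-care percentages at $33\tfrac13$
  and $66\tfrac23$ (upper edges closed, a deterministic tie-break), and
  the published "77–99%" upper bin is read as 67–99%, the only reading
  that partitions the scale. Species with no care at all receive no
  score and are excluded from care models automatically (their score is
  `NA` and PGLS deletes casewise).

All logarithms are natural. lnCVR is conventionally natural-log; using
the same base for SSD and the gametic indices keeps every index on one
log scale, and no downstream statistic depends on the base.

## PGLS with maximum-likelihood Pagel's lambda

The regression model is $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 C_\lambda)$, where $C$ holds shared
root-to-MRCA path lengths and $C_\lambda$ multiplies its off-diagonals by
$\lambda \in [0,1]$. At fixed $\lambda$ the estimator is exact GLS via
Cholesky whitening; $\sigma^2$ is profiled by ML (divisor $n$) for the
likelihood, while standard errors use the $n-k$ residual variance so that
on a star phylogeny the fit coincides with OLS, t and p values included.
$\lambda$ is estimated by a bounded one-dimensional search of the profile
log-likelihood (tolerance $10^{-6}$), the optimum is compared against
both endpoints, and ties break toward the smaller $\lambda$. ML is the
default criterion (matching how $\lambda$ is usually reported in
comparative analyses); REML is available via `method = "REML"`.

Adjusted $R^2$ is defined from the GLS analogue of explained variance:
$R^2$ compares the whitened residual sum of squares against the
whitened intercept-only fit, and
$R^2_{adj} = 1-(1-R^2)(n-1)/(n-k-1)$ with $k$ predictors. The published
tables this mirrors report adjusted $R^2$ without defining it; this
definition is used consistently and is stated here so results are
interpretable.

Two properties worth knowing, both under test: multiplying all branch
lengths by a constant changes only $\hat\sigma^2$ (so branch-length
units are irrelevant to $\hat\lambda$, t and p), and the slope test holds
approximately nominal size at $n = 64$ when $\lambda$ is re-estimated per
fit (measured rejection rate ≈ 0.055 at $\alpha = 0.05$ with a fixed
covariate; with a phylogenetically structured covariate the test is
slightly anticonservative, a known finite-sample cost of plugging in
$\hat\lambda$).

The care score is treated as a continuous variable in PGLS, replicating
standard practice in this literature; its ordinal nature is acknowledged
but not modelled.

## Phylogenetic multiple imputation

Missing trait cells are modelled jointly: for the $n \times k$ species ×
trait matrix $Y$,
$\mathrm{vec}(Y) \sim N(\mathbf{1} \otimes \mu,\; R \otimes C_\lambda)$
with per-trait root means $\mu$, cross-trait Brownian covariance $R$, and
one common $\lambda$ (the simplest model consistent with fitting a
lambda-transformed Brownian process to several traits; a per-trait
$\lambda$ would not guarantee a positive-semidefinite joint covariance in
general). Parameters are estimated by ML on the observed data: closed
form per $\lambda$ when the table is complete, otherwise EM with exact
conditional moments in the E step, and $\lambda$ profiled by an outer
bounded search (tolerance $10^{-3}$ — imputation moments are insensitive
to finer resolution).

`impute_moments()` returns the exact conditional mean and variance of
every missing cell given all observed cells. `draw_imputations()` fills
the cells with independent normal draws at those moments, ten completed
tables by default, each with a seed derived deterministically from the
master seed. Per-model fits across the completed tables are pooled as
mean ± sample SD of every reported parameter (`pool_fits()`), the
presentation used in the tables this package emulates; Rubin's rules are
deliberately not the default.

The leave-one-out reliability check masks each observed cell in turn and
correlates the re-imputed conditional means with the original values per
trait. The default fast mode keeps the model parameters fixed and uses
the precision-matrix identity
$\hat y_i = y_i - (\Omega(y-\mu))_i / \Omega_{ii}$, which is exactly the
held-out conditional mean at one matrix inversion; `refit = TRUE`
re-estimates parameters per deletion (with $\lambda$ held fixed) at
quadratic cost. The conventional reliability bar is $r \ge 0.8$.

The care score is never imputed: it is categorical and its missingness
(no-care species) is structural, not accidental.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested, emulating a 64-species comparative dataset:

* **Tree**: pure-birth (Yule) with rate 1, ultrametric, like a timetree;
  a coalescent option provides an alternative shape. Tips are relabelled
  `s1..sn`.
* **Traits**: multivariate Brownian motion with Pagel's $\lambda$
  (default common $\lambda$); log-scale morphology (body masses, gamete
  sizes, testis mass, clutch size) shares a correlation of 0.6 through a
  common size axis, a realistic level of allometric integration.
* **Sex groups**: each species gets a latent male-care fraction
  $u \sim U(0,1)$ and a no-care flag with probability 27/64 (the no-care
  fraction of the emulated dataset). The implied effect sizes are
  $\delta = \text{effect} \cdot (u - \tfrac12) + \varepsilon$,
  $\varepsilon \sim N(0, 0.1)$, built into the per-sex summaries so that
  `ln_cvr()` and `hedges_d()` recover them exactly (female CV 0.5,
  within-sex samples of 20, lognormal success means). The generative
  law of individual success values is deliberately not asserted —
  published datasets report only summaries, so the generator works at
  the summary level.
* **Missingness**: missing-completely-at-random, exactly
  $\mathrm{round}(\text{rate} \times n)$ cells per column (deterministic
  counts make tests exact), at the default per-column rates 31% (female
  mass), 20% (male mass), 48% (testis mass), 36% (male gamete size), 31%
  (female gamete mass), 27% (clutch size), and 14%/7%/23% for the three
  selection effect sizes. Only the marginal fractions of the emulated
  dataset are known, so MCAR is the only defensible mechanism. Care
  columns are never masked.
* **Auxiliary species**: `simulate_dataset(n_aux = ...)` adds extra tips
  observed for a subset of columns, emulating the augmentation of an
  imputation model with partially observed outside species.

What passing tests on these data do *not* show: robustness to
non-ultrametric trees with fossil tips, to non-Brownian (e.g. OU) trait
evolution, to informative missingness, or to the measurement error that
pervades literature-compiled trait values. Those are properties of real
compilations that the generator intentionally does not emulate.

## Numerical choices

* Covariances enter every solver through Cholesky factorization; a
  near-singular observed block (e.g. perfectly collinear traits) gets a
  relative ridge of $10^{-10}$ before factorization fails.
* Zero-length branches are accepted (identical-covariance tips);
  negative lengths are rejected at parse time. Polytomies are treated as
  true multifurcations.
* Trees are not required to be ultrametric; an optional depth
  normalization (`phylo_vcv(..., normalize_depth = TRUE)`) only rescales
  the Brownian rate and is off by default.
* Grafting a species attaches it at a fraction of the sister's terminal
  branch with a matching tip branch, so ultrametric trees stay
  ultrametric and existing path lengths are untouched.
* Conditional variances are clamped at zero from below; draws with zero
  conditional variance are deterministic.
* Every stochastic function takes an explicit integer seed and restores
  the caller's RNG state; multi-dataset procedures derive per-dataset
  seeds from the master seed below $2^{31}$.

## Problem sizes used in the checks

The package's statistical checks run at sizes chosen to make Monte-Carlo
error small relative to the tolerance being asserted: oracle equivalences
on 200 (GLS) and 100 (OLS-limit) random instances of up to 15 and 30
tips; $\lambda$ recovery on 200-tip trees with 100 replicates per true
value; null calibration at $n = 64$ with 1000 replicates; LOO reliability
at the full 64-species, 9-trait configuration; and the end-to-end
directional check over 50 replicate pipeline runs of all 18 planned
models. The directional check asserts rates per model across replicates:
the care models must be significant in more than 80% of runs while no
gametic-bias term may reach that rate (a joint "every null term
non-significant in every run" criterion would be incoherent — with twelve
independent null terms per run at $\alpha = 0.05$ it would fail about
half the time by construction).

## Known limitations

* A single common $\lambda$ across traits in the imputation model; the
  PGLS stage estimates $\lambda$ per model, so the two stages can
  disagree about signal strength.
* Hedges' d inputs for the Bateman-gradient contrast are caller-defined
  (see above).
* The published sign sentence for the gametic bias indices is
  self-contradictory ("a positive value indicates a male-biased gamete
  size (or gametic investment), a positive value indicates a
  female-biased gamete size"); the package follows the formula's
  algebra — positive = male-biased relative investment — and flags the
  ambiguity here rather than silently resolving it.
* No phylogenetic logistic/ordinal regression, no OU correlation
  structure, no Rubin's-rules pooling by default, no tree inference or
  dating.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_species = 64, effect_care_on_selection = -3, seed = 11)
ds <- simulate_dataset(cfg, mask = TRUE)
derived <- derive_indices(ds$raw)
report <- run_plan(derived, ds$tree, default_plan(), mode = "original")
subset(report$results, model == "bivariate_07")
```

The care model (`care_score ~ delta_I`) recovers a strongly negative
slope, while the gametic-bias models hover at their null rates — the
qualitative pattern the pipeline is designed to detect.
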