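---
title: "Estimating age-varying genetic effects by meta-regression of GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating age-varying genetic effects by meta-regression of GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemeta)
```

## The problem

Genome-wide association studies (GWAS) are routinely combined by
fixed-effect meta-analysis to gain power.  That pooling assumes one common
true effect per SNP.  When the genetic effect changes with age — as
documented for BMI, blood pressure, bone mineral density and other traits —
the pooled estimate is an average over the age distribution of the
contributing studies, and its confidence interval says nothing about the
effect at any particular age.  Most GWAS do not report within-study
SNP-by-age interaction analyses, so the two-stage interaction
meta-analysis used for treatment-covariate interactions in trials is
rarely available.

`agemeta` implements the alternative: random-effects **meta-regression of
per-study effect estimates on study-level age moments**.  It needs only
what GWAS normally publish per study — the per-allele estimate
$\hat\beta_{1j}$, its standard error, and the mean and SD of age — and it
returns both the genetic effect at any reference age and the SNP-by-age
interaction coefficients.

## Models

Per study, the summary estimate is taken from the age-adjusted OLS
regression $y_{ij} = \beta_{0j} + \beta_{1j} SNP_{ij} + \beta_{2j}
age_{ij} + \epsilon_{ij}$ (`fit_study()`); no interaction or quadratic
terms are ever fitted within study, mirroring standard GWAS practice.

The pooling models for the collection $\{\hat\beta_{1j}, s_j\}$ are:

* **Fixed effect** (`fixed_effect_ma()`): $\hat\beta_{1j} = \beta_{SNP} +
  \eta_j$, $\eta_j \sim N(0, s_j^2)$; inverse-variance weights $1/s_j^2$.
* **Random effects** (`random_effects_ma()`): adds $\xi_j \sim N(0,
  \tau^2)$ with $\tau^2$ estimated by REML; weights $1/(s_j^2 +
  \hat\tau^2)$.
* **Meta-regression** (`meta_regression()`): $\hat\beta_{1j} = \beta_{SNP}
  + \beta_{SNP \times age} m_{1j} + \beta_{SNP \times age^2} m_{2j} +
  \beta_{SNP \times age^3} m_{3j} + \xi_j + \eta_j$ with residual
  heterogeneity $\tau^2_{res}$ (REML) and generalized least squares for
  the coefficients.

The moderators are the study-level moments of centred age, recoverable
from the reported mean and SD alone (`derive_age_moments()`):
$m_1 = \bar a - c$, $m_2 = SD^2 + (\bar a - c)^2$, and
$m_3 = (\bar a - c)^3 + 3(\bar a - c)SD^2$.  The $m_2$ identity is exact
up to the $n$ vs $n-1$ variance denominator; cohort sizes make the
difference negligible, and the reported sample SD is used as-is.  The
$m_3$ formula assumes zero within-study age skewness — exact for uniform
or any symmetric age distribution; a `mean_age3` column overrides it when
the raw third moment is available.

Why this recovers interactions: in a large age-adjusted study the
per-allele coefficient converges to $\beta_{SNP} + \beta_{SNP\times age}
\overline{a}_j + \beta_{SNP \times age^2} \overline{a^2_j}$, so the
between-study variation of mean age identifies the interaction terms.
Consequently a collection whose study mean ages coincide carries no
information about them; `meta_regression()` raises a collinearity error
naming the offending moderator in that case rather than returning an
unstable fit.

### Centring

With centre $c$, the intercept is the genetic effect at age $c$ and the
linear coefficient is the slope of the effect-by-age curve at $c$.  Under
recentring the top-degree coefficient is invariant and the lower-order
coefficients transform by the exact binomial shift — e.g. for a quadratic
model the slope at $c$ is $\beta_{SNP\times age} + 2c\beta_{SNP\times
age^2}$.  The fitted curve itself (`predict_effect_at_age()`) is
centring-invariant; prediction uses plain powers of $(age - c)$, because
the derived moments stand in for study-level expectations during fitting
only.  The intercept SE is minimised at the inverse-variance weighted
mean age (`weighted_mean_age()`, weights $1/s_j^2$), which is also the
age at which a plain meta-analysis estimate is interpretable when the
effect changes at most linearly with age.

### Heterogeneity

`heterogeneity()` reports Cochran's $Q = \sum_j (y_j - \hat y_j)^2/s_j^2$
with fitted values from the fixed-effect-weighted (moderator) regression,
and $I^2 = \max(0, (Q - df)/Q) \times 100$.  For moderator models these
are residual statistics, so the drop in $I^2$ from the intercept-only fit
to the age-moment fit measures how much heterogeneity age explains.

### Overlapping samples

When one cohort contributes estimates at several measurement ages the
rows are correlated.  `build_covariance()` assembles the block-diagonal
covariance with within-cohort correlations $r_{jk} = \min(n_j,
n_k)/\sqrt{n_j n_k}$ by default (complete containment of the smaller
occasion), or any user-supplied correlation structure;
`gls_meta_fit()` then solves the generalized least squares problem with
weight matrix $(\Sigma + \tau^2 I)^{-1}$, estimating $\tau^2$ by REML on
the eigenbasis-whitened problem.  A diagonal $\Sigma$ reproduces the
independence fits exactly.  Two subtleties are worth knowing:

* Acknowledging shared participants can only *lose* information about the
  effect at a single age, so the pooled-effect SE never shrinks.  But
  positively correlated occasions make within-cohort *contrasts* more
  precise, so interaction-coefficient SEs can legitimately decrease —
  the adjustment is not a uniform inflation.
* Perfectly correlated duplicated rows carry a zero-variance,
  zero-information component that is dropped from the whitened problem;
  perfectly correlated rows that *disagree* make the weight matrix
  irreparably singular and raise an error with the condition number.

## The simulator

`simulate_collection()` generates individual-level multi-study data under
five nested scenarios for the phenotype of participant $i$ in study $j$
(switches in `scenario_spec()`): linear age effect and genotype
(scenario 1), plus a linear SNP-by-age interaction (2), plus a quadratic
age main effect (3, 4), plus a quadratic interaction (5).  The genotype
coefficient receives a study-level random shift $u_j \sim N(0,
\sigma^2_{between})$ — a shift of the SNP coefficient only, not of the
age terms.  Defaults are the base-case parameterisation: baseline 25,
age effect 0.010/yr, quadratic age 0.001, main effect 1.5 per allele,
linear interaction 0.020, quadratic interaction 0.001, unit within- and
between-study SDs, MAF 0.2, 40 studies of 1000 participants with ages on
10–59 years.

Age diversity is controlled by the overlap percentage: per-study windows
of equal width $w = span/(1 + (k-1)(1-p))$ with centres spaced
$w(1-p)$, so adjacent windows share the fraction $p$ of their width —
0% tiles the range disjointly (high diversity of study mean ages), 100%
makes every window the full range.  Explicit per-study windows can be
supplied to reproduce any published design.  Ages are continuous uniform
within the window.  One root seed spawns per-study sub-streams, so a
change to one study's size never perturbs another study's draws.

What the simulator does *not* emulate: genotyping error, LD and
multi-SNP architecture, binary traits, non-uniform or skewed within-study
age distributions, informative study sizes (e.g. older cohorts being
systematically smaller), or participant overlap between *different*
cohorts.  Passing calibration tests therefore demonstrates correctness of
the estimators under the stated sampling model, not robustness to those
real-data features.

## The Monte Carlo harness

`run_cell()` simulates one design cell repeatedly, reduces each study
with `fit_study()`, applies each estimator (`fe`, `re`, `mr1`, `mr2`,
`mr3`), and records per-replicate estimates, SEs and CIs; failures are
recorded per replicate, never silently dropped.  `summarise_replicates()`
computes the five standard performance measures — mean, bias, 95% CI
coverage, empirical SE, mean reported SE — each with its Monte Carlo
standard error (bias: $EmpSE/\sqrt{R}$; coverage: $\sqrt{p(1-p)/R}$;
EmpSE: $EmpSE/\sqrt{2(R-1)}$).  Truth values for each estimand are
*derived* from the generating parameters and the centring
(`true_effects()`): the effect at age $c$, the curve slope at $c$
($\beta_{SNP\times age} + 2c\,\beta_{SNP\times age^2}$), and the
quadratic coefficient — never entered by hand.  `run_grid()` crosses
factor levels into independent cells with derived sub-seeds; because
replicate sub-seeds are drawn in a single block, the first $R$
replicates of a longer run reproduce a shorter run exactly, so the full
published-scale grid (1000 replicates, study counts 10–80, sizes
1000–10000, SDs 1–3, five overlap levels) is purely a configuration
change.  The package's own calibration checks use $R = 500$ replicates
of the base-case cell per scenario, which resolves coverage to about
$\pm 1$ percentage point and keeps a full run within a few minutes on
one CPU; those sizes are the package's chosen defaults, with
$R = 1000$ available by configuration.

Calibration results the test suite verifies at those sizes: both
meta-analyses and both meta-regressions are unbiased when no interaction
exists; under a linear interaction the meta-analyses estimate the effect
at the weighted mean age (so their CIs for the age-10 effect
under-cover badly) while degree-1 meta-regression is unbiased with
nominal coverage; under a quadratic interaction only the degree-2 model
is unbiased; fixed-effect mean SEs understate the empirical SE whenever
$\sigma_{between} > 0$ while REML random-effects SEs track it; and
age-diverse (0% overlap) collections estimate the main effect more
precisely than fully overlapping ones.

## The applied pipeline

`run_applied()` ingests a cohort-by-occasion summary table (CSV with
columns `cohort_id, occasion_age, beta1, se, n`; an XLSX supplement can
be converted by mapping exactly those columns), runs the fixed-effect
meta-analysis, a cubic uncentred meta-regression with overlap-adjusted
weights, reports $I^2$ before and after the age moderators, and exports
the signed effect-by-age curve.  Occasion rows use the occasion age as
the mean age with `sd_age = 0` unless per-occasion SDs are supplied, so
the moments collapse to pure powers of age.  The report prints both the
summed per-occasion sample size and the summed per-cohort maximum
(approximate unique participants), labelled, because the two counts
differ under repeated measurement.

`emulate_applied_table()` generates a synthetic table of that shape — 8
cohorts of 569–7482 participants, 10 occasions on ages 0–13 — whose true
per-allele effect follows a built-in cubic that is negative before age 3
and positive after age 5.5 with a single sign change between.  The cubic
coefficients (−0.07, 0.005, 0.0032, −0.00014) were chosen so that the
truth clears zero by at least three fitted-curve standard errors at both
boundary ages given the cohort sizes; with smaller margins the sign
pattern would be a coin flip on any finite synthetic table and the
pipeline test would be uninformative.  This table is synthetic: it
exercises the pipeline's behaviour, it does not reproduce any published
cohort's numbers.

## Numerical choices

* **REML**: 1-D profile of $\tau^2$ by bounded derivative-free search
  (`optimize`, tolerance $10^{-8}$, upper bound $10^3 \times
  \max(s_j^2, var(y))$), polished by solving the analytic restricted
  score equation with `uniroot` (tolerance $10^{-12}$) — value-based
  search alone localises the maximiser only to $\sqrt{\epsilon}$, which
  is visible as non-reproducibility under recentring.  Negative
  solutions truncate at 0; a non-finite restricted likelihood raises an
  error rather than returning silently.
* **Linear algebra**: all weighted solves equilibrate columns first; raw
  cubic moments reach $\sim 10^5$ and the normal equations are otherwise
  ill-conditioned.  One step of iterative refinement follows.
* **Confidence intervals**: Wald with $z_{0.975}$ by default.  The
  Knapp–Hartung small-sample adjustment ($t$ critical values, scaled
  covariance, truncation at 1) is available via `knapp_hartung = TRUE`
  but off by default: the plain-Wald under-coverage with few studies is
  a documented property of the method being studied, not a defect to
  patch silently.
* **Degenerate inputs**: monomorphic-SNP or constant-age studies are
  dropped deterministically with a warning; zero-residual studies are
  returned with `se = 0` and flagged; non-PSD user correlation blocks
  are projected to the nearest PSD matrix (eigenvalue clipping) with a
  warning reporting the adjustment size; `Q = 0` yields $I^2 = 0$.

## Limitations

Single-variant focus (no genome-wide looping, LD or multi-SNP models);
quantitative traits only; polynomials up to degree 3 (no splines);
overlap correlations are supplied or rule-derived, never estimated from
individual-level data; and exact replication of any published
application requires that publication's per-cohort table — the bundled
synthetic table checks behaviour, not published numbers.  Meta-regression
pays for its flexibility with wider intervals when no age-varying effect
exists, and with few or age-homogeneous studies it has little power —
with identical study mean ages, none at all.
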