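---
title: "Methods: simulating and estimating genetically informed returns to schooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating genetically informed returns to schooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

The target parameter is the causal return to a year of schooling on
prime-age earnings. The package implements the standard identification
ladder: covariate-adjusted OLS (biased by any unobserved confounding),
sibling and twin fixed effects (immune to family-shared confounding,
still exposed to individual-level confounding), and Mendelian
randomization (MR), which instruments schooling with a polygenic index
(PIV) built from education-associated SNPs. MR is valid under the usual
IV assumptions: relevance (A1), independence of the instrument from
outcome confounders (A2), exclusion — no pathway from the SNPs to
earnings except through schooling (A3) — and monotonicity (A4). Sibling-MR
adds family fixed effects to the IV stages so the identifying variation is
the meiotic lottery within sibships, which is random conditional on the
parental genotypes; a within-sibling family-based GWAS (FGWAS) instead
re-estimates the SNP weights free of family-level confounding and applies
them on a disjoint unrelated sample.

Because the registry and cohort microdata such designs require are
access-restricted, the package's empirical surface is a simulator whose
causal and confounding structure contains each threat the estimators are
meant to address, so every robustness claim is a testable property of a
known data-generating process.

# The generative model

`simulate_population()` draws, in order:

1. **SNP panel** (`draw_snp_panel`): `n_snps` (default 335) independent
   biallelic SNPs with effect-allele frequencies uniform on
   `allele_freq_range` (default 0.05–0.95). True per-allele schooling
   effects `t_j` are scaled so that the true polygenic score has standard
   deviation `pi_first_stage` (default 0.26 years) under Hardy–Weinberg at
   the base frequencies. The *score weights* actually used to build the
   index are `w_j = t_j + sd(t)(c_e e_j + c_d eta_j + c_s v_j)`:
   estimation noise (`weight_noise`, default 0.2), plus optional
   contamination by the per-SNP nurture effects `eta_j`
   (`weight_dynastic`) and the stratification direction `v_j`
   (`weight_strat`) — a population GWAS absorbs indirect and structure
   effects into its weights, a within-family GWAS does not. The vectors
   `eta` and `v` are orthogonalized against `t` within the panel: their
   independence from the direct effects is an assumption of the designs
   under study, and imposing it exactly removes finite-panel chance
   alignment that would confound even an ideal within-family analysis.
2. **Parents** (`simulate_parent_pairs`): genotypes binomial at the
   subpopulation frequencies; spousal assortment by Gaussian-copula rank
   matching on the parental index to a target correlation
   `rho_assortative`; parental education, log earnings and ages at first
   birth generated from the parental true scores (these feed the analysis
   covariates and the between-family balance signal).
3. **Offspring**: sibship sizes from `offspring_dist` (default 40/45/15%
   for 1/2/3 children), twin pairs with probability `twin_prob` (MZ share
   `mz_share`), Mendelian transmission with each transmitted allele
   Bernoulli(g/2) — MZ co-twins duplicate one meiosis. A heritable latent
   ability (midparent mean plus segregation, so MZ correlate 1 and DZ/sibs
   0.5), an individual environment confounder, a family environment with a
   birth-year drift component (shared by twins, not by age-spaced
   siblings), and a genetic-nurture score `N = (G_m + G_f)'eta` complete
   the latent structure.
4. **Schooling** (`generate_schooling`): latent
   `S* = 13 + pi (1 + hetero_first_stage * gain) T_std + (channel loadings) + noise`,
   rounded and clipped to 6–23 years. The `gain` modifier also raises the
   individual earnings return (`hetero_kappa`), so when
   `hetero_first_stage > 0` instrument compliers have above-average
   returns — the complier-averaging explanation for MR exceeding OLS.
5. **Earnings** (`generate_earnings_panel`): zero before labor-market
   entry at age `S + 7`; afterwards log-normal around a Mincer profile in
   potential experience `x = age - S - 7`:
   `log y = 11.2 + 0.1292 x - 0.0038 x^2 + beta_i S + channels + noise`,
   with `beta_true = 0.08` log points per year.

## Calibration of the experience profile

The slope and curvature are tied together: the profile peaks at
`x* = slope / (2 curvature) = 17` years of experience, i.e. around age 37
for 13 years of schooling — the middle of the prime-age measurement
window (mean of the top three earnings years over ages 34–40). Placing the
peak there makes the experience drag of additional schooling average to
zero across the window, so the measured prime-age return equals
`beta_true` and the estimator-recovery experiments have a well-defined
target. The same parameters put the crossover at which high-schooling mean
earnings overtake low-schooling earnings at about age 27, and age-specific
returns are negative before it and positive after — the life-cycle shape
the estimators are probed against. Prime-age levels are scaled so median
prime-age earnings are in the hundreds of thousands (NOK-like units).

## What the simulator does and does not emulate

It emulates the features the estimators interact with: Mendelian
transmission and the within-family lottery, MZ/DZ structure, integer
schooling with floor/ceiling, panel earnings with entry timing and a
concave experience profile, family-level and individual-level confounding,
directional and balanced pleiotropy, assortative mating, discrete
stratification, and cohort self-selection at the family level
(`genotyped_prob`, optionally earnings-graded). It does not emulate
linkage disequilibrium, genotyping error or missingness, real earnings
distributions beyond qualitative shape, taxes or institutional detail, or
time-varying macro effects. Passing tests therefore demonstrate internal
validity of the estimators against these mechanisms, not performance on
real registry data.

# Estimators and inference

`fit_returns()` partials the covariate design out of outcome, exposure and
instrument (Frisch–Waugh–Lovell), demeans within family for the
fixed-effects variants (dropping covariates that are constant — or, like
parental age at birth against birth year, collinear — within families),
and computes the just-identified ratio estimator with a cluster-robust
sandwich variance using the `G/(G-1) * (n-1)/(n-k)` correction; `k` counts
absorbed fixed effects. The default clustering follows the reporting
convention of the field: the family-by-birth-cohort intersection for
within-family models, birth cohort otherwise; one-way on any variable and
two-way by inclusion–exclusion are available. Confidence intervals use a
t distribution on `G - 1` degrees of freedom. Anderson–Rubin intervals
invert the cluster-robust test that the instrument coefficient is zero in
a regression of `Y - b S` on the instrument; endpoints are found by
bisection from a bracket of ±10 Wald standard errors, doubled until the
statistic crosses its critical value (ten doublings, then the side is
declared unbounded rather than erroring).

The summary-level suite follows the standard formulations: IVW as the
weighted mean of per-SNP Wald ratios with weights `gamma^2 / se(Gamma)^2`
and multiplicative random-effects dispersion floored at 1; Egger as WLS
with intercept; the weighted median by interpolation of the standardized
cumulative weights at 0.5 with a parametric bootstrap SE (default 1,000
draws); the mode with a normal kernel and a modified Silverman bandwidth
`0.9 min(sd, mad) n^(-1/5)` times `bandwidth_factor`, ties broken toward
the peak with more nearby weight and flagged; ranked-strength (core-gene)
grouping into 10 groups by default, reporting the core-group IVW and the
cumulative trajectory. Harmonization orients every SNP so the exposure
association is nonnegative — the convention Egger requires; all estimators
are invariant to allele re-coding and SNP order.

## FGWAS weight uncertainty

The Norway-only-style instrument is built from *estimated* within-family
SNP effects. Conditional on those weights the 2SLS standard error
understates the procedure's dispersion (a generated-regressor problem):
chance alignment between weight noise and the nurture or structure effects
perturbs the estimate beyond the sampling noise the fit sees. `fgwas_mr()`
therefore redraws the weights from their FGWAS sampling distribution
(default 50 draws), recomputes the estimate per draw, and adds the
dispersion in quadrature to the conditional standard error. Relatedly, the
within-family GWAS needs per-SNP signal-to-noise well above one for the
instrument to be mostly signal; the family-channels experiment below uses
60 SNPs with a ~20,000-sibship discovery sample so that the per-SNP
F statistics are comfortably large, rather than the 335-SNP default whose
per-SNP effects would be mostly estimation noise at that discovery size.

# Sensitivity, decomposition, life cycle

The union-of-CI sensitivity analysis re-estimates the IV model with the
outcome replaced by `Y - delta Z` over a grid of hypothesized direct
effects per SD of the instrument (default 201 points from 0 to 1.5 times
the reduced form), takes the envelope of the per-delta Wald (or AR)
intervals, and locates the breakdown `delta` where the lower bound reaches
zero by bisection (tolerance 1e-4 of the reduced-form scale; if the lower
bound is non-monotone on the grid the first grid crossing is used and
flagged). With one instrument the adjusted estimate obeys
`beta(delta) = beta - delta / first stage` exactly, which the tests verify
to 1e-8.

The IV–OLS gap decomposition uses covariance weights: margin weights
proportional to `cov(s_res, 1{S >= s})` (OLS) and `cov(z_res, 1{S >= s})`
(IV), stratum weights proportional to `P(x) var(s_res | x)` and
`P(x) cov(z_res, S | x)` over sex-by-parental-earnings-quartile strata.
The covariate component evaluates the weight difference at stratum OLS
effects, the margin component the within-stratum margin-weight differences
at margin increments (margins pooled until at least 30 observations sit on
each side), and the residual — confounding plus complier-vs-population
averaging, which the method cannot separate — is the remainder, so the
three components sum to the gap identically. The sequencing (covariate
component first) is a reporting convention; `order = "margin_first"` swaps
it. The monotonicity check passes when all stratum IV weights are
nonnegative (the testable implication used in practice); per-margin IV
weights at sparsely populated schooling levels are noise-dominated in
finite samples, so they are reported for inspection and enter the pass
criterion only on request.

Age-specific returns fit the chosen estimator with each age's absolute
earnings (zeros retained) as the outcome; lifetime return is the
undiscounted mean over ages; the IRR solves
`sum_a beta_a (1+r)^{-(a - a_min)} = 0` by bracketed root finding
(tolerance 1e-6) with a sign-change scan over (-0.9, 10), warning and
returning the root nearest zero if the profile changes sign more than
once. Education is profitable when the IRR exceeds the 2.3% real market
rate used as the default comparison.

# Experiment designs (study conditions)

The acceptance experiments fix these conditions; seeds are constants in
the test code.

* **Null recovery**: 28,500 families (~50,000 offspring), 335 SNPs, all
  channels off. OLS, sibling FE, DZ and MZ twin FE, MR and sibling-MR all
  recover `beta_true = 0.08` within three standard errors.
* **Ability confounding**: loadings +0.8 on schooling and -0.25 on log
  earnings (the negative individual-level confounding story: high
  earnings potential at low schooling). OLS is biased far beyond its
  standard error; MR is not.
* **Family channels**: dynastic loadings 0.4/0.10 with weight
  contamination 0.8, assortment 0.3, two subpopulations with frequency
  offsets 0.03 and earnings offsets 0.15 with weight contamination 0.5;
  30,000 families weighted toward sibships so the genotyped discovery
  sample holds roughly 16,000 sibships. Population MR is biased;
  sibling-MR and FGWAS-based MR recover the truth within three (weight-
  uncertainty-inflated) standard errors.
* **Pleiotropy**: (i) 100 SNPs with 35% carrying directional direct
  effects (mean 0.025 per allele) — about 40% of IVW weight is invalid,
  IVW is biased, the weighted median is not; (ii) 35 SNPs at 50,000
  individuals, all with directional direct effects (mean 0.015)
  independent of instrument strength (InSIDE) — the Egger slope stays on
  target and the intercept interval excludes zero.
* **AR coverage**: 500 replicates of 1,500 independent genotyped
  individuals, 20 SNPs; the 95% AR interval covers the true return in
  95% ± 3% of replicates. Individuals are independent by design, so
  clustering is at the individual level here.
* **Preset `"composite"`**: adds heritable ability (+0.8/+0.15), family
  environment (0.6/0.2) with birth-year drift 0.6, a twin-shared schooling
  environment (0.8), and complier heterogeneity (kappa 0.02,
  responsiveness 0.5), chosen from the bias algebra so the qualitative
  ordering MZ-FE < DZ-FE < sibling-FE < OLS < MR emerges — the pattern the
  estimator comparison is designed to explain.

# Numerical and degenerate-input choices

Standardization of a constant score returns zeros rather than NaN (a null
first stage is a legal configuration). Zero-variance covariates are
absorbed by the intercept with a record; genuinely collinear non-constant
designs raise an error naming the pivot columns. Monomorphic SNPs are
dropped from association scans; SNPs without within-family variation are
omitted (not zero-filled) from FGWAS weights; discovery/estimation family
overlap is a hard error. The breakdown share and reporting conversions
round half-up (0.5 away from zero), matching printed one-decimal
percentages. Bootstrap and weight-redraw counts default to 1,000 and 50,
reduced in tests where only determinism or point values are at stake.

# Limitations

The simulator's independence assumptions are imposed exactly (orthogonal
nurture/stratification directions), so it cannot by construction probe
violations of InSIDE-type assumptions beyond the planted magnitudes; the
genotyped-unrelated estimation sample consists of singleton families, a
simplification of kinship-threshold filtering; assortment is single-
generation (no equilibrium gametic-phase disequilibrium); and the
decomposition's component attribution depends on the chosen sequencing, as
documented. Within-family clustering defaults mirror a reporting
convention rather than a single "correct" level; both alternatives are one
argument away.
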