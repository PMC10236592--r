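---
title: "Pedigree-based genetic analysis of nutrient-efficiency traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based genetic analysis of nutrient-efficiency traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effigen)
```

## The problem

Protein efficiency (PE) in growing-finishing pigs is the proportion of total
dietary crude-protein intake that a pig retains in its carcass between
experiment start (~20 kg live weight) and slaughter (~106 kg). Phosphorus
efficiency (PhE) is the analogous ratio for phosphorus. Selecting for these
ratios promises less nitrogen and phosphorus excretion per kg of pork, but
selection is only worthwhile if the traits are heritable and not
antagonistic with the production and meat-quality traits already in breeding
goals. This package implements the full analysis chain needed to answer
those questions from raw records: phenotype derivation, pedigree
relationship matrices, REML animal models with litter effects, bivariate
models for genetic correlations, AIC screening of fixed-effect structures,
and a sensory mixed model — plus a synthetic-data generator so that every
stage can be validated end to end against known truth.

## Phenotype derivation

Carcass composition comes from a dual-energy X-ray absorptiometry (DXA) scan
of the left cold carcass half. Published prediction equations convert the
scan to retained masses, with `P` the left half's share of the total cold
carcass weight:

$$CP_{carcass}\,(g) = -482.745 + 0.23\,(Lean_{DXA} \times P)$$
$$Ph_{carcass}\,(g) = -6.388 + 0.109\,(BMC_{DXA} \times P) + 0.004\,(Lean_{DXA} \times P)$$

Efficiencies subtract the composition the animal brought into the
experiment, estimated as sex-specific per-kg contents multiplied by the
start weight, and divide by the recorded nutrient intake:

$$PE = \frac{CP_{slaughter} - CP_{start}}{CP_{intake}}.$$

The per-kg baseline contents were chemically measured on 38 piglets in the
original work but never published; `default_baseline()` therefore carries
placeholder values (~31 g protein and ~4.6 g phosphorus per kg live weight)
chosen only for scale plausibility, and every quantitative result in the
package's tests is either insensitive to them or supplies explicit values.
Users with measured baselines should pass their own `baseline_composition`.

Performance traits use the growth period between the start of the grower
phase and slaughter: `ADG = (BW_slaughter - BW_start) / (age_slaughter -
age_start)`, `ADFI = total feed / duration`, and `FCR = ADFI / ADG` (so
`FCR * ADG == ADFI` holds to machine precision by construction). Water
holding is measured as drip loss `(w1 - w2)/w1 * 100` and cooking loss
`(w2 - w3)/w2 * 100` on a loin chop. Because slaughter age and slaughter
weight are strongly collinear, the models use the residual of age regressed
on weight (`rAgeLW`, `residual_age()`) in place of raw age.

Quality control flags — efficiencies outside (0, 1), non-positive predicted
carcass masses, negative losses — are reported, never silently dropped;
`drop_flagged = TRUE` makes dropping explicit.

## The animal model

For each trait the univariate model is

$$y = Xb + Z_a a + Z_c c + e, \qquad
  a \sim N(0, A\,\sigma^2_A),\;
  c \sim N(0, I\,\sigma^2_{CE}),\;
  e \sim N(0, I\,\sigma^2_R),$$

where `A` is the pedigree numerator relationship matrix computed by the
tabular recursion (`additive_relationship()`): processing animals with
parents before offspring, $a_{ii} = 1 + a_{sd}/2$ and $a_{ij} = (a_{js} +
a_{jd})/2$. Unknown parents are unrelated, non-inbred base-population
founders. The litter (common-environment) term is included for the
efficiency and performance traits, which are measured on the full pedigreed
cohort; carcass traits measured on a single-treatment subset omit it,
matching the original analysis. Heritability is $h^2 = \sigma^2_A /
(\sigma^2_A + \sigma^2_{CE} + \sigma^2_R)$ and the litter effect
$CE^2 = \sigma^2_{CE} / \sigma^2_P$.

Bivariate models give each random term an unstructured 2x2 covariance
matrix; genetic correlations rescale the additive covariance,
$r_g = \mathrm{cov}_A / \sqrt{V_{A1} V_{A2}}$, and phenotypic correlations
rescale the summed covariances. Records missing one trait are retained for
the other: the restricted likelihood is taken over the observed entries
only, which matters because meat-quality traits exist for roughly half the
cohort.

## The REML engine

Variance components are estimated by maximising the restricted
log-likelihood

$$\ell_R = -\tfrac12\left(\log|V| + \log|X'V^{-1}X| + y'Py\right)$$

with dense average-information (AI) updates: the update direction is
$\mathrm{AI}^{-1}g$ with analytic gradients, step-halved until the
restricted likelihood does not decrease. When a proposed step leaves the
parameter space or the AI system is singular, the engine falls back on the
expectation-maximization-style update
$\theta_k \leftarrow \theta_k + \theta_k^2 q_k^{-1}(y'PQ_kPy -
\mathrm{tr}(PQ_k))$, which is monotone; a vanishing EM gain is accepted as a
boundary optimum. Numerical choices, all visible as arguments:

* convergence at $|\Delta\ell_R| < 10^{-8}$ together with relative component
  changes below $10^{-6}$, or three consecutive flat-likelihood iterations
  (which occur only when a parameter rides a boundary); at most 200
  iterations;
* variances bounded below by $10^{-6}\times$ the phenotypic variance of the
  OLS residuals; correlations clamped to $[-0.999, 0.999]$ and flagged when
  they finish at the cap;
* starting values split the OLS phenotypic variance 1/3 to the additive
  term, 1/10 to each further random term, remainder to the residual;
  bivariate covariances start at half the geometric mean of the
  corresponding variance starts;
* when a covariance sits at the correlation cap with the gradient pointing
  outward, the AI step is taken along the cap manifold
  ($a_{12} = \pm 0.999\sqrt{a_{11}a_{22}}$) via a chain-rule Jacobian, and
  variances stuck at the lower bound with outward gradients are frozen out
  of the step. Without this the optimiser creeps along the boundary for
  hundreds of iterations.

Dense linear algebra is a deliberate choice: at the study scale (~1.5k
pedigree entries, ~1071 records, ~2.1k stacked observations bivariate) a
dense Cholesky factorisation takes well under a second, and the A-matrix
inverse is never needed explicitly. The engine is generic over random terms
with known covariance structures, which is how the sensory model (judge and
session, identity structures) reuses it.

Standard errors of components come from the inverse AI matrix at
convergence; SEs of heritabilities, litter shares and correlations use a
first-order delta-method expansion. The original analysis does not state
how its software computed ratio SEs; the delta method is the standard
first-order choice and is validated here against a parametric bootstrap
(agreement within 25% on the designs tested). An optional one-sided
likelihood-ratio test against the boundary null $\sigma^2_A = 0$
(`lrt = TRUE`, p-value from the $\tfrac12\chi^2_1$ mixture) stands in for
the unspecified significance labels on published variance components.

## Fixed-effect screening

Before the animal models, the fixed-effect structure is screened by
all-subsets OLS with `dredge_aic()`: every subset of the candidate terms
that respects marginality (an interaction only with both main effects),
ranked by $AIC = -2\ell + 2k$ with $k$ counting coefficients plus the
residual variance. The top set is every model within delta AIC < 2; the
single best model's terms are what the animal models use, with AIC ties
broken by fewer parameters and then term order (the source analysis is
silent on ties). Screening is per trait, since the retained interactions
differed between meat-quality traits in the original study. A guard refuses
more than $2^{20}$ candidates.

## Sensory analysis

Panel scores (0-10 line scale) are modelled per attribute as

$$Y = \mu + Session + Judge + Sex + PE\,group + Fat\,thickness +
\varepsilon$$

with judge and session random (identity structures, same REML engine) and
the rest fixed. Fisher's LSD separates the protein-efficiency group means:
adjusted means average model predictions over the other fixed factors with
equal weight, and a pair differs when the difference exceeds
$t_{1-\alpha/2,\,df}\sqrt{2\,MS_{error}/n_{eff}}$. Two conventions are
undocumented in the source and chosen here explicitly: $n_{eff}$ is the
harmonic mean of the two group sizes (unbalanced groups), and $df$ is the
residual degrees of freedom of the fixed-effect projection, $n -
\mathrm{rank}(X)$ — an approximation to whatever the original commercial
tool used; at this data scale the conclusions are insensitive to either
choice. A compact letter display summarises the separation.

## The synthetic-data generator

The generator exists so that the whole pipeline can be validated against
known truth while the study's raw data remain embargoed. Its defaults *are*
the study conditions:

* **Pedigree**: 39 sires and 79 dams produce 118 litters (48 dams with one
  litter, 23 with two, 8 with three) across 14 farrowing series; litter
  sizes are Poisson with mean 9.08, giving ~1071 phenotyped offspring. The
  parent generation descends from a founder layer sized so the whole
  pedigree is ~1.4k animals (three generations), matching the reported
  pedigree scale.
* **Traits**: the five efficiency/performance traits carry the published
  additive, litter and phenotypic variances; residual variances are the
  remainders. Genetic correlations are the published estimates. Litter and
  residual correlations are not published: litter correlations are set
  equal to the phenotypic ones and residual covariances derived as
  $\mathrm{cov}_P - \mathrm{cov}_A - \mathrm{cov}_{CE}$, eigen-clipped to
  positive semi-definite if a user-modified configuration requires it (the
  defaults do not).
* **Breeding values** descend the pedigree by recursive Mendelian sampling:
  founders $N(0, G_a)$, offspring = parent average + a deviation with
  covariance $\tfrac12 G_a (1 - (F_s + F_d)/2)$ using exact inbreeding
  coefficients — linear cost in pedigree size and exact under inbreeding,
  unlike a whole-matrix factorisation.
* **Fixed effects**: the gap between the published phenotypic SDs of the
  pooled data and the model variances is allocated to sex, treatment, year,
  slaughter-weight and temperature effects (shares 0.3/0.2/0.2/0.2/0.1),
  with level effects standardised so the allocation is exact. Covariates
  are drawn from independent marginals — the source gives no joint
  distribution.
* **Observables** are back-generated by inverting the derivation formulas
  (duration from ADG, feed from ADFI, DXA masses from the carcass
  equations), so `derive_phenotypes()` reproduces the simulated traits to
  machine precision. This is intentional: the acceptance surface is
  pipeline correctness, not growth physiology, so no attempt is made to
  model feed-intake trajectories or growth curves. Because the published
  carcass-protein equation is used exactly as printed, the back-solved DXA
  lean masses are larger than a physical half-carcass lean mass would be;
  they are consistent placeholders, not biology.
* **Water-holding traits** (drip and cooking loss) are generated for a
  509-animal carcass subset with their own two-trait additive architecture
  on the shared pedigree and no litter term, then back-generated into chop
  weights. Their genetic correlations with the efficiency traits are *not*
  simulated: the published tables do not pin down a complete joint
  seven-trait covariance, and inventing one would add assumptions the
  validation does not need.
* **Sensory data** are simulated independently with their own judge,
  session and group-effect configuration, mirroring the published pattern
  (a juiciness difference for the high-PE group, nothing elsewhere).

What passing tests on this generator do **not** show: robustness to real
DXA measurement error, selection or non-random mating, genotype-by-diet
interaction, non-normal trait distributions, or missingness that is
informative rather than structural. They do show that every formula,
matrix, and estimator in the chain is internally correct and that the
estimators recover known parameters at the study's design scale.

## Validation strategy and problem sizes

Each computational stage is checked against an independent oracle: the
relationship matrix against gene-dropping Monte-Carlo IBD estimates;
univariate REML against the closed-form balanced half-sib ANOVA components
and against a brute-force likelihood grid on an 8-animal pedigree; delta
SEs against a 200-draw parametric bootstrap; the subset enumeration against
a hand count; the LSD test against pairwise t-tests in the fixed-effects
limit; the generator against quantitative-genetic identities (Mendelian
variance, full-sib covariance, offspring-midparent regression).

Parameter-recovery suites run at two scales, chosen as a compromise between
statistical resolution and a test suite that runs in minutes: univariate
recovery on a reduced design (~12 sires, ~200 offspring, 20 replicates),
and bivariate genetic-correlation recovery at the full study shape (~1071
offspring, 20 replicates), the latter also re-run by
`scripts/acceptance.R`. At the study's design scale a bivariate genetic
correlation is estimated with an SE of roughly 0.15-0.2 per replicate —
matching the precision the original study reports — so means over 20
replicates still move by a few hundredths between seed batches, and REML
correlation estimates at a true value of 0.61 carry a small finite-sample
attenuation toward zero from replicates where an additive variance
collapses to its boundary. The recovery tolerance (±0.05 on the mean) sits
deliberately at the edge of that precision.

## Known limitations

* Two traits per bivariate model; no multi-trait (>2) or maternal-effect
  models, no genomic relationships, no Bayesian sampling.
* The LSD degrees-of-freedom and $n_{eff}$ conventions are documented
  approximations, not a reimplementation of the original tool's internals.
* The baseline composition defaults are placeholders (see above).
* Dense algebra bounds practical pedigree size at a few thousand animals;
  million-animal evaluations need sparse mixed-model machinery out of scope
  here.
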