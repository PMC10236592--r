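# effigen

Quantitative-genetic analysis of nutrient-efficiency traits in
growing-finishing pigs: from raw feeder and carcass-scan records to
heritabilities, litter effects and genetic correlations.

## The problem

Protein efficiency (PE) — the share of dietary crude protein a pig retains
in its carcass between ~20 kg and slaughter — and its phosphorus analogue
(PhE) are sustainability traits: more efficient pigs excrete less nitrogen
and phosphorus per kg of meat. Whether breeding can improve them depends on
(i) deriving the phenotypes correctly from feeder records and dual-energy
X-ray (DXA) carcass scans, (ii) estimating their heritability and the
litter (common-environment) share with a pedigree animal model, and (iii)
checking for trade-offs with production and meat-quality traits via genetic
correlations. `effigen` implements that entire chain, together with a
sensory-panel mixed model and a synthetic-data generator that reproduces
the study's pedigree and trait architecture so every stage is testable
without the embargoed raw data.

The core model is the animal model

```
y = Xb + Z_a a + Z_c c + e,   a ~ N(0, A V_A),  c ~ N(0, I V_CE),  e ~ N(0, I V_R)
```

with `A` the pedigree numerator relationship matrix. Variance components
are estimated by a from-scratch average-information REML engine (dense
algebra, EM fallback, boundary-aware steps), univariately and bivariately
(unstructured 2x2 covariances, records missing one trait retained). Derived
parameters: `h2 = V_A/V_P`, `CE2 = V_CE/V_P`, `r_g = cov_A/sqrt(V_A1 V_A2)`,
`r_p` from the summed covariances, all with delta-method standard errors.
Fixed-effect structures are screened beforehand by all-subsets AIC with
marginality (`dredge_aic()`), and sensory scores get a judge/session mixed
model with Fisher's LSD group separation.

## Worked example

Simulate a study-shaped dataset (≈1071 phenotyped pigs in 118 litters from
39 sires and 79 dams, three-generation pedigree of ≈1.45k animals), derive
the phenotypes from the raw records, and fit the PE animal model:

```r
library(effigen)

cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)
d   <- derive_phenotypes(sim$records)

fit <- fit_animal_model(
  d$phenotypes, "pe",
  ~ sex + treatment + year_of_change + slaughter_bw + temperature,
  sim$pedigree, litter = "litter_id")
fit
#> REML fit: 1041 records, 17 fixed-effect columns
#> restricted logL: 3099.471185 (converged in 9 iterations)
#>  component   estimate       se boundary
#>     animal 7.8444e-04 1.77e-04    FALSE
#>     litter 1.3132e-05 3.44e-05    FALSE
#>   residual 2.8739e-04 9.42e-05    FALSE
fit$parameters
#>   parameter trait    estimate           se
#> 1        h2    pe 0.723011804 1.187404e-01
#> 2       ce2    pe 0.012103733 3.184835e-02
#> 3        vp    pe 0.001084961 8.233156e-05
```

The heritability estimate (0.72 ± 0.12 on this replicate) scatters around
the generating value `h2 = 5.2e-4 / 9.6e-4 = 0.54` with the sampling spread
a ~39-sire design implies; the recovery tests average over 20 such
replicates. The litter share is near zero, as configured. Bivariate fits
work the same way:

```r
biv <- fit_animal_model_bivariate(
  d$phenotypes, c("pe", "phe"),
  ~ sex + treatment + year_of_change + slaughter_bw + temperature,
  sim$pedigree, litter = "litter_id")
subset(biv$parameters, parameter %in% c("rg", "rp"))
```

The numbered scripts under `analysis/` run the full workflow (simulate →
derive → AIC screening → genetics reports → sensory LSD) and write their
tables under `results/`; `vignettes/protein-efficiency-genetics.Rmd`
documents the models, the numerical choices and the generator's
assumptions.

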