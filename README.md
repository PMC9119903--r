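# stagegrowth

Bayesian modelling of stage-specific somatic growth and abundance for
riverine fish populations monitored by multi-pass depletion electrofishing.

Long-term monitoring programmes for stream salmonids such as European
grayling (*Thymallus thymallus*) produce three intertwined data streams:
individual fork lengths with scale-read ages, per-pass removal counts from
depletion surveys, and environmental records (daily air temperature and
discharge, annual habitat and prey indices). `stagegrowth` provides the full
chain needed to ask how abiotic and biotic conditions shape growth
differently across life stages — juveniles (age 0+), sub-adults (age 1+) and
adults (ages 2+–5+) — for the fisheries scientists and quantitative
ecologists who run such programmes.

## The models

**Abundance.** Latent abundance per year *y*, site *s* and age-class *a*
follows an N-mixture model with an explicit imperfect-detection layer for a
*k*-pass depletion survey:

    N_{y,s,a} ~ Poisson(lambda_{y,s,a}),  log lambda_{y,s,a} = alpha_{y,s,a}
    C_{s,a,j} ~ Binomial(p_g, N_{s,a} - sum_{i<j} C_{s,a,i})

with capture probability `p_g` shared within groups (age 0+ vs older
grayling; all trout). Posterior mean abundances become the intra- and
inter-specific competitor covariates of the growth model.

**Growth.** Expected length at age extends the von Bertalanffy curve
`L(t) = L_inf (1 - e^{-K (t - t_0)})` by letting standardised, stage-specific
covariates scale the annual growth increment:

    mu_{y,s,1}   = L_inf (1 - e^{-K (t_1 - t_0)}) e^{theta_1 . X_{y,s,1}}
    mu_{y+1,s,a} = mu_{y,s,a-1}
                   + (L_inf - mu_{y,s,a-1}) (1 - e^{-K (t_a - t_0)})
                     e^{theta_l . X_{y+1,s,l}}

and individual lengths are Normal around their cell's expected value.
Covariate structure is simplified stage by stage (juvenile, then sub-adult,
then adult), removing coefficients whose 95% credible interval straddles
zero, and the final model is verified against "candidate full models" by
PSIS-LOO (Pareto-smoothed importance-sampling leave-one-out
cross-validation, re-implemented here).

The covariates module derives the explanatory variables from raw series:
seasonal window means, high-temperature day counts, low/high-flow day counts
against the Q90/Q10 flow-duration percentiles, z-standardisation, and a
Pearson collinearity screen (`|r| >= 0.7`).

A synthetic-data generator reproduces the statistical shape of a 17-year,
six-site programme (six grayling age-classes, two trout size-classes, 3-pass
depletion with single-pass early years) with known truth, so the entire
chain is testable without any field data.

## Worked example

```r
library(stagegrowth)

study <- generate_study(synthetic_truth(n_lengths = 2000), seed = 1)
fit <- fit_growth(study$records, study$covariates,
                  settings = mcmc_settings(chains = 3, iterations = 6000,
                                           burn_in = 3000, thin = 10, seed = 2))
subset(fit$summary, parameter %in% c("Linf", "K", "t0"))
#>   parameter    mean    lo95    hi95 rhat
#> 1      Linf 350.154 347.515 352.578 1.01
#> 2         K   0.138   0.125   0.152 1.01
#> 3        t0  -2.374  -2.712  -2.058 1.01
```

The generating truth here was `L_inf = 350` mm, `K = 0.14` per year and
`t_0 = -2.3` years; all three posterior means land on the truth with R-hat
well below the 1.1 convergence bar. The post-hoc year trend on expected
length at age (mm per year, averaged across sites, with 95% credible
intervals from the posterior draws):

```r
expected_length_series(fit)$trend
#>   age_class  slope  lo95  hi95
#> 1         1 -0.076 -0.29  0.13
#> 2         2  0.554  0.29  0.82
#> 3         3  0.927  0.61  1.26
#> 4         4  0.643  0.35  0.96
#> 5         5  0.434  0.11  0.76
#> 6         6  3.602 -6.85 14.60
```

Juvenile expected length is flat over the simulated period while older
age-classes drift upward — the signature of the declining adult abundance
built into the generator's covariate trends (fewer competitors, larger
adults). The wide interval at age 5+ reflects how few old fish the
age-frequency profile supplies.

From there, `staged_simplification()` reduces the covariate structure,
`candidate_full_models()` + `psis_loo()` + `select_model()` verify it, and
`marginal_effect()` traces covariate effects in raw units. Depletion catches
are fitted with `fit_abundance()`, whose posterior means feed
`abundance_covariates()`. A command-line driver
(`inst/scripts/stagegrowth-pipeline.R`, commands `simulate`, `covariates`,
`abundance`, `fit`, `simplify`, `loo`, `report`) chains the same functions
over CSV/YAML files.

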