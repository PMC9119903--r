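---
title: "Methods: stage-specific growth and depletion abundance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specific growth and depletion abundance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, the choices made
where the design was genuinely open, and what its validation machinery does
and does not demonstrate.

## The abundance model

Multi-pass depletion electrofishing removes fish on successive passes, so
catches decline at a rate governed by the per-pass capture probability. The
package models counts from each sampling unit (year x site x class) as

$$N \sim \mathrm{Poisson}(\lambda), \qquad
  C_j \mid N \sim \mathrm{Binomial}\!\left(p_g,\; N - \textstyle\sum_{i<j} C_i\right),$$

with $\log \lambda = \alpha$ given a Normal(0, sd 10) prior and
$p_g \sim \mathrm{Beta}(1,1)$ shared across units within a capture group
(grayling: age 0+ alone, ages 1+–5+ together; trout: all together). The
assumptions are the standard removal-sampling ones: a closed unit during the
survey (stop nets), equal catchability within a group, and no behavioural
response across passes.

**Exact marginalisation.** Summing the sequential binomial layer over the
Poisson latent state gives independent Poisson catches,
$C_j \sim \mathrm{Poisson}(\lambda\, p (1-p)^{j-1})$ — Poisson thinning. The
sampler therefore works on this exact marginal likelihood (no truncation
bound is involved) and reconstructs the latent abundance per retained draw
from its exact conditional, $N = \sum_j C_j + \mathrm{Poisson}(\lambda
(1-p)^k)$. Single-pass units ($k = 1$) sit in the same joint model: their
$\lambda$ and $p$ are confounded in isolation but identified through the
capture probability shared with three-pass units. This is how the package
combines the single-pass early years with the later three-pass design; how
the original monitoring programme combined them is not documented, so the
joint model is this package's choice.

The sampler is an adaptive Metropolis-within-Gibbs written in R: all unit
intercepts are proposed in one vectorised sweep (valid because units are
independent given $p$), group capture probabilities are updated on the logit
scale, and proposal scales adapt by Robbins–Monro during burn-in only
(targets 0.44 for scalar updates, 0.234 for the grouped update). Production
settings are 3 chains of 30,000 iterations, 10,000 burn-in, thinning 100.

## The growth model

Expected length at age follows a von Bertalanffy curve whose annual
increment is scaled by stage-specific covariates. With age-classes
$a = 1..6$ (ages 0+–5+), life stages $l$ = juvenile ($a=1$), sub-adult
($a=2$), adult ($a \ge 3$), and standardised covariate vectors
$X_{y,s,l}$:

$$\mu_{y,s,1} = L_\infty\left(1 - e^{-K (t_1 - t_0)}\right)
               e^{\theta_1 \cdot X_{y,s,1}}$$
$$\mu_{y+1,s,a} = \mu_{y,s,a-1} +
  \left(L_\infty - \mu_{y,s,a-1}\right)\left(1 - e^{-K (t_a - t_0)}\right)
  e^{\theta_l \cdot X_{y+1,s,l}},$$

with individual lengths $L_i \sim \mathrm{Normal}(\mu_{y,s,a},
1/\sqrt{\tau})$. Expected length is a property of the (year, site,
age-class) cell, not of individuals, so cohorts share the recursion; cells
in the first study year at ages 2+ and older have no within-frame parent and
are anchored by free initial-length parameters $\mu_{\mathrm{init}}$, one
per site and age-class.

Two structural choices deserve comment:

* **Increment (Fabens) form.** The covariate multiplier acts on the growth
  *increment* and the previous expected length is carried forward. A
  non-accumulating variant in which each year's expected length is just the
  scaled increment is retained behind `literal = TRUE` for comparison; only
  the increment form produces the familiar saturating length-at-age profile
  (roughly 128, 227, 290 mm for the first three age-classes under
  $L_\infty = 347.61$, $K = 0.14$, $t_0 = -2.27$) and it is the default
  everywhere.
* **Age values.** $t_a = a$, the age-class index. Age 0+ fish are caught in
  autumn after roughly one growing season anchored at $t_0 < 0$; this is the
  only assignment consistent with the deterministic baselines above.

**Priors** (`growth_priors()`): zero-centred Normals with sd
$1/\sqrt{0.001} \approx 31.6$ for $t_0$ (years) and the covariate
coefficients (standardised scale, where plausible effects are of order
0.01–0.15, so this is genuinely weak); $K \sim \mathrm{Gamma}(1,1)$;
$\tau \sim \mathrm{Gamma}(0.01, 0.01)$ on the Normal precision. For the
*length-scale* parameters — $L_\infty$ and the initial-year expected
lengths, which live at 200–350 mm — a zero-centred prior with sd 31.6 mm is
not weak: in our 20-replicate recovery experiments it shrank the
initial-year lengths enough to bias $K$ upward and $t_0$ toward zero and
destroy interval coverage. The package therefore defaults these to sd
1000 mm, keeping all priors weakly informative on each parameter's natural
scale; the narrower reading remains one argument away for sensitivity work.

**Sampler.** A purpose-built C++ Metropolis-within-Gibbs. The Normal
likelihood with a common precision depends on the data only through per-cell
counts, means and sums of squares, so a likelihood evaluation costs
O(cells), not O(records). Each iteration sweeps scalar random-walk updates
over all parameters, then repeats an adaptive *joint* random-walk update of
$(L_\infty, \log K, t_0)$ three times using the running sample covariance of
those draws (scaled by $2.38^2/3$) — the three curve parameters ride a
narrow posterior ridge that scalar proposals traverse slowly — and finally
draws the precision $\tau$ from its conjugate Gamma conditional. Proposal
scales adapt only during burn-in. Starting values are data-driven and
overdispersed per chain: the asymptote near the largest observed fish,
$K \in (0.08, 0.35)$, first-year cell means (jittered) for the initial
lengths. Chain $c$ is seeded with `seed + c - 1`; runs are exactly
reproducible.

## Covariate engineering

Seasonal windows are closed calendar-date intervals: spring–autumn is
1 April–30 September of the growth year; autumn–winter runs 1 October of the
previous year to 31 March (leap days included). Juvenile covariates use only
the spring–autumn window of the growth year; sub-adult and adult covariates
may additionally use the autumn–winter window ending in that year.
High-temperature days use a strict `> 20` °C comparison ("exceeded");
low/high-flow days use inclusive comparisons against the Q90/Q10
flow-duration thresholds, the 10th/90th empirical percentiles of all daily
discharges over the full reference period. All quantiles in the package
(flow thresholds, credible intervals) use linear interpolation between order
statistics (`stats::quantile` type 7). Missing discharge days can be filled
from a donor gauging series by a date join before any window statistic is
computed.

Year-level variables (temperature, flow, macrophyte cover, invertebrate
biomass) are replicated across sites; abundance covariates vary by year and
site. Macrophyte cover and the invertebrate biomass index are accepted as
single annual values because the upstream monitoring programmes report them
that way; site-level resolution, where available, can be supplied by giving
the assembler a site-varying input instead. Every variable is z-standardised
(mean 0, sample sd 1) over its year x site support, with the mean and sd
stored so marginal-effect axes can be drawn in raw units. The collinearity
screen reports all within-stage pairs with $|r| \ge 0.7$ and removes only
variables named in a configured drop list — by default the
high-temperature-day count, keeping mean temperature as the more fundamental
influence; an unresolved flagged pair is an error because choosing a member
to keep is an ecological judgement the software must not make silently.

## Simplification and model comparison

Starting from saturated stage sets, the juvenile stage is simplified with
sub-adult and adult covariates omitted, then the sub-adult stage with adult
covariates omitted, then the adult stage. Within a stage the rule is:
refit, find coefficients whose equal-tailed 95% credible interval contains
zero, remove the one with the smallest $|\mathrm{mean}|/\mathrm{sd}$ (the
most centrally straddling), repeat. One-at-a-time removal is the default
because it is the conservative reading of an iterative interval-based
procedure; batch removal of all straddlers per refit is available
(`batch = TRUE`). Fit seeds derive from a master seed plus the fit's
position in the lineage, so a simplification path is exactly replayable.

The final full model is checked against one candidate per stage — the full
model plus that stage's last-removed variable — using PSIS-LOO computed from
the pointwise log-likelihood matrix over retained draws. The PSIS
implementation follows the published algorithm: importance ratios
$1/p(y_i \mid \theta_s)$, tail length $\min(0.2 S, 3\sqrt{S})$, a
generalised-Pareto fit to the tail exceedances by the Zhang–Stephens
profile posterior-mean estimator (with the standard weak shape prior),
replacement of the tail by expected order statistics of the fitted
distribution, truncation at the raw maximum, and the tail-shape diagnostic
$\hat k$ reported per observation (0.5/0.7 thresholds; a fit with more than
10% of observations above 0.7 is flagged unreliable). Model selection takes
the lowest LOOIC, resolving ties within one standard error of the pairwise
elpd difference toward the model with fewer covariates.

## The synthetic-data generator

The generator emulates the statistical structure of the motivating
monitoring programme: 17 years x 6 sites, six grayling age-classes plus two
trout size-classes, three-pass depletion with single-pass surveys in the six
earliest years, about 5,600 length records with 15% recaptures, and an
age-frequency profile declining with age (few 5+ fish). Daily temperature is
a calendar-aligned seasonal sinusoid (mean 10.5 °C, amplitude 7 °C, noise sd
3 °C, trend +0.02 °C/yr) and daily discharge a lognormal around a
winter-peaking baseflow (median 2 m³ s⁻¹), with trend directions chosen to
mimic the observed series: a slow rise in summer flows (fewer low-flow
days), declining invertebrate biomass, declining adult grayling abundance,
increasing juvenile trout abundance. Growth truth defaults sit near the
fitted values for the population that motivated the package
($L_\infty = 350$ mm, $K = 0.14$, $t_0 = -2.3$, residual sd 15 mm), and the
stage-coefficient truth carries the final-model sign structure with
magnitudes back-computed from the reported marginal effect sizes (for
example, adult conspecific abundance $-0.13$, the strongest effect;
juvenile spring–autumn temperature $+0.048$), with exact zeros for the
covariates found uninfluential — so simplification experiments have real
zeros to find. Initial-year expected lengths are anchored at the
covariates-at-means von Bertalanffy baseline.

Lengths used for fitting are generated from the *true-abundance* covariate
table; an analysis may instead re-estimate abundances from the simulated
catches, introducing realistic covariate measurement error. What passing
simulation tests show is that the estimation machinery recovers parameters
when the model is true at study scale; they do not validate the model
against unmodelled features of real data — individual growth heterogeneity,
sex effects, non-Normal length errors, spatial correlation among sites, or
observation error in the environmental series.

## Validation problem sizes

The package's own validation (in `tests/testthat/test-acceptance.R`) uses:
a single-unit exhaustive grid posterior ($N$ from the total catch to 600,
999-point capture-probability grid, 601-point quadrature over the log-mean
prior) against the MCMC fit; 20 replicate studies of about 2,000 lengths
each fitted with 3 chains x 6,000 iterations (3,000 burn-in, thin 10) for
interval coverage and simplification accuracy; exact leave-one-out
refitting on a 40-record, 8-year, single-site fit against PSIS-LOO; and
1,100+ simulated depletion units at $p = 0.6$ for the capture-fraction
identity $1 - (1-p)^3$. These sizes were chosen as the smallest at which
each property is sharply testable.

## Degenerate inputs and edge rules

Constant discharge series yield coincident Q90/Q10 with a warning;
zero-variance covariates are an error naming the variable; a chain that
never moves a parameter is reported as (infinite) non-convergence rather
than crashing the Gelman–Rubin computation, and `gelman_rubin()` itself
errors on zero within-chain variance; the classic (non-split) Gelman–Rubin
statistic is the default, with a split-chain option; empty seasonal windows
are errors naming the year and window, and windows missing more than 10% of
days warn. Length records with age-classes above 6 are rejected at
ingestion (too few old fish to estimate growth). Every stochastic entry
point requires an explicit seed.

## Known limitations

Abundance means are independent per year, site and class (no covariates on
$\lambda$, no spatial or temporal smoothing). Growth is annual — no
seasonal decomposition — and assumes a single shared residual variance,
maturation fixed at the sub-adult/adult boundary, and no sex structure.
PSIS-LOO inherits its usual caveat: observations with $\hat k > 0.7$
(highly influential points, common in very small fits) make the importance
sampling unreliable, which the result flags. The CLI driver is a thin
convenience over the R functions; the functions are the supported
interface.
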