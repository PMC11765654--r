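---
title: "Methods: vertical stratification and causal mediation at forest edges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertical stratification and causal mediation at forest edges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods implemented in `stratmed`,
the assumptions behind them, and the numerical and design choices made where
the problem left them open. It is the package's methodological reference;
the README shows the user-facing workflow.

## The scientific setting

Paired bait traps — one in the canopy (around 23 m), one in the understory
(around 1 m) — sample fruit-feeding nymphalid butterflies at edge, ridge and
valley sites, with temperature and light loggers at each trap recording
hourly or two-hourly. Each capture is one marked individual (recaptures
excluded upstream). The questions are (i) whether species' canopy
probability decreases at forest edges, and (ii) how much of that change is
carried by the light gradient, the temperature gradient, or the turnover of
species composition, as opposed to a direct edge effect.

## Stratification tests

For species $s$ and habitat class $h$ (edge, or forest = ridge + valley
pooled), the canopy probability is $\hat p_{sh} = C_{sh}/(C_{sh}+U_{sh})$,
and the delta-edge index is
$\Delta_s = \hat p_{s,\text{forest}} - \hat p_{s,\text{edge}}$, defined for
species captured in both habitat classes. Positive $\Delta_s$ means the
species descends at the edge. The sign test treats the number of species
with $\Delta_s > 0$ as the observed count in a two-cell goodness-of-fit
problem against a 50:50 expectation,
$G = 2\sum_{c} O_c \ln(O_c/E_c)$ with $E_c = n/2$, referred to
$\chi^2_1$.

Choices worth stating:

* **Tie rule.** $\Delta_s = 0$ is classed *nonpositive*. With count data,
  ties occur (species seen only in the canopy in both habitats, say), and
  folding them into the nonpositive class makes the test conservative for
  the descent hypothesis.
* **Zero cells.** $O \ln O \to 0$ as $O \to 0$, so the statistic is defined
  for any split, including 0 or $n$ positives.
* **Filter order.** The sensitivity filters apply cumulatively: first the
  strict understory genera (*Caligo*, *Eryphanis*, *Taygetis*) are removed,
  then species with fewer than three individuals at the edge or in the
  forest. Whether the genus filter in the second step includes *Eryphanis*
  is immaterial for the packaged counts: *E. lycomedon* fails the minimum
  count in the forest either way.
* The test is a goodness-of-fit test of the sign split, not a test of
  independence in a two-way table; the implementation follows the procedure
  that reproduces the published statistics exactly.

## The structural causal model

Per capture $i$: exposure $FE_i \in \{0, 1\}$ (edge vs forest; ridge and
valley collapse to 0 at analysis time but stay distinct in storage),
mediators $LD_i$ (canopy-minus-understory log-light difference), $TD_i$
(temperature difference, downstream of $LD$), $FCT_i$ (logit-scale forest
canopy tendency of the captured species), and outcome $CAN_i \in \{0,1\}$
(canopy trap). Gaussian linear regressions for $LD$, $TD$, $FCT$ and a
logistic regression for $CAN$, exactly the edges of the causal graph — no
interactions, no species-varying slopes. Regression coefficients carry flat
(variance $10^6$ normal) priors; error sds uniform $(0, 50]$ priors.
Covariates enter unstandardised; a centering reparameterisation used inside
the sampler (below) is exact and invisible in the reported coefficients.

**Light transformation.** Loggers record lux; analysis uses
$\ln(\text{lux} + 1)$. The offset handles night-time zeros; natural log and
offset 1 are package conventions (configurable), recorded in the run
manifest. Filtering through vegetation is multiplicative and insect
photoreception follows the Weber–Fechner law, so the log scale is the
substantively right one.

**Capture hour.** Trap checks have day resolution; captures lacking a
time-of-day are assigned a representative hour (default 12:00, the middle of
the trapping window) and flagged `hour_assumed`. The assumption propagates
into $LD_i$/$TD_i$ construction.

## Missing data as part of the joint posterior

Two missingness mechanisms matter: loggers were absent or knocked down for
stretches (not at random in time), and several sites never carried loggers;
and canopy-tendency priors from earlier work do not cover all taxa. Both are
handled inside the one posterior, so the mediation and missing-data parts
inform each other.

**Abiotic state space.** One latent hourly series per habitat × stratum ×
variable combination — 12 when all three habitats are instrumented. Each
series follows an hour-of-day harmonic baseline (first and second
harmonics: level, two amplitude/phase pairs) plus AR(1) deviations
($|\rho| < 1$, process sd), observed through logger records with Gaussian
noise. The published account specifies the state-space form but not the
dynamics; the harmonic-AR(1) choice is this package's, motivated by the
strong diurnal cycle in the data with few parameters, and is flagged as
such. Series are keyed by habitat type, not site: all loggers of one
habitat-stratum pair inform one shared series, which is exactly what makes
captures at never-instrumented sites imputable. The hour grid is fixed at
1 h; two-hourly loggers observe every other state; hours with no record
carry latent states with no likelihood term. Mean levels get broad,
informative priors (temperature: normal(25, 5) °C, from typical lowland
wet-forest records; log-light: normal(6, 3) canopy, normal(2, 3) understory
— package defaults, configurable). The initial state is diffuse around the
baseline.

**Canopy tendencies.** Species with published canopy-probability posteriors
enter through normal distributions fitted to the logit-transformed posterior
quantiles (least squares of the logit quantiles on standard normal
quantiles; the fit criterion is unspecified upstream, least squares is the
package's choice and recovers the parameters exactly when the source is
logit-normal). Species without priors draw their tendency from a tribe-level
hierarchy: tribe mean $\sim$ normal(0, 2.5), tribe sd $\sim$
half-normal(1.5) on the logit scale (package defaults). Tendencies are
sampled jointly with everything else, so capture data sharpen them.

**A degeneracy, and how the package avoids it.** Writing the composition
regression with *fully latent* outcomes — every observation contributing a
Gaussian likelihood term on its species' latent tendency — creates a
degenerate joint mode: the finitely many latent tendencies can collapse onto
the regression plane, sending the error sd to zero and the density to
infinity, and that spike dominates any continuous prior on the sd. The same
trap exists for the abiotic contrasts if both the regression outcome and the
covariate are latent states. The package therefore anchors each regression
in observed data: the composition regression observes the prior-study logit
means for pinned species (latent outcomes only for the prior-less
minority), and the mediator regressions observe logger-derived contrasts
where the capture's habitat-hour has them (latent outcomes only for
unmatched captures). The canopy equation always uses the fully latent
quantities, so imputation and uncertainty propagation are unaffected. With
some outcomes genuinely observed, their residuals pin the error sd and the
spike is gone. This is the package's resolution of an ambiguity in the
source description, and the non-degenerate part of the posterior is
unchanged by it.

## Sampling and convergence

Fitting uses JAGS (Gibbs/slice sampling; the `glm` module contributes block
samplers for the linear-Gaussian and plain-logistic structure). Numerical
choices:

* Exact centering reparameterisation: the sampler works with
  $\alpha_T^c = \alpha_T + \gamma_T \bar{LD}$ and
  $\alpha_C^c = \alpha_C + \lambda \bar{LD} + \tau \bar{TD} + \phi \bar{F}$
  (data-derived constants), and the original intercepts are recovered as
  deterministic nodes. This removes extreme posterior correlations without
  changing the model.
* The Bernoulli probability is clamped to $[10^{-12}, 1-10^{-12}]$ in the
  latent-tendency model forms so the likelihood stays computable if the
  linear predictor saturates in floating point during early adaptation.
* Error-sd priors are bounded below at $10^{-3}$ (uniform $(10^{-3}, 50]$)
  so precisions stay finite under slice sampling. This is numerically, not
  statistically, motivated.
* Seeds: one master seed fans out to per-chain RNG streams and to the
  effect-stage Monte Carlo; fits are reproducible draw-for-draw.

The convergence gate requires split-$\widehat R \le 1.01$ and effective
sample size $\ge 400$ on every structural coefficient, with at least two
chains. A Gibbs backend has no divergent-transition diagnostic; the
divergence count is reported as 0 and the gate rests on $\widehat R$/ESS.
Runs failing the gate still return their artifacts, flagged
`converged = FALSE` with a warning — never silently — and the effect stage
refuses them unless forced. A model built from single-exposure data (all
forest, say) is flagged unidentified at build time. Zero-row data are
rejected outright: under the flat-prior design there is no proper
prior-only posterior to sample.

## Effect decomposition

Potential-outcomes notation: $LD(a)$ is the light difference under exposure
$a$; $TD(a, LD(a'))$ the temperature difference under exposure $a$ with the
light argument set to its value under $a'$; $FCT(a)$ the tendency under the
composition of exposure $a$. Expected canopy probabilities
$E\{CAN(a, LD(a_L), TD(a_T, LD(a_{TL})), FCT(a_F))\}$ are evaluated along
the telescoping sequence

$$(0, LD(0), TD(0, LD(0)), FCT(0)) \to (1, \cdot) \to (1, LD(1), \cdot)
\to (1, LD(1), TD(1, LD(1)), \cdot) \to (1, LD(1), TD(1, LD(1)), FCT(1)),$$

whose consecutive differences are the natural direct effect, light effect,
temperature effect and species composition effect; the endpoint difference
is the total causal effect and the edge effect is $TCE - SCE$. The NDE is
the exposure contrast at all-control mediator values ("holding light,
temperature and tendency constant"). This sequential order is one valid
decomposition consistent with the published effect definitions;
interventional analogues are noted, not implemented.

Within each posterior draw the expectations are Monte Carlo averages over
$K$ mediator draws (default 1000) under **common random numbers**: one
standard-normal triple serves every counterfactual setting, which is both
the correct single-individual counterfactual semantics (the individual's
noise is shared across worlds) and what makes the telescoping additivity
$\text{NDE} + \text{light} + \text{temperature} + \text{SCE} = \text{TCE}$
and $\text{edge} = \text{TCE} - \text{SCE}$ hold to machine precision per
draw. The reference population enters only through its size (each member's
covariates are fully replaced by counterfactual draws), so the package
exposes $K$ directly and defaults it to the population size when one is
supplied.

Because the outcome-equation argument is linear in the three jointly
Gaussian noise variables, each expectation is also a one-dimensional
Gaussian-logistic integral; `effects_quadrature()` evaluates the same
contrasts by adaptive quadrature. This deterministic route serves as the
independent cross-check of the Monte Carlo path and as the oracle-truth
generator for recovery studies.

## The synthetic-data generator

`sim_study()` emulates the field design: 10 edge, 12 ridge and 10 valley
sites with paired traps (trap heights drawn near 23 m and 0.9 m); ~30 days
of hourly latent abiotic series from habitat- and stratum-specific diurnal
curves (canopy brighter and hotter by day, slightly cooler at night; edge
strata bright and hot, the edge understory resembling the forest canopy)
plus AR(1) noise; hourly/two-hourly loggers with configurable MCAR gaps and
an elevated missingness rate in the first half of the study (the early
logger shortage); a species pool of 120 with log-series abundances and
tribe-clustered tendencies, sized so a default run observes captures,
species and tribes on the scale of the emulated study (~700 / ~90 / 12);
capture events Poisson per site-day in daylight trap hours (08:00–16:00
uniform); composition shift at the edge by exponential tilting of sampling
weights in the species tendency; and the capture stratum drawn from the
logistic outcome equation at the true latent contrasts. All outputs are
byte-reproducible given the seed, and the ground truth (coefficients,
species tendencies, latent series, oracle effects) ships alongside.

`sim_scm()` is the *model-faithful* generator: mediators drawn directly
from the structural equations at the configured coefficients. Coefficient
and effect recovery are assessed against `sim_scm()`, where the fitted
model's functional form matches the data-generating process exactly; the
field emulator's light and temperature differences come from diurnal curves,
so its implied regression coefficients are only approximately the
configured ones and it is used to exercise input handling, the state space
and the pipeline. What passing recovery tests show, therefore, is that the
machinery estimates the model it claims to estimate — not that the linear
mediation model is an adequate description of any particular forest, and not
robustness to misspecification (the posterior predictive checks are the tool
for that question on real data).

Default true coefficients mirror the qualitative pattern of interest —
strong negative direct edge coefficient, weak light and temperature
coefficients, positive composition shift, a light difference that shrinks at
the edge — and were fixed once, before any recovery measurement, as the
generator's study conditions.

## Problem sizes and tolerances in the test suite

The suite checks the stratification layer exactly (all printed
probabilities and delta-edge values to 4 decimals, tolerance $5\times
10^{-5}$; G statistics to 1 decimal; a likelihood-ratio oracle agreement to
$10^{-10}$ over all splits with $n \le 12$). The statistical layers run at
desk scale, chosen to finish in minutes on one core while leaving the
checks well-powered: effect recovery on 20 replicates of 1000 captures
across 32 sites (mean absolute error $\le 0.05$ per effect; 95% interval
coverage $\ge 18/20$); state-space imputation on a 14-day canopy/understory
pair with 20% gaps against the exact true-parameter Gaussian smoother
(RMSE ratio $\le 1.5$); null calibration of the sign test over 500
replicates against the exact size of the discrete test at $n = 41$, and of
the effect posteriors over 20 null replicates. Monte Carlo error of the
decomposition is checked to scale as $K^{-1/2}$.

## Known limitations

* The mediation model is deliberately low-flexibility: linear mediator
  effects, no splines, no species-varying slopes, no interaction between
  light and temperature paths. Real stratification responses may be
  threshold-like rather than difference-driven.
* No cross-series covariance in the state space beyond what the regressions
  induce; no humidity, rainfall or spectral-composition series.
* No sensitivity analysis for unmeasured confounding; the effect estimates
  are causal only to the extent the assumed graph is complete.
* The sign test ignores per-species sampling error in $\Delta_s$ (species
  with a single capture per habitat contribute as much as abundant ones);
  the sensitivity filters are the guard against that.
* Ridge and valley are pooled as forest in both layers; habitat-specific
  forest effects are out of scope.
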