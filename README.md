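# stratmed

Vertical stratification and causal mediation analysis for forest-edge
butterfly communities.

Fruit-feeding nymphalid butterflies show strong vertical community structure:
most species keep either to the forest canopy or to the understory. At forest
edges, canopy species have long been observed to descend — a change
classically attributed to the collapse of the light gradient between strata.
`stratmed` is an R toolkit for analysing this phenomenon from paired
canopy/understory bait-trap data with co-located temperature and light
loggers. It is written for community ecologists who want to move beyond
association and ask *why* canopy probability changes at the edge.

The package has two analysis layers:

1. **Stratification tests.** For each species common to edge and forest
   locations, the canopy probability (canopy captures / total captures) is
   computed per habitat and the *delta edge* index is their difference,

   `delta = P(canopy | forest) − P(canopy | edge)`,

   positive when a species descends at the edge (ties count as nonpositive).
   A likelihood-ratio sign test, `G = 2 Σ O ln(O/E)` with `E = n/2` and
   `df = 1`, asks whether more species than expected show positive delta
   edge, with two sensitivity filters (removal of strict understory genera;
   a minimum of three individuals per habitat).

2. **A joint Bayesian structural-causal mediation model.** On the
   individual-capture level, the forest-edge indicator `FE` acts on the
   canopy-capture outcome `CAN` directly and through three mediators: the
   canopy-minus-understory log-light difference `LD`, the temperature
   difference `TD` (itself downstream of `LD`), and the species forest
   canopy tendency `FCT` (composition change). The structural equations are

   ```
   LD  = alpha_L + beta_L FE + e_L
   TD  = alpha_T + beta_T FE + gamma_T LD + e_T
   FCT = alpha_F + beta_F FE + e_F
   logit P(CAN = 1) = alpha_C + beta_C FE + lambda LD + tau TD + phi FCT
   ```

   Missing data are handled inside the same posterior: the hourly abiotic
   series are modelled as a 12-dimensional state space (habitat × stratum ×
   variable) with an hour-of-day harmonic baseline and AR(1) deviations, so
   captures that could never be matched to a logger still receive `LD`/`TD`;
   species without published canopy-tendency priors are imputed
   hierarchically by tribe. Causal effects are then read off the posterior
   with a potential-outcomes decomposition (common random numbers,
   telescoping contrasts): the natural direct effect (NDE), light effect,
   temperature effect, species composition effect (SCE), total causal effect
   (TCE), and the edge effect defined as `TCE − SCE`. Within every draw the
   four components sum exactly to the TCE.

Fitting uses JAGS through `rjags`; a synthetic-data generator with known
ground truth (`sim_study()`, `sim_scm()`) makes every stage testable without
any field data.

## Worked example: stratification tests

The package ships the canopy/understory counts of the 41 nymphalid species
common to edge and forest locations from a mark–release study at La Selva,
Costa Rica:

```r
library(stratmed)
suite <- gtest_suite(nymphalid_counts())
suite$tests
#> # A tibble: 3 × 6
#>   test                      n_species n_positive     G    df       p
#>   <chr>                         <int>      <int> <dbl> <int>   <dbl>
#> 1 all_common_species               41         28  5.62     1 0.0178
#> 2 understory_genera_removed        37         28 10.2      1 0.00138
#> 3 min_count_filter                 14         12  7.92     1 0.00488
```

28 of 41 species show a decreased canopy probability at the edge — a
significant excess over the 20.5 expected under no edge response — and the
excess survives both sensitivity filters. `suite$delta` holds the
per-species table (`plot_delta_edge()` draws it).

## Worked example: mediation on synthetic data

```r
study <- sim_study(sim_config(n_days = 10), seed = 21)
data  <- prepare_mediation_data(study$captures,
                                abiotic_series(study$loggers, study$sites))
fit   <- fit_mediation(data, fct_priors = study$fct_priors,
                       config = sampler_config(seed = 3, adapt = 1000,
                                               warmup = 2000, draws = 5000))
glance(fit)
#>       n mode    chains draws max_rhat min_ess n_divergent identified converged
#>     224 species      2 10000     1.00   1024.           0 TRUE       TRUE

effects <- effect_decomposition(fit, K = 1000, seed = 7)
tidy(effects)
#>   term                estimate conf.low.95 conf.high.95
#> 1 nde                -0.141        -0.305        0.0504
#> 2 light_effect       -0.0554       -0.199        0.0720
#> 3 temperature_effect -0.000203     -0.00900      0.00804
#> 4 sce                 0.152         0.0755       0.239
#> 5 edge_effect        -0.196        -0.308       -0.0792
```

(50% intervals omitted here for width.) The generator's oracle truths for
this configuration are NDE −0.137, light −0.007, temperature 0.001, SCE
0.104, TCE −0.040, edge −0.144 — each inside its 95% credible interval. The
effects are on the canopy-probability scale; `autoplot(effects)` draws the
forest plot, and `posterior_predictive_check(fit)` reports regression
discrepancy p-values and a calibration table for the logistic block.
`run_pipeline()` chains all stages (summaries, G-tests, joint fit, effects,
checks) over a directory of CSVs with a reproducible run manifest.

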