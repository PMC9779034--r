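# arealrisk

Bayesian small-area risk mapping for areal count data. The package is
aimed at spatial epidemiologists and social scientists who observe
event counts per administrative area (the motivating shape: counts of
women assaulted by a current or former partner per department, with the
female population 13–49 at risk) and want smoothed relative-risk
estimates plus interpretable area-level covariate effects.

It implements the full chain such an analysis needs:

* **Standardization** — expected counts by indirect standardization and
  the standardized morbidity ratio, SMR\_i = y\_i / e\_i with
  e\_i = pop\_i · Σy / Σpop.
* **Contiguity** — queen/rook neighbourhood graphs from GeoJSON
  polygons or edge lists, and the intrinsic CAR structure matrix
  Q₀ = D − W (so uᵀQ₀u = Σ_{i∼j}(u_i − u_j)²).
* **Covariate reduction** — Bayesian exploratory factor analysis with
  dedicated loadings, x\_j = λ\_j f\_{z\_j} + ε\_j, in which the number
  of factors and the variable-to-factor allocation z are sampled
  jointly with the loadings (Metropolis–Hastings with the loading
  integrated out analytically).
* **Risk model** — the Besag–York–Mollié convolution model

  y\_i ~ Poisson(e\_i θ\_i),  log θ\_i = α₀ + x\_iᵀβ + u\_i + v\_i

  with u an ICAR spatial effect, v\_i ~ N(0, 1/τ\_v), fitted by
  Metropolis-within-Gibbs (10,000 iterations, 4,000 warm-up by
  default).
* **Reporting** — coefficient and relative-risk posterior summaries,
  exceedance probabilities P(θ\_i > 1), split-chain R̂ and effective
  sample size, choropleth GeoJSON export, and a YAML-configured
  pipeline (`run_pipeline()`) that writes every intermediate plus a
  MANIFEST.

Because the motivating data (forensic case records, national survey
aggregates) are restricted, the package ships a synthetic-study
generator (`default_study()`, `simulate_study()`) that reproduces the
statistical structure the analysis assumes — 33 areas including an
island, heterogeneous populations, proportion-scale covariates with a
dedicated factor structure, spatially correlated log-risks — so every
stage is testable end to end.

## Worked example

```r
library(arealrisk)

study <- default_study(seed = 1)          # 33-area synthetic study
d     <- expected_counts(study$data)      # indirect standardization
sort(smr(d), decreasing = TRUE)[1:3]
#>   A32   A13   A03
#> 2.718 1.989 1.255

# factor analysis on the standardized covariates
bf <- befa_fit(standardize_columns(d$X),
               befa_config(K_max = 3, n_iter = 10000, n_warmup = 4000,
                           seed = 2))
allocation_summary(bf)[c(1, 6, 10), c("covariate", "factor", "sign", "retained")]
#>             covariate factor sign retained
#> 1  decides_own_health      2    1     TRUE
#> 6        no_education      1   -1     TRUE
#> 10 sales_services_work      0   NA    FALSE

# convolution model on the factor scores
fit <- bym_fit(d, Xcov = factor_scores(bf), graph = study$graph,
               n_iter = 10000, n_warmup = 4000, n_chains = 3, seed = 3)
summarize_coefficients(fit)
#>        name    mean     sd    q2.5  q97.5
#> 1 Intercept -0.1850 0.0263 -0.2364 -0.131
#> 2  factor_1 -0.1742 0.0340 -0.2392 -0.107
#> 3  factor_2  0.3010 0.0341  0.2350  0.373
#> 4  factor_3  0.0844 0.0334  0.0188  0.146

head(relative_risk_summary(fit)[order(-relative_risk_summary(fit)$mean), ], 3)
#>    area mean q2.5 q97.5 prob_exceed
#> 32  A32 2.72 2.67  2.77           1
#> 13  A13 1.99 1.96  2.02           1
#> 3   A03 1.25 1.22  1.29           1
```

Reading the output: the ten covariates collapse onto the three
generating factors with the right memberships and signs (the fitted
factor labels are arbitrary — fitted factor 2 is the household-decision
factor generated as factor 1), the unallocated noise column is
dropped, and the coefficient posteriors bracket the generating effects
(−0.2, and 0.3 / −0.2 / 0.1 on the scores) while the highest posterior
relative risks pick out the areas simulated with the largest excess
risk. `classify_areas(factor_scores(bf))` labels each area by the
quadrant of two chosen factor scores, the biplot-style typology.

The same chain runs from the shell:

```sh
Rscript inst/scripts/run_pipeline.R --config my_config.yaml --out results/
```

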