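---
title: "Small-area risk mapping: models, priors and design choices"
author: "arealrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area risk mapping: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Counts of a health or social outcome aggregated over administrative
areas (here styled after a national study of physical intimate-partner
violence against women across 33 departments, with population at risk
the women aged 13--49) are too noisy to compare directly: the raw
standardized morbidity ratio (SMR) of a small-population area swings
wildly, and a choropleth of raw SMRs mostly displays population size.
`arealrisk` implements the standard Bayesian remedy -- the
Besag--York--Mollié (BYM) convolution model -- together with the
upstream steps such an analysis needs: indirect standardization, a
covariate correlation screen, and a Bayesian exploratory factor
analysis (BEFA) that compresses many collinear area-level proportions
into a few interpretable factors before they enter the risk model.

# Models

## Standardization and SMR

Expected counts use indirect standardization with a single all-areas
reference rate,
$e_i = \mathrm{pop}_i \sum_j y_j / \sum_j \mathrm{pop}_j$, so that
$\sum_i e_i = \sum_i y_i$ and the population-weighted mean SMR
($\mathrm{SMR}_i = y_i / e_i$) is exactly 1. No age stratification is
applied: the package treats the denominator as whatever population the
user supplies, and `area_data()` accepts externally computed expected
counts for users with stratified expectations.

## The convolution model

$$y_i \mid \theta_i \sim \mathrm{Poisson}(e_i \theta_i), \qquad
\log \theta_i = \alpha_0 + x_i^\top \beta + u_i + v_i$$

with $u$ an intrinsic CAR (ICAR) spatial effect on the contiguity
graph -- conditionally $u_i \mid u_{-i} \sim N(\bar u_{\partial i},
1/(\tau_u d_i))$ -- and $v_i \sim N(0, 1/\tau_v)$ unstructured
heterogeneity. Contiguity defaults to the queen rule (areas sharing at
least one boundary point are neighbours); rook is available.

Two reading choices deserve note. First, a literally uniform prior on
every $v_i$ would make the convolution unidentifiable (each $v_i$ could
absorb $y_i$ entirely), so the package uses the standard proper reading
$v_i \sim N(0, 1/\tau_v)$ with a Gamma hyperprior. Second, the
precision hyperpriors default to $\mathrm{Gamma}(0.5, 0.0005)$, the
long-standing disease-mapping convention; both are configurable through
`bym_priors()`.

## Dedicated-loading factor analysis

Standardized covariates follow
$x_j = \lambda_j f_{z_j} + \varepsilon_j$ with allocation
$z_j \in \{0, 1, \dots, K_{\max}\}$ ($0$ = no factor), orthogonal
standard-normal factors, $\lambda_j \sim N(0, s_0^2)$ and inverse-gamma
idiosyncratic variances. The number of active factors is not fixed: the
sampler moves through allocation space, so model dimension is inferred
jointly with the loadings. Every active factor must carry at least
`min_dedicated` (default 2) covariates -- a single-variable factor is
not identified.

Two defaults define the parsimony behaviour and are worth understanding:

* **Allocation prior.** The null allocation gets prior weight equal to
  `K_max` (half the per-covariate mass on "no factor"). A uniform prior
  over $0..K_{\max}$ would implicitly favour structure simply because
  there are combinatorially many allocated configurations -- e.g. 45
  ways to form one two-variable factor from six covariates with
  $K_{\max}=3$ -- and pure-noise data would be assigned spurious
  factors.
* **Loading prior SD.** Defaults to $\sqrt{m}$ (unit information). The
  loading prior sets the Occam penalty of the integrated likelihood
  that drives allocation moves; with a fixed prior SD the penalty does
  not grow with the number of areas while the apparent "signal" of a
  chance sample correlation does, so spurious allocations would not die
  out as $m$ grows. Unit-information scaling makes the penalty behave
  like BIC and gives consistent null recovery on noise. Both defaults
  can be overridden.

Retention follows a posterior rule: a covariate is retained when its
posterior probability of the null allocation is below
`retention_threshold` (default 0.5). The raw Metropolis--Hastings
acceptance rate of each covariate's allocation proposals is reported
alongside for users who track that index. Factor correlation is fixed
to the identity (orthogonal factors); oblique structures and
cross-loadings are out of scope.

# Samplers

## BEFA

Metropolis-within-Gibbs. Allocations move one covariate at a time with
the loading integrated out analytically (the integrated likelihood is
verified against numerical quadrature in the test suite), with moves
that would strand a factor below `min_dedicated` vetoed. Because
single-covariate moves can therefore never *create* a factor, each
sweep also makes several grouped birth/death attempts --
`min_dedicated` null covariates jointly founding an empty factor, or a
minimal factor dissolving. These are reversible-jump moves with a
data-informed proposal: the newborn factor's scores are drawn from
their Gibbs conditional given the group (loadings pinned at moment
estimates), with the proposal-vs-prior density correction carried in
the Hastings ratio. This matters because an empty factor's scores are
a prior draw, and under the unit-information loading prior a birth
evaluated against prior-drawn scores is essentially never accepted --
the chain would sit at the null model however strong the factor signal
is. Loadings, scores and idiosyncratic variances are Gibbs
updates; sign indeterminacy is resolved by flipping each
(loading, score) pair so the lowest-index member of every factor loads
positively.

Label switching is handled at summary time: recovery assertions compare
partitions, and `factor_scores()` matches each draw's factors to the
modal member sets (aligning signs by correlation with the factor's
first covariate) before averaging.

One consequence of sharing a single RNG stream across the sweep is that
permuting the covariate columns changes the realized draws; column
order exchangeability holds statistically (the same partitions are
recovered) but not bit-for-bit.

## BYM

Also Metropolis-within-Gibbs, with block structure chosen so the
chains converge within the default protocol of 10,000 sweeps and 4,000
warm-up:

1. $(\alpha_0, \beta)$: joint adaptive random walk (target acceptance
   20--40%, adaptation during warm-up only, kernel frozen afterwards),
   followed by univariate slice refreshes of each fixed effect -- their
   conditionals are log-concave, and the slice steps decorrelate the
   block far faster than the random walk alone.
2. each $u_i$: univariate slice sampling from Poisson $\times$ CAR
   conditional, then an *exchange scan*: only $u_i + v_i$ enters the
   likelihood, so the split between spatial and unstructured effect is
   resampled exactly from its Gaussian conditional with the linear
   predictor held fixed. Without this the $u/v$ (hence
   $\tau_u/\tau_v$) decomposition mixes only by diffusion -- the
   well-known weak identifiability of the convolution model.
3. per-component recentering of $u$ (the ICAR is defined only up to a
   constant per connected component); the mean removed from the largest
   component is folded into $\alpha_0$ so the linear predictor there is
   unchanged. Areas with no neighbour (islands) keep $u_i = 0$ and are
   informed by covariates and $v_i$ alone; the alternative of manually
   adding an edge is available in the graph module.
4. each $v_i$: univariate slice sampling.
5. conjugate Gamma draws for $\tau_u$, $\tau_v$, plus an interweaving
   step: the effect is re-expressed in non-centered form
   ($\tilde u = \sqrt{\tau_u}\, u \sim \mathrm{ICAR}(1)$) and
   $\log\tau$ is slice-sampled there, so a precision move rescales the
   whole effect vector and traverses the funnel-shaped ridge that the
   centered conjugate draw explores only slowly.

Defaults are 10,000 iterations, 4,000 warm-up, 3 chains, no thinning.
Convergence is gated quantitatively (split-chain $\widehat R < 1.05$,
ESS > 400 by default) rather than graphically, so a pipeline run can
assert convergence unattended.

Covariates enter as the posterior-mean BEFA factor scores plus any raw
columns the configuration adds -- a two-stage plug-in without
propagation of factor-score uncertainty, matching how such analyses are
typically run.

# The synthetic study generator

Because the kind of data this analysis consumes (forensic case counts,
national survey aggregates) is restricted, the package carries a
generator that emulates the study conditions end to end:

* **Region**: 33 areas -- a 5x6 block of unit squares, two squares
  appended east, and one island with no neighbour, exercising the
  degree-0 code path (real national maps contain archipelagos).
* **Populations**: log-normal, median 200,000 women at risk per area,
  `sdlog` 0.6, spanning roughly 50k--1M.
* **Covariates**: ten proportion-scale columns with means 8--78% and
  SDs of 2--10 percentage points, organised in three dedicated factors
  (household decision-making; education/purchase autonomy, with "no
  education" loading negatively; reproductive-health knowledge) plus
  one unallocated noise column.
* **Risk surface**: $\alpha_0 = -0.2$, $\beta = (0.3, -0.2, 0.1)$ on
  standardized factor scores, $\sigma_u = 0.3$, $\sigma_v = 0.1$,
  base rate 0.017 events per woman over the pooled study window --
  effect magnitudes in the range such analyses report.

All randomness flows from one integer seed through named substreams
(populations, scores, noise, u, v, y), so adding a component to the
generator never perturbs another component's draws, and the same seed
is bit-reproducible.

What the generator does *not* emulate: individual-level survey records
(simulation is at the area-aggregate level the analysis consumes),
reporting artefacts such as underreporting that varies by area, and
real boundary geometry. Passing tests therefore demonstrate that the
machinery recovers known structure under the model's own assumptions,
not that those assumptions hold in any particular real dataset.

# Numerical choices and degenerate inputs

* ICAR draws are spectral: normal coordinates with variance
  $\sigma_u^2/\lambda_k$ on positive-eigenvalue eigenvectors, zero mass
  on component indicators, then exact per-component recentering.
* `expected_counts()` refuses all-zero case totals (the SMR is
  undefined); `smr()` names the area on a zero expected count.
* Geometry contiguity uses exact coordinate predicates by default; a
  `snap` tolerance is available for dirty boundary exports. Queen
  means any shared point; rook requires a positive-length shared
  stretch (or two distinct touch points, which on areal boundaries
  implies one).
* Quadrant classification (`classify_areas()`) labels exact zeros on
  the positive side.
* `log_posterior_bym()` returns `-Inf` for overflowing states instead
  of raising, so samplers and optimizers can treat it as a bare
  objective.
* ESS of a zero-variance chain is reported as the total draw count with
  a `zero_variance` flag rather than NaN.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run the generator at the study
scale (33 areas) with the full 10,000/4,000 protocol for the headline
recovery and calibration checks (20 and 5 seeded replicates
respectively, 2 chains each), m = 200 for factor-analysis recovery, and
smaller lattices (9--16 areas, shorter chains) for unit-level
distributional checks. These sizes were chosen so each property is
tested at conditions where its expected behaviour is unambiguous.

# Known limitations

* Orthogonal factors only; no cross-loadings, oblique rotations or
  ordinal measurement models.
* Two-stage plug-in of factor scores into the risk model; factor-score
  uncertainty is not propagated.
* No BYM2/Leroux reparameterization and no spatio-temporal extension;
  counts are pooled over the study window.
* The acceptance index reported per covariate is the raw MH acceptance
  rate; retention decisions use the posterior null-allocation
  probability, which is the operational rule.
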