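---
title: "Coupled life-cycle state-space models for cod and haddock: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled life-cycle state-space models for cod and haddock: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gadlife)
```

# The system and the models

`gadlife` implements a pair of age-structured life-cycle state-space
models for two interacting, harvested gadoids of the Barents Sea:
Northeast Arctic haddock and Atlantic cod.  Adult cod prey on juvenile
haddock; at older ages the two species are competitors.  The package
couples the two single-species models semi-integrally: the cod model is
run (or fitted) first, its biomass over ages 3–12 enters the haddock
model as the predation covariate $G_y$, and counterfactual cod harvest
scenarios are propagated into haddock trajectories by hindcasting.

## Haddock process model

Ages $0$–$A$ (0-based), one time step per year.  Spawning biomass uses
ages 1 and older,
$$S_y = \sum_{a\ge 1} N_{a,y} P_{a,y} W_{a,y},$$
with maturity $P$ and weight-at-age $W$ (kg) supplied as data tables.
Recruitment is a stochastic exponential stock–recruitment relationship
with a temperature-dependent fecundity:
$$\ln N_{0,y} \sim \mathcal N\!\left(\ln(S_y\,\varphi_y) - m_e -
\sigma_\varphi^2/2,\; \sigma_\varphi^2\right),\qquad
\varphi_y = \varphi\,\delta_T\,e^{T_\varphi (T_y - \bar T)},$$
where $T_y$ is the winter (December–February) temperature and
$\delta_T = Y/\sum_y e^{T_\varphi (T_y - \bar T)}$ makes the mean of
$\varphi_y$ over the years equal $\varphi$ *exactly* — that unbiasedness
is the reason the correction exists, and it is what fixes the
multiplicative placement of $\delta_T$ (an additive reading of the
printed exponent would not have this property).  The $-\sigma_\varphi^2/2$
term is the usual lognormal mean correction, so
$E[N_{0,y}] = S_y \varphi_y e^{-m_e}$.  Fecundity $\varphi$ is in eggs
per gram of spawning biomass; $S_y$ (kg) is converted internally.

Total mortality decomposes as $Z = M + F$.  For juvenile ages the
natural mortality carries cod predation and compensatory density
dependence,
$$M_{a,y} = m_a\,\delta_a\,e^{g_a G_y}\,(1 + D_a N_{a,y}),\qquad
\delta_a = Y\Big/\sum_y e^{g_a G_y},$$
with $m_a$ the baseline for ages $<4$ and the fixed adult $M_{4+}$
otherwise.  The predation coefficients $g_a$ are defined for ages 0–4
(the analysis stage reports the predation effect through age 4, so the
multiplicative $\delta_a e^{g_a G_y}$ factor applies to age 4 on top of
$M_{4+}$); density dependence $D_a$ is restricted to ages $<4$.  With
$D_a = 0$ the mean over years of $M_{a,y}$ equals its baseline exactly,
again by construction of $\delta_a$.

Fishing mortality follows a random-walk log effort:
$F_{a,y} = f_a e^{e_y}$ for ages $\ge 3$, $e_{y+1} = e_y + \sigma_F
\varepsilon_y$.  Survival is $N_{a+1,y+1} = N_{a,y}e^{-Z_{a,y}}$ with
the oldest age terminal by default (a plus-group is available behind a
flag).  Latent catches follow the Baranov equation
$$C_{a,y} = \frac{F_{a,y}}{F_{a,y}+M_{4+}} N_{a,y}
\left(1 - e^{-(F_{a,y}+M_{4+})}\right),$$
using the fixed adult mortality in the competing-risk split as the
equation is written; a configuration switch substitutes the
age-specific $M_{a,y}$ instead.

## Haddock observation model

Reported landings are lognormal and unbiased for the latent catch,
$L_{a,y} = C_{a,y}\,e^{\varepsilon_{L} - \sigma_{L,a}^2/2}$; survey
indices (ages 1+) are
$I_{a,y} = q_a N_{a,y}\, e^{\varepsilon_{I} + \xi_y}$ with catchability
$q_a$ and a year effect $\xi_y \sim \mathcal N(0, \sigma_\xi^2)$ shared
across ages within a year — correlated observation errors from shared
survey conditions.

## Cod process model

Cod is tracked from eggs through age 13: $N_e = SSB\cdot\tau\,
e^{\sigma_{sp}\varepsilon}$, $N_l = N_e e^{-t_e M_e}$ and
$N_z = N_l e^{-t_l M_l + \psi_l T_l}$, with $T_l$ the June–August
temperature; the temperature term sits outside the duration product so
positive $\psi_l$ raises 0-group survival, which is the stated biology.
Transitions into ages 1–4 carry inter-cohort (cannibalism) density
dependence,
$$N_{a,y} = \frac{N_{a-1,y-1}}{1 + \beta_a N_{a-1,y-1}}\,e^{-M_j},$$
whose realized survival is strictly decreasing in abundance
(compensatory) and saturates at $e^{-M_j}/\beta_a$.  The printed
transition ranges leave the 0-group$\to$1, 1$\to$2, 4$\to$5 and
9$\to$13 steps unstated; the package closes the gaps by using the
juvenile form up to age 4 and the adult form
$N_{a,y} = N_{a-1,y-1} e^{-(F_{a-1,y-1}+M_{4+})}$ from age 4 upward
(fishing starts at age 4), tracking ages to 13 so the ages 3–12
biomass covariate is computable.  All bounds are configurable.  Cod
selectivity is log-scale ($F_{a,y} = e^{f_a + f_y}$); the observation
model duplicates the haddock one.

The covariate delivered to haddock is unweighted total biomass over
ages 3–12 in metric tons; a maturity-weighted variant is available
behind a flag (the two phrasings "mature population biomass" and
"biomass from age 3 to 12" differ; the unweighted reading is the
default because the age range is stated explicitly).

# Synthetic data

`lc_scenario()` + `generate_dataset()` emulate the *structure* of
ICES-style assessment inputs — age-by-year weight, maturity, survey
index and landings tables plus annual temperature series — with known
parameter truth, so estimation, hindcasting and the analysis stages are
testable without any download.  No attempt is made to imitate actual
survey values.

Two profiles are shipped.  `"paper"` has the dimensions of the real
application: haddock ages 0–9 over 1980–2012 (33 years) nested in cod
ages 1–13 over 1959–2012 (54 years).  `"tiny"` (haddock ages 0–5 over
20 years, cod ages 1–6 over 26 years) is the scale used for repeated
estimation experiments.  Default parameter values were chosen once for
demographic realism: lifetime reproductive rate near one at the mean
environment (computed from the survivorship schedule, which fixes the
egg-stage mortalities $m_e$ and $M_e$ and the equilibrium age
structures used as initial abundances), juvenile mortality falling with
age, logistic maturity, von-Bertalanffy-type weights, dome-shaped
survey catchability, a warming trend of 0.3 °C per decade with
interannual noise, and positive predation on haddock ages 0–1.  The
resulting populations fluctuate within a factor of ~3 over a run —
comparable to real stock-assessment series.  In the tiny profile the
density-dependence coefficients and the survey year effect are zero
(they are active in the paper profile), which keeps the small recovery
experiments well identified; this is a deliberate simplification of the
tiny profile, not of the model.

What the generator does *not* emulate: model misspecification (data are
generated from the fitted model's own equations), survey-design
artefacts such as age-reading error or spatially varying catchability,
and autocorrelated environmental noise beyond the linear trend.
Passing recovery tests therefore demonstrates internal calibration of
the estimator, not robustness to the mismatches real data would add.

# Estimation

The joint posterior is over a configured subset of the parameters plus
the latent process innovations, in the non-centred parameterization:
recruitment/spawning innovations and effort increments are sampled as
standard normals and the abundance states are reconstructed
deterministically.  The correlated survey year effect is marginalized
analytically (compound-symmetry covariance across ages within a year,
inverted by a rank-one update), which removes one latent per year at no
approximation.  Missing observations contribute exactly zero likelihood
terms.

Priors default to weakly informative shapes — Normal on unconstrained
coefficients, Normal on the log scale for positive quantities,
half-Normal for SDs — all fully overridable through `lc_priors()`.
These defaults are this package's choices; the original application's
prior table is not reproduced here.  The default estimation subset for
haddock (`recovery_priors_haddock()`) is the temperature effect
$T_\varphi$, catchabilities $q_{1..3}$, predation $g_0$, a common index
SD $\sigma_I$, and the initial log effort; the $g_0$ prior SD is set
from the spread of the observed covariate (a unit-scaling choice).
Everything else is held at its baseline value — the usual design for a
scaled-down recovery experiment.

The sampler (`lc_mcmc()`) is an adaptive Metropolis-within-Gibbs:
componentwise Gaussian random-walk proposals with per-coordinate scales
adapted during warm-up toward 0.44 acceptance, plus two extra move
types that target the posterior's known slow directions: (a) joint
proposals from the running empirical covariance of the chain
(adaptive-Metropolis moves, target 0.23), and (b) exact *ridge moves*
that shift $T_\varphi$ (or $g_0$) together with compensating
recruitment innovations so the latent trajectory is unchanged — a
volume-preserving shear in which only prior terms decide acceptance.
Without the ridge moves the $T_\varphi$–innovation trade-off dominates
the autocorrelation time and the convergence rule below is not reliably
met at desk scale.  All adaptation freezes at the end of warm-up.  The
haddock density and chain loop are compiled (Rcpp); an independent R
implementation of the same density is kept in the test suite and
checked against the compiled one at random points.  The cod density
runs in R through the identical sampler algorithm.

Settings: 3 chains, 2,000 warm-up sweeps, 2,000 retained sweeps by
default (`mcmc_settings()`); the full protocol of the original
application (3 chains, 250,000 burn-in, 250,000 iterations thinned by
1,000) is available as `profile = "full"`.  Convergence is flagged by
the Gelman–Rubin statistic: R-hat $< 1.1$ for every model parameter
(`rhat()` implements the classic non-split formula).  Chains start from
prior-centre values with independent overdispersion (SD 0.5), so R-hat
is a meaningful between-chain diagnostic.

The recovery experiment the tests run: 10 replicate tiny-profile
datasets, each fitted as above; the 95% credible intervals must cover
the generating $T_\varphi$, $q_{1..3}$, $g_0$ and $\sigma_I$ in at
least 8 of 10 replicates, with all parameter R-hats below 1.1.  One fit
takes a few seconds on one CPU; the replicate set runs in about a
minute.

# Hindcasting

`build_scenarios()` spans harvest intensities $F_m$ from 0.5 to 1.5.
The default semantics is a *multiplier* on the cod fishing-mortality
surface, implemented as a $\log F_m$ shift of the selectivity — this
preserves the estimated selectivity pattern and the effort random walk,
and makes $F_m = 1$ reproduce the baseline run bit-exactly under a
shared seed.  An absolute-F mode is provided.  For each ensemble member
the cod model is re-simulated with fresh process noise, its ages 3–12
biomass is handed to a haddock parameter draw, and the haddock model is
re-simulated (`lc_hindcast()`).  Posterior parameter draws enter via
`posterior_params()`; a point estimate or known truth can be used for
either species.

Two numerical design choices matter here.  First, the $\delta_a$
predation corrections are *frozen at their baseline (estimation-period)
values* inside scenario simulations: recomputing them from a
counterfactual $G_y$ series would re-normalize mean predation mortality
and cancel the very contrast the scenario creates.  Second, scenarios
share innovation streams (common random numbers), so ensemble members
are paired across the $F_m$ grid and scenario contrasts are not diluted
by independent process noise.  Ensembles are summarized by pointwise
means and central 95% envelopes; the variability statistic is the
across-year standard deviation of the ensemble-mean trajectory, with
the mean across-draw SD reported alongside (the original figure does
not define its statistic; both readings are reported).

# Interaction analyses

`predation_summary()` reports, per haddock age 0–4, the posterior of
$g_a$ scaled by the mean cod biomass, with 95% bounds and a sign
classification (an interval containing zero is "not significant").

`weighted_smooth()` regresses an estimated log-abundance series on a
covariate (temperature, or the cod inter-cohort interaction) with a
penalized thin-plate smooth, observations weighted inversely to their
squared standard errors (normalized to mean one, so only relative
weights matter).  The smooth basis dimension is capped at 5 — with at
most 33 annual points a larger basis is not supportable — and the
penalty is selected by generalized cross-validation; the report carries
the percent deviance explained and the GCV score, assembled across
stages by `deviance_table()`.  The inter-cohort covariate is the
realized year-varying effect $\beta_a N_{a-1,y-1}$
(`intercohort_series()`): the interaction *strength* is a parameter,
so the year-indexed quantity regressed against is its product with the
preceding cohort's abundance; any other supplied series can be used
instead.

# Numerical choices and degenerate inputs

Zero spawning biomass yields zero recruits (legal, degenerate); the
Baranov equation handles $F = M = 0$ as the zero-catch limit without
dividing by zero.  Proposals that overflow $e^{g_a G_y}$ evaluate to
log-density $-\infty$ rather than NaN, so the sampler rejects them.
Observation SDs of exactly zero are allowed in simulation (the noise
factor collapses to its mean correction) but not in estimation, where
the lognormal density requires positive SDs.  Exact-zero variance
draws give R-hat 1 by convention when chains agree.  All random draws
are consumed in a fixed documented order (recruitment series, effort
increments, landings block, index block, year effects), so a single
seed reproduces a run bit-exactly.

# Known limitations

The coupling is one-way (cod affects haddock); the reverse interaction
and any third species are out of scope, as is fully joint two-species
estimation — the semi-integrated design, with the cod biomass entering
haddock as a fixed covariate, is deliberate.  The sampler is a
random-walk scheme: adequate at the tested scales, but a
gradient-based sampler would scale better to the full-dimension
problem.  Forward forecasting beyond the observed year range is
intentionally not provided; the hindcast design exists precisely to
avoid overconfident projection.
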