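# gadlife

Coupled age-structured life-cycle state-space models for two
interacting, harvested gadoids: Northeast Arctic haddock
(*Melanogrammus aeglefinus*) and Atlantic cod (*Gadus morhua*) in the
Barents Sea.  Adult cod prey on juvenile haddock; at older ages the two
species compete.  The package is for quantitative fisheries ecologists
who want to (i) estimate stage-specific interaction strengths from
survey indices and landings while separating process stochasticity from
observation error, and (ii) ask counterfactual management questions —
*what would the haddock stock have done had cod been fished harder?* —
by hindcasting over a past period with known environmental forcing.

## The models

Each species is a state-space model on an age-by-year grid: a process
model for the latent abundances and an observation model tying them to
error-prone data.

**Haddock** (ages 0–9): spawning biomass `S_y = Σ_a N_ay P_ay W_ay`
feeds a stochastic, temperature-dependent recruitment

    ln N_0y ~ N( ln(S_y φ_y) − m_e − σ_φ²/2 , σ_φ² ),
    φ_y = φ δ_T exp(T_φ (T_y − T̄)),   δ_T = Y / Σ_y exp(T_φ (T_y − T̄)),

so the mean fecundity over years is exactly `φ`.  Juvenile natural
mortality carries cod predation and compensatory density dependence,

    M_ay = m_a δ_a exp(g_a G_y) (1 + D_a N_ay),   δ_a = Y / Σ_y exp(g_a G_y),

where `G_y` is cod biomass over ages 3–12 (metric tons).  Fishing
mortality follows a random-walk log effort (`F_ay = f_a e^{e_y}`,
ages 3+), catches follow the Baranov competing-risk split, landings are
unbiased-lognormal around latent catch, and survey indices (ages 1–9)
are `I_ay = q_a N_ay exp(ε + ξ_y)` with a year effect `ξ_y` shared
across ages.

**Cod** (eggs → larvae → 0-group → ages 1–13): early survival depends
on summer temperature (`exp(−t_l M_l + ψ_l T_l)`), juvenile transitions
carry inter-cohort cannibalism `N/(1+βN) e^{−M_j}`, the fishery acts
from age 4, and the observation model mirrors haddock's.

Estimation is Bayesian: an adaptive Metropolis-within-Gibbs sampler
(compiled likelihood, non-centred latent innovations, analytically
marginalized year effect, tailored moves for the slow posterior
directions) with the Gelman–Rubin R-hat < 1.1 convergence rule.  A
synthetic-data module generates complete two-species datasets with
known truth, mirroring the shape of ICES-style assessment tables.

## Worked example

Simulate a small two-species system with known truth, fit the haddock
model, and hindcast cod harvest scenarios:

```r
library(gadlife)

sc  <- lc_scenario("tiny", seed = 1)          # truth: T_phi = 0.3, q1 = 0.5,
ds  <- generate_dataset(sc)                   #   q2 = 0.7, q3 = 0.8, g0 = 3e-4
fit <- lc_fit(ds$haddock, "haddock", sc$haddock,
              recovery_priors_haddock(ds$haddock), mcmc_settings(seed = 1))
print(fit)
```

```
Life-cycle state-space model fit (haddock)
  7 sampled parameters + 39 latent innovations, 20 years
  3 chains x 2000 retained draws; max R-hat (parameters) = 1.012 -> converged (R-hat < 1.1)
   param    median        sd       q2.5    q97.5  rhat
   T_phi 0.1529032 0.2067242 -0.2532273 0.561171 1.001
    q[1] 0.5081188 0.0355199  0.4460676 0.586097 1.002
    q[2] 0.6156709 0.0407384  0.5399532 0.700820 1.001
    q[3] 0.7632462 0.0501979  0.6710086 0.871560 1.001
    g[0] 0.0005259 0.0004178 -0.0003035 0.001348 1.000
 sigma_I 0.2696096 0.0214214  0.2331993 0.315635 1.001
      e0 0.0657273 0.0578877 -0.0490018 0.178495 1.012
```

Every 95% interval covers its generating value: the catchabilities are
recovered tightly, while the temperature effect and the predation
coefficient are honestly wide — twenty years of one covariate only
carry so much information, and the intervals say so.

```r
cb <- cod_biology(ds$cod$W, ds$cod$P, ds$cod$T)
hb <- haddock_biology(ds$haddock$W, ds$haddock$P, ds$haddock$T, ds$haddock$G)
hc <- lc_hindcast(sc$cod, sc$haddock, build_scenarios(c(0.5, 1.0, 1.5), draws = 40),
                  cb, hb, sc$init_cod, sc$init_had, seed = 1)
print(hc)
```

```
Harvest-intensity hindcast:
  Fm mean_cod_biomass_t mean_had_abundance mean_had_ssb_kg had_variability
 0.5               3305            4463775          726577         2630948
 1.0               2810            6119714          959065         1899985
 1.5               2400            8186716         1241909          825547
```

Tripling cod harvest intensity (Fm 0.5 → 1.5) lowers mean cod biomass
by ~27% and, by releasing predation on haddock ages 0–1, nearly doubles
mean haddock abundance and spawning biomass — the compensatory pattern
the coupled models encode.

The downstream analysis stage (`predation_summary()`,
`weighted_smooth()`, `deviance_table()`) summarizes stage-specific
predation effects and regresses estimated log-abundances on temperature
or on the cod inter-cohort interaction with error-weighted penalized
smooths.

A command-line surface wraps the same pipeline:
`run_cli(c("simulate", "--profile", "tiny", "--seed", "1", "--out", "data/"))`,
with subcommands `simulate`, `validate`, `fit`, `hindcast`, `analyze`
(see `inst/cli/gadlife.R` for the Rscript wrapper).

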