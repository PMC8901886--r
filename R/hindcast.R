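## Hindcasting engine: re-simulate the observed period under
## counterfactual cod harvest intensities and propagate the resulting
## predator-biomass covariate through the haddock model.

#' Build harvest-intensity scenarios
#'
#' One scenario per harvest-intensity value `Fm`.  In `"multiplier"`
#' mode (default) `Fm` scales the cod fishing-mortality surface
#' `F_ay` — implemented as a `log(Fm)` shift of the selectivity, which
#' preserves the estimated selectivity pattern and the effort random
#' walk; `Fm = 1` reproduces the baseline run exactly under a shared
#' seed.  In `"absolute"` mode `Fm` is imposed as a flat
#' fishing-mortality level on all fished ages and years.
#'
#' @param fm_grid numeric vector of harvest intensities (default the
#'   0.5-1.5 range of the study design).
#' @param mode `"multiplier"` or `"absolute"`.
#' @param draws ensemble size per scenario (>= 1).
#' @return list of `harvest_scenario` objects.
#' @export
build_scenarios <- function(fm_grid = seq(0.5, 1.5, by = 0.25),
                            mode = c("multiplier", "absolute"),
                            draws = 100L) {
  mode <- match.arg(mode)
  if (!length(fm_grid)) stop("empty Fm grid")
  if (any(fm_grid <= 0)) stop("harvest intensities must be > 0")
  if (anyDuplicated(fm_grid)) stop("duplicate Fm values in the grid")
  if (draws < 1L) stop("draws must be >= 1")
  lapply(fm_grid, function(fm) {
    structure(
      list(Fm = fm, mode = mode, draws = as.integer(draws)),
      class = "harvest_scenario"
    )
  })
}

# apply a harvest scenario to one cod parameter set
.scenario_params <- function(params, scenario) {
  if (scenario$mode == "multiplier") {
    params$f_a <- params$f_a + log(scenario$Fm) # cod selectivity is log scale
    params
  } else {
    params # absolute mode handled via F_override
  }
}

#' Hindcast the cod population under a harvest scenario
#'
#' For each ensemble member, simulates the cod life cycle over the year
#' range with fishing mortality set by the scenario and fresh process
#' noise, and emits the total-biomass trajectory and the
#' predator-biomass covariate `G_y` consumed by the haddock model.
#'
#' @param object cod parameters: a single [cod_params()] (known truth or
#'   point estimate, recycled over draws) or a list of parameter sets
#'   (e.g. from [posterior_params()]).
#' @param scenario a `harvest_scenario` from [build_scenarios()].
#' @param biology a [cod_biology()].
#' @param n_init first-year abundance at ages 1+.
#' @param seed integer seed for the ensemble.
#' @param process_noise set `FALSE` for the deterministic skeleton.
#' @return list with matrices `biomass` and `G` (draws x years) and the
#'   scenario.
#' @export
hindcast_cod <- function(object, scenario, biology, n_init, seed = 1L,
                         process_noise = TRUE) {
  stopifnot(inherits(scenario, "harvest_scenario"))
  par_list <- if (inherits(object, "cod_params")) {
    rep(list(object), scenario$draws)
  } else {
    object
  }
  if (length(par_list) != scenario$draws) {
    stop("need one parameter set per draw (", scenario$draws, ")")
  }
  set.seed(seed)
  yrs <- names(biology$T_l)
  bio_mat <- G_mat <- matrix(
    NA_real_, scenario$draws, length(yrs),
    dimnames = list(NULL, yrs)
  )
  for (i in seq_len(scenario$draws)) {
    p <- .scenario_params(par_list[[i]], scenario)
    f0 <- attr(par_list[[i]], "e0")
    if (is.null(f0)) f0 <- 0
    Fov <- NULL
    if (scenario$mode == "absolute") {
      Fov <- matrix(0, length(p$ages), length(yrs))
      Fov[p$ages >= p$fish_min_age, ] <- scenario$Fm
    }
    sim <- simulate_cod(p, biology, n_init,
      seed = NULL, f0 = f0,
      process_noise = process_noise, obs_noise = FALSE, F_override = Fov
    )
    W <- t(biology$W[yrs, as.character(p$ages), drop = FALSE])
    bio_mat[i, ] <- colSums(sim$N * W) / 1000 # total biomass, metric tons
    G_mat[i, ] <- sim$G
  }
  list(biomass = bio_mat, G = G_mat, scenario = scenario)
}

#' Hindcast the haddock population given a predator-biomass ensemble
#'
#' Pairs each haddock parameter draw with one `G_y` trajectory from the
#' cod hindcast and re-simulates the haddock life cycle with fresh
#' process noise, returning total-abundance and spawning-biomass
#' trajectory ensembles.
#'
#' @param object haddock parameters: a single [haddock_params()]
#'   (recycled) or a list of parameter sets from [posterior_params()].
#' @param G_ensemble draws x years matrix of predator biomass (metric
#'   tons), year names covering the haddock biology years.
#' @param scenario a `harvest_scenario` (sets the ensemble size).
#' @param biology a [haddock_biology()]; its `G_y` entry is replaced per
#'   draw.
#' @param n_init first-year abundance at ages 1+.
#' @param seed integer seed.
#' @param process_noise set `FALSE` for the deterministic skeleton.
#' @return list with matrices `abundance` (total individuals, all ages)
#'   and `ssb` (kg), both draws x years, and the scenario.
#' @export
hindcast_haddock <- function(object, G_ensemble, scenario, biology, n_init,
                             seed = 1L, process_noise = TRUE) {
  stopifnot(inherits(scenario, "harvest_scenario"))
  par_list <- if (inherits(object, "haddock_params")) {
    rep(list(object), scenario$draws)
  } else {
    object
  }
  if (length(par_list) != scenario$draws) {
    stop("need one haddock parameter set per draw (", scenario$draws, ")")
  }
  if (nrow(G_ensemble) != scenario$draws) {
    stop("G ensemble has ", nrow(G_ensemble), " draws, scenario needs ", scenario$draws)
  }
  yrs <- names(biology$T_y)
  if (!all(yrs %in% colnames(G_ensemble))) {
    stop("G ensemble does not cover the haddock years")
  }
  set.seed(seed)
  N_mat <- S_mat <- matrix(
    NA_real_, scenario$draws, length(yrs),
    dimnames = list(NULL, yrs)
  )
  G_base <- biology$G_y[yrs] # estimation-period covariate
  for (i in seq_len(scenario$draws)) {
    bio <- biology
    bio$G_y[yrs] <- G_ensemble[i, yrs]
    e0 <- attr(par_list[[i]], "e0")
    if (is.null(e0)) e0 <- 0
    p <- par_list[[i]]
    # predation corrections frozen at their baseline values: the fitted
    # mortality response M(G) is carried into the counterfactual, not
    # re-normalized over the scenario's own G series
    delta_base <- vapply(
      names(p$g_a),
      function(a) length(G_base) / sum(exp(p$g_a[[a]] * G_base)), numeric(1)
    )
    sim <- simulate_haddock(p, bio, n_init,
      seed = NULL, e0 = e0,
      process_noise = process_noise, obs_noise = FALSE,
      delta_a = delta_base
    )
    N_mat[i, ] <- colSums(sim$N)
    S_mat[i, ] <- sim$SSB
  }
  list(abundance = N_mat, ssb = S_mat, scenario = scenario)
}

#' Summarize a trajectory ensemble
#'
#' Pointwise mean and central 95% credibility envelope across draws,
#' plus two variability statistics: the across-year standard deviation
#' of the ensemble-mean trajectory (`variability`) and the mean
#' across-draw standard deviation (`spread`).
#'
#' @param ensemble draws x years matrix.
#' @return list with data frame `by_year` (year, mean, lo95, hi95) and
#'   scalars `variability`, `spread`.
#' @export
summarize_ensemble <- function(ensemble) {
  if (!length(ensemble)) stop("empty ensemble")
  ensemble <- as.matrix(ensemble)
  qs <- apply(ensemble, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  mu <- colMeans(ensemble)
  by_year <- data.frame(
    year = as.integer(colnames(ensemble)), mean = mu,
    lo95 = qs[1, ], hi95 = qs[2, ], row.names = NULL
  )
  list(
    by_year = by_year,
    variability = stats::sd(mu),
    spread = mean(apply(ensemble, 2, stats::sd))
  )
}

#' Run the full two-species hindcast over a harvest-intensity grid
#'
#' For each scenario: hindcast cod under the scaled harvest, feed each
#' draw's biomass covariate into the haddock model, and summarize the
#' cod-biomass, haddock-abundance and haddock-SSB ensembles.
#'
#' @param cod_object,had_object parameter sets (single objects or
#'   per-draw lists) for the two species.
#' @param scenarios list from [build_scenarios()].
#' @param cod_biology,had_biology biology objects.
#' @param cod_init,had_init first-year abundances.
#' @param seed integer seed.  All scenarios share the same innovation
#'   streams (common random numbers), so ensemble members are paired
#'   across harvest intensities and scenario contrasts are not diluted
#'   by independent process noise.
#' @param process_noise passed through to the simulators.
#' @return object of class `lc_hindcast`: per-scenario summaries and raw
#'   ensembles.
#' @export
lc_hindcast <- function(cod_object, had_object, scenarios,
                        cod_biology, had_biology, cod_init, had_init,
                        seed = 1L, process_noise = TRUE) {
  res <- lapply(seq_along(scenarios), function(s) {
    sc <- scenarios[[s]]
    hc <- hindcast_cod(cod_object, sc, cod_biology, cod_init,
      seed = seed, process_noise = process_noise
    )
    hh <- hindcast_haddock(had_object, hc$G, sc, had_biology, had_init,
      seed = seed + 1000L, process_noise = process_noise
    )
    list(
      Fm = sc$Fm,
      cod_biomass = summarize_ensemble(hc$biomass),
      had_abundance = summarize_ensemble(hh$abundance),
      had_ssb = summarize_ensemble(hh$ssb),
      ensembles = list(
        cod_biomass = hc$biomass, G = hc$G,
        had_abundance = hh$abundance, had_ssb = hh$ssb
      )
    )
  })
  structure(list(scenarios = res, seed = seed), class = "lc_hindcast")
}

#' @export
print.lc_hindcast <- function(x, ...) {
  cat("Harvest-intensity hindcast:\n")
  df <- do.call(rbind, lapply(x$scenarios, function(s) {
    data.frame(
      Fm = s$Fm,
      mean_cod_biomass_t = mean(s$cod_biomass$by_year$mean),
      mean_had_abundance = mean(s$had_abundance$by_year$mean),
      mean_had_ssb_kg = mean(s$had_ssb$by_year$mean),
      had_variability = s$had_abundance$variability
    )
  }))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.lc_hindcast <- function(x, quantity = c("had_abundance", "had_ssb", "cod_biomass"), ...) {
  quantity <- match.arg(quantity)
  old <- graphics::par(mfrow = c(1, length(x$scenarios)), mar = c(4, 4, 2, 0.5))
  on.exit(graphics::par(old))
  for (s in x$scenarios) {
    b <- s[[quantity]]$by_year
    graphics::plot(b$year, b$mean,
      type = "l", ylim = range(b$lo95, b$hi95),
      xlab = "year", ylab = quantity, main = sprintf("Fm = %.2f", s$Fm)
    )
    graphics::lines(b$year, b$lo95, lty = 2)
    graphics::lines(b$year, b$hi95, lty = 2)
  }
  invisible(x)
}
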