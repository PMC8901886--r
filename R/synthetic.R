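## Synthetic two-species datasets with known parameter truth.
##
## The generator emulates the structure of ICES-style assessment inputs
## (age-by-year weight, maturity, survey-index and landings tables plus
## annual temperature series): lognormal observation errors, correlated
## year effects, effort random walks and temperature-dependent
## recruitment.  It makes no attempt to imitate actual survey values,
## only their statistical shape.

#' Synthetic study scenario
#'
#' Bundles year ranges, true parameters for both species, the
#' temperature model and initial abundances.  Two profiles ship with the
#' package:
#'
#' * `"tiny"` — haddock ages 0-5 over 20 years nested in cod ages 1-6
#'   over 26 years; small enough for repeated estimation experiments.
#' * `"paper"` — the full dimensions of the Barents Sea application:
#'   haddock ages 0-9 over 33 years (1980-2012) nested in cod ages 1-13
#'   over 54 years (1959-2012).
#'
#' Default parameter values are chosen so that both populations are
#' demographically balanced (lifetime reproductive rate near one at the
#' mean environment) with realistic age patterns: juvenile mortality
#' falling with age, logistic maturity, von-Bertalanffy-type weights,
#' dome-shaped survey catchability, and a slow warming trend with
#' interannual noise.
#'
#' @param profile `"tiny"` or `"paper"`.
#' @param seed integer seed stored with the scenario and used by
#'   [generate_dataset()].
#' @param dropout fraction of observation cells randomly set missing
#'   (default 0; real assessment tables have gaps).
#' @return list of class `lc_scenario`.
#' @export
lc_scenario <- function(profile = c("tiny", "paper"), seed = 1L, dropout = 0) {
  profile <- match.arg(profile)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (profile == "tiny") {
    years_cod <- 1987:2012
    years_had <- 1993:2012
    had <- haddock_params(
      ages = 0:5,
      phi = 100, T_phi = 0.3, m_e = 10.22, sigma_phi = 0.35,
      m_a = c(`0` = 1.0, `1` = 0.6, `2` = 0.42, `3` = 0.35), M4plus = 0.25,
      g_a = c(`0` = 3e-4, `1` = 1.5e-4, `2` = 5e-5, `3` = 0, `4` = 0),
      D_a = c(`0` = 0, `1` = 0, `2` = 0, `3` = 0),
      f_a = c(`3` = 0.15, `4` = 0.25, `5` = 0.3), sigma_F = 0.1,
      q_a = c(`1` = 0.5, `2` = 0.7, `3` = 0.8, `4` = 0.6, `5` = 0.4),
      sigma_L_a = 0.1, sigma_I_a = 0.25, sigma_xi = 0
    )
    cod <- cod_params(
      ages = 1:6,
      tau = 5e5, sigma_sp = 0.4, M_e = 0.278, t_e = 30,
      M_l = 0.08, t_l = 60, psi_l = 0.12, M_j = 0.5,
      beta_a = c(`1` = 2.5e-7, `2` = 5e-8, `3` = 1e-8, `4` = 1e-8),
      M4plus = 0.3,
      f_a = log(c(`4` = 0.25, `5` = 0.35, `6` = 0.4)), sigma_f = 0.08,
      q_a = c(`1` = 0.3, `2` = 0.5, `3` = 0.7, `4` = 0.8, `5` = 0.6, `6` = 0.4),
      sigma_L_a = 0.1, sigma_I_a = 0.25, sigma_xi = 0,
      biomass_ages = 3:6
    )
    init_had <- c(1.84e6, 1.01e6, 6.6e5, 4.0e5, 2.4e5)
    init_cod <- c(8.1e5, 4.7e5, 2.85e5, 1.72e5, 9.9e4, 5.2e4)
    growth <- list(
      had = c(winf = 6, k = 0.25, a50 = 3.5, s = 0.7),
      cod = c(winf = 15, k = 0.2, a50 = 4.5, s = 0.7)
    )
  } else {
    years_cod <- 1959:2012
    years_had <- 1980:2012
    had <- haddock_params(
      ages = 0:9,
      phi = 100, T_phi = 0.3, m_e = 9.85, sigma_phi = 0.4,
      m_a = c(`0` = 1.2, `1` = 0.7, `2` = 0.5, `3` = 0.4), M4plus = 0.2,
      g_a = c(`0` = 3e-4, `1` = 1.5e-4, `2` = 5e-5, `3` = -2e-5, `4` = 0),
      D_a = c(`0` = 2e-8, `1` = 1e-8, `2` = 5e-9, `3` = 0),
      f_a = c(
        `3` = 0.05, `4` = 0.15, `5` = 0.3, `6` = 0.4, `7` = 0.45,
        `8` = 0.45, `9` = 0.45
      ), sigma_F = 0.1,
      q_a = c(
        `1` = 0.4, `2` = 0.6, `3` = 0.8, `4` = 0.8, `5` = 0.7,
        `6` = 0.5, `7` = 0.4, `8` = 0.3, `9` = 0.2
      ),
      sigma_L_a = 0.1, sigma_I_a = 0.3, sigma_xi = 0.1
    )
    cod <- cod_params(
      ages = 1:13,
      tau = 5e5, sigma_sp = 0.4, M_e = 0.285, t_e = 30,
      M_l = 0.08, t_l = 60, psi_l = 0.12, M_j = 0.45,
      beta_a = c(`1` = 2.5e-7, `2` = 5e-8, `3` = 1e-8, `4` = 1e-8),
      M4plus = 0.25,
      f_a = log(c(
        `4` = 0.1, `5` = 0.2, `6` = 0.3, `7` = 0.35, `8` = 0.4,
        `9` = 0.4, `10` = 0.4, `11` = 0.4, `12` = 0.4, `13` = 0.4
      )),
      sigma_f = 0.08,
      q_a = stats::setNames(
        c(0.3, 0.5, 0.7, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.15, 0.1, 0.05),
        1:13
      ),
      sigma_L_a = 0.1, sigma_I_a = 0.3, sigma_xi = 0.1,
      biomass_ages = 3:12
    )
    init_had <- c(
      1.51e6, 7.48e5, 4.54e5, 2.89e5, 2.04e5, 1.24e5, 6.78e4, 3.54e4, 1.85e4
    )
    init_cod <- c(
      8.5e5, 5.2e5, 3.3e5, 2.1e5, 1.48e5, 9.42e4, 5.43e4, 2.98e4, 1.56e4,
      8.13e3, 4.24e3, 2.22e3, 1.16e3
    )
    growth <- list(
      had = c(winf = 6.5, k = 0.2, a50 = 5, s = 0.8),
      cod = c(winf = 18, k = 0.15, a50 = 6.5, s = 0.9)
    )
  }
  structure(
    list(
      profile = profile, seed = as.integer(seed), dropout = dropout,
      years_cod = years_cod, years_had = years_had,
      haddock = had, cod = cod,
      init_had = init_had, init_cod = init_cod, growth = growth,
      env = list(
        winter_mean = 4, winter_trend = 0.3, winter_sd = 0.4,
        summer_mean = 8, summer_trend = 0.3, summer_sd = 0.5
      ) # trends in degrees C per decade
    ),
    class = "lc_scenario"
  )
}

#' Generate winter and summer temperature series
#'
#' Gaussian interannual variation around a linear warming trend
#' (specified in degrees C per decade); the winter (December-February)
#' series drives haddock recruitment, the summer (June-August) series
#' cod larval survival.
#'
#' @param scenario an [lc_scenario()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with named vectors `winter` and `summer` over the cod
#'   (long) year range.
#' @export
generate_environment <- function(scenario, seed = scenario$seed) {
  if (!is.null(seed)) set.seed(seed)
  yrs <- scenario$years_cod
  t <- yrs - yrs[1]
  e <- scenario$env
  list(
    winter = stats::setNames(
      e$winter_mean + e$winter_trend / 10 * t + e$winter_sd * stats::rnorm(length(t)),
      yrs
    ),
    summer = stats::setNames(
      e$summer_mean + e$summer_trend / 10 * t + e$summer_sd * stats::rnorm(length(t)),
      yrs
    )
  )
}

# deterministic growth/maturity age curves of a profile
.age_curves <- function(g, ages) {
  W <- g[["winf"]] * (1 - exp(-g[["k"]] * (ages + 0.5)))^3
  P <- 1 / (1 + exp(-(ages - g[["a50"]]) / g[["s"]]))
  list(W = W, P = P)
}

#' Generate weight-at-age and maturity tables
#'
#' Weights follow a von-Bertalanffy-type length-weight curve scaled by a
#' lognormal year condition factor (shared across ages, so weight stays
#' strictly increasing in age within every year); maturity is a logistic
#' ogive in age with a small year-to-year shift of the midpoint.
#'
#' @param scenario an [lc_scenario()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list of [age_year_table()]s: `W_had`, `P_had` (haddock years)
#'   and `W_cod`, `P_cod` (cod years).
#' @export
generate_biology <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function(g, ages, yrs) {
    cond <- exp(0.05 * stats::rnorm(length(yrs)))
    a50y <- g[["a50"]] + 0.1 * stats::rnorm(length(yrs))
    W <- outer(cond, g[["winf"]] * (1 - exp(-g[["k"]] * (ages + 0.5)))^3)
    P <- t(vapply(
      a50y, function(m) 1 / (1 + exp(-(ages - m) / g[["s"]])),
      numeric(length(ages))
    ))
    list(
      W = age_year_table(W, yrs, ages, "weight", "kg"),
      P = age_year_table(P, yrs, ages, "maturity", "proportion")
    )
  }
  had <- mk(scenario$growth$had, scenario$haddock$ages, scenario$years_had)
  cod <- mk(scenario$growth$cod, scenario$cod$ages, scenario$years_cod)
  list(W_had = had$W, P_had = had$P, W_cod = cod$W, P_cod = cod$P)
}

#' Generate a complete synthetic two-species dataset
#'
#' Composes the pipeline: environment, biology tables, cod simulation,
#' the cod biomass covariate `G_y` restricted to the haddock years, and
#' the haddock simulation, returning the observation tables together
#' with the full latent truth for parameter-recovery experiments.
#'
#' @param scenario an [lc_scenario()].
#' @param seed seed for the whole generation (default: the scenario's).
#' @return list of class `lc_dataset` with `haddock` and `cod`
#'   `observed_dataset`s and a `truth` record (parameters, latent
#'   states, simulator outputs, seed).
#' @export
generate_dataset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "lc_scenario"))
  set.seed(seed)
  env <- generate_environment(scenario, seed = NULL)
  bio <- generate_biology(scenario, seed = NULL)

  cod_bio <- cod_biology(bio$W_cod, bio$P_cod, env$summer)
  cod_sim <- simulate_cod(scenario$cod, cod_bio, scenario$init_cod, seed = NULL)

  yrs_h <- as.character(scenario$years_had)
  had_bio <- haddock_biology(
    bio$W_had, bio$P_had,
    T_y = env$winter[yrs_h], G_y = cod_sim$G[yrs_h]
  )
  had_sim <- simulate_haddock(scenario$haddock, had_bio, scenario$init_had, seed = NULL)

  mk_obs <- function(sim, species, W, P, T, G = NULL, n_init) {
    I <- age_year_table(
      t(sim$I), as.integer(colnames(sim$I)), as.integer(rownames(sim$I)),
      "survey_index", "index"
    )
    L <- age_year_table(
      t(sim$L), as.integer(colnames(sim$L)), as.integer(rownames(sim$L)),
      "landings", "individuals"
    )
    if (scenario$dropout > 0) {
      I[stats::runif(length(I)) < scenario$dropout] <- NA_real_
      L[stats::runif(length(L)) < scenario$dropout] <- NA_real_
    }
    structure(
      list(
        species = species, I = I, L = L, W = W, P = P, T = T, G = G,
        n_init = n_init
      ),
      class = "observed_dataset"
    )
  }
  structure(
    list(
      haddock = mk_obs(
        had_sim, "haddock", bio$W_had, bio$P_had,
        T = env$winter[yrs_h], G = cod_sim$G[yrs_h],
        n_init = scenario$init_had
      ),
      cod = mk_obs(
        cod_sim, "cod", bio$W_cod, bio$P_cod,
        T = env$summer, n_init = scenario$init_cod
      ),
      truth = list(
        scenario = scenario, seed = seed, env = env,
        haddock = had_sim, cod = cod_sim
      )
    ),
    class = "lc_dataset"
  )
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat(sprintf(
    "observed_dataset (%s): %d years, survey ages %s-%s, landings ages %s-%s\n",
    x$species, nrow(x$I),
    colnames(x$I)[1], colnames(x$I)[ncol(x$I)],
    colnames(x$L)[1], colnames(x$L)[ncol(x$L)]
  ))
  invisible(x)
}

#' Write / read a dataset bundle as plain-text files
#'
#' One CSV per table (`<species>_<quantity>.csv` in the age-by-year
#' dialect), `year,value` CSVs for the temperature and covariate series,
#' and a YAML run-metadata record (profile, seed, initial abundances).
#'
#' @param ds an `lc_dataset` from [generate_dataset()].
#' @param dir directory to create/fill.
#' @return `dir` (write) or an `lc_dataset`-shaped list without the
#'   truth record (read), invisibly for write.
#' @export
write_dataset_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "lc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in c("haddock", "cod")) {
    o <- ds[[sp]]
    for (nm in c("I", "L", "W", "P")) {
      write_age_year_table(o[[nm]], file.path(dir, paste0(sp, "_", nm, ".csv")))
    }
    write_year_series(o$T, file.path(dir, paste0(sp, "_T.csv")), "temperature")
    if (!is.null(o$G)) {
      write_year_series(o$G, file.path(dir, paste0(sp, "_G.csv")), "biomass_t")
    }
  }
  meta <- list(
    profile = ds$truth$scenario$profile,
    seed = ds$truth$seed,
    dropout = ds$truth$scenario$dropout,
    n_init_haddock = as.numeric(ds$haddock$n_init),
    n_init_cod = as.numeric(ds$cod$n_init)
  )
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' @rdname write_dataset_bundle
#' @export
read_dataset_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.yaml")
  if (!file.exists(meta_path)) stop("no dataset bundle at ", dir)
  meta <- yaml::read_yaml(meta_path)
  rd <- function(sp, G = FALSE) {
    out <- list(
      species = sp,
      I = read_age_year_table(file.path(dir, paste0(sp, "_I.csv")), "survey_index"),
      L = read_age_year_table(file.path(dir, paste0(sp, "_L.csv")), "landings"),
      W = read_age_year_table(file.path(dir, paste0(sp, "_W.csv")), "weight", "kg"),
      P = read_age_year_table(file.path(dir, paste0(sp, "_P.csv")), "maturity"),
      T = read_year_series(file.path(dir, paste0(sp, "_T.csv"))),
      n_init = meta[[paste0("n_init_", sp)]]
    )
    if (G) out$G <- read_year_series(file.path(dir, paste0(sp, "_G.csv")))
    structure(out, class = "observed_dataset")
  }
  list(
    haddock = rd("haddock", G = TRUE), cod = rd("cod"),
    meta = meta
  )
}

#' Validate a dataset bundle
#'
#' Checks table invariants (positive weights, maturities in [0, 1],
#' matching year ranges, no negative observations) and returns a
#' character vector of problems (empty when valid).
#'
#' @param bundle result of [read_dataset_bundle()] or an `lc_dataset`.
#' @return character vector of problems; `character(0)` if valid.
#' @export
validate_dataset <- function(bundle) {
  probs <- character(0)
  for (sp in c("haddock", "cod")) {
    o <- bundle[[sp]]
    if (is.null(o)) {
      probs <- c(probs, paste(sp, "missing"))
      next
    }
    if (any(o$W <= 0, na.rm = TRUE)) probs <- c(probs, paste(sp, "weights not positive"))
    if (any(o$P < 0 | o$P > 1, na.rm = TRUE)) probs <- c(probs, paste(sp, "maturity outside [0,1]"))
    if (any(o$I < 0, na.rm = TRUE)) probs <- c(probs, paste(sp, "negative survey index"))
    if (any(o$L < 0, na.rm = TRUE)) probs <- c(probs, paste(sp, "negative landings"))
    if (!identical(rownames(o$W), rownames(o$P))) probs <- c(probs, paste(sp, "W/P year mismatch"))
    if (!all(rownames(o$I) %in% names(o$T))) probs <- c(probs, paste(sp, "temperature does not cover survey years"))
  }
  probs
}
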