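#' Cod spawning stock biomass
#'
#' Identical formula to the haddock [compute_ssb()]: the two species
#' share the `sum_a N_a P_a W_a` kernel.
#'
#' @inheritParams compute_ssb
#' @return spawning biomass in kg.
#' @export
cod_ssb <- function(N, P, W) compute_ssb(N, P, W)

#' Cod early life stages: eggs, larvae, 0-group
#'
#' `N_e = SSB * tau * exp(sigma_sp * noise)`;
#' `N_l = N_e * exp(-t_e * M_e)`;
#' `N_z = N_l * exp(-t_l * M_l + psi_l * T_l)`.
#' The larval temperature term enters outside the duration product, so a
#' positive `psi_l` raises 0-group survival in warm summers.
#'
#' @param SSB spawning biomass in kg (`tau` is eggs per kg).
#' @param params a [cod_params()].
#' @param T_l larval-season (June-August) temperature (degrees C).
#' @param noise standard-normal draw for the spawning process, or 0.
#' @return named vector `c(N_e, N_l, N_z)`.
#' @export
early_life <- function(SSB, params, T_l, noise = 0) {
  if (SSB < 0) stop("SSB must be >= 0")
  if (params$t_e < 0 || params$t_l < 0) stop("stage durations must be >= 0")
  SSB <- unname(SSB)
  T_l <- unname(T_l)
  noise <- unname(noise)
  N_e <- SSB * params$tau * exp(params$sigma_sp * noise)
  N_l <- N_e * exp(-params$t_e * params$M_e)
  N_z <- N_l * exp(-params$t_l * params$M_l + params$psi_l * T_l)
  c(N_e = N_e, N_l = N_l, N_z = N_z)
}

#' Juvenile transition with inter-cohort (cannibalism) density dependence
#'
#' `N_next = N_prev / (1 + beta * N_prev) * exp(-M_j)`.  The realized
#' survival `exp(-M_j) / (1 + beta * N)` is strictly decreasing in
#' `N_prev` when `beta > 0` (compensatory), and `N_next` saturates at
#' `exp(-M_j) / beta` as `N_prev` grows.
#'
#' @param N_prev abundance of the preceding age class, previous year.
#' @param beta inter-cohort interaction strength (per individual, >= 0).
#' @param M_j juvenile annual mortality (per year).
#' @return abundance entering the next age class.
#' @export
juvenile_transition <- function(N_prev, beta, M_j) {
  if (any(N_prev < 0) || any(beta < 0) || any(M_j < 0)) {
    stop("N_prev, beta and M_j must be >= 0")
  }
  N_prev / (1 + beta * N_prev) * exp(-M_j)
}

#' Adult transition under fishing and natural mortality
#'
#' `N_next = N_prev * exp(-(F_prev + M4plus))`; the same exponential
#' survival kernel as the haddock [advance_age()] with `Z = F + M`.
#'
#' @param N_prev abundance of the preceding age class, previous year.
#' @param F_prev fishing mortality on that class that year (per year).
#' @param M4plus adult natural mortality (per year).
#' @return abundance entering the next age class.
#' @export
adult_transition <- function(N_prev, F_prev, M4plus) {
  if (any(F_prev < 0) || any(M4plus < 0)) stop("F_prev and M4plus must be >= 0")
  advance_age(N_prev, F_prev + M4plus)
}

#' Cod fishing mortality from an effort random walk
#'
#' `f_y = f_{y-1} + increment`; `F_ay = exp(f_a + f_y)` for ages from
#' `fish_min_age` upward, 0 below (the cod selectivity `f_a` is on the
#' log scale).
#'
#' @param f_a log selectivity named by age (>= fish_min_age).
#' @param f0 initial log effort.
#' @param sigma_f increment SD (>= 0).
#' @param increments standard-normal draws (length `Y - 1`), or zeros.
#' @param ages ages of the returned matrix rows (default: ages named in
#'   `f_a`).
#' @return list with `F` (ages x years matrix) and `f` (log effort by year).
#' @export
cod_fishing_mortality <- function(f_a, f0, sigma_f, increments,
                                  ages = as.integer(names(f_a))) {
  if (sigma_f < 0) stop("sigma_f must be >= 0")
  f <- f0 + c(0, cumsum(sigma_f * increments))
  F <- matrix(0, length(ages), length(f), dimnames = list(age = ages, year = seq_along(f)))
  fished <- as.character(ages) %in% names(f_a)
  F[fished, ] <- exp(outer(f_a[as.character(ages[fished])], f, "+"))
  list(F = F, f = f)
}

#' Cod catch (Baranov equation)
#'
#' Same contract as the haddock [baranov_catch()], with the fixed adult
#' natural mortality `M4plus`.
#'
#' @inheritParams baranov_catch
#' @param M4plus adult natural mortality (per year).
#' @return catch in individuals.
#' @export
cod_catch <- function(N, F, M4plus) baranov_catch(N, F, M4plus)

#' Predator biomass covariate
#'
#' Total cod biomass over ages 3-12 (the covariate consumed by the
#' haddock model), in metric tons: `G_y = sum_a N_ay * W_ay / 1000`.
#' Optionally maturity-weighted (mature biomass) via `P`.
#'
#' @param N abundance-at-age for one year (named by age).
#' @param W weight-at-age in kg (named by age).
#' @param ages ages to sum over (default 3:12).
#' @param P optional maturity-at-age for mature-biomass weighting.
#' @return biomass in metric tons.
#' @export
mature_biomass <- function(N, W, ages = 3:12, P = NULL) {
  idx <- as.character(ages)
  if (!all(idx %in% names(N)) || !all(idx %in% names(W))) {
    stop("ages ", paste(setdiff(idx, names(N)), collapse = ", "), " missing from N/W")
  }
  w <- if (is.null(P)) 1 else P[idx]
  sum(N[idx] * W[idx] * w) / 1000
}

#' Forward-simulate the cod life cycle
#'
#' Stage order per year: spawning biomass, eggs, larvae, 0-group, then
#' (into the next year) juvenile transitions with the inter-cohort term
#' and adult transitions under fishing; catches and the lognormal
#' observation model are applied to the finished matrices.  Noise order:
#' spawning series, effort increments, landings, indices, year effects.
#'
#' @param params a [cod_params()].
#' @param biology a [cod_biology()].
#' @param n_init abundance at ages `1:max(ages)` in the first year.
#' @param years calendar years to simulate (defaults to the biology years).
#' @param seed integer seed, or `NULL`.
#' @param f0 initial log fishing effort.
#' @param process_noise,obs_noise logical switches as in
#'   [simulate_haddock()].
#' @param F_override optional fixed fishing-mortality matrix (ages x
#'   years) replacing the effort random walk — used by the hindcast
#'   engine to impose harvest scenarios.
#' @return list of class `cod_sim` with `N` (ages x years), `N_e`, `N_l`,
#'   `N_z`, `SSB`, `f`, `F`, `C`, `G` (biomass covariate, metric tons),
#'   observations `L`, `I`, and the consumed `noise`.
#' @export
simulate_cod <- function(params, biology, n_init,
                         years = as.integer(names(biology$T_l)),
                         seed = NULL, f0 = 0,
                         process_noise = TRUE, obs_noise = TRUE,
                         F_override = NULL) {
  stopifnot(inherits(params, "cod_params"), inherits(biology, "cod_biology"))
  if (!is.null(seed)) set.seed(seed)
  ages <- params$ages
  A <- length(ages)
  Y <- length(years)
  yrs <- as.character(years)
  if (!all(yrs %in% rownames(biology$W))) stop("biology does not cover the requested years")
  if (length(n_init) != A) stop("n_init must give ages 1:", max(ages))
  if (any(n_init < 0)) stop("initial abundances must be >= 0")

  W <- t(biology$W[yrs, as.character(ages), drop = FALSE])
  P <- t(biology$P[yrs, as.character(ages), drop = FALSE])
  T_l <- biology$T_l[yrs]

  noise <- list(
    sp = if (process_noise) stats::rnorm(Y) else rep(0, Y),
    eff = if (process_noise) stats::rnorm(Y - 1L) else rep(0, Y - 1L)
  )

  if (is.null(F_override)) {
    fm <- cod_fishing_mortality(params$f_a, f0, params$sigma_f, noise$eff, ages)
    F <- fm$F
    f <- fm$f
  } else {
    stopifnot(identical(dim(F_override), c(A, Y)))
    F <- F_override
    f <- rep(NA_real_, Y)
  }

  dn <- list(age = as.character(ages), year = yrs)
  N <- matrix(NA_real_, A, Y, dimnames = dn)
  SSB <- N_e <- N_l <- N_z <- stats::setNames(numeric(Y), yrs)
  N[, 1L] <- n_init
  juv <- names(params$beta_a) # destination ages of the juvenile transition

  for (y in seq_len(Y)) {
    SSB[y] <- cod_ssb(N[, y], P[, y], W[, y])
    el <- early_life(SSB[y], params, T_l[y], noise$sp[y])
    N_e[y] <- el[["N_e"]]
    N_l[y] <- el[["N_l"]]
    N_z[y] <- el[["N_z"]]
    if (y < Y) {
      prev <- c("0" = unname(N_z[y]), stats::setNames(N[, y], ages))
      for (i in seq_len(A)) {
        a <- ages[i]
        src <- as.character(a - 1L)
        if (as.character(a) %in% juv) {
          N[i, y + 1L] <- juvenile_transition(
            prev[[src]], params$beta_a[[as.character(a)]], params$M_j
          )
        } else {
          N[i, y + 1L] <- adult_transition(
            prev[[src]], F[i - 1L, y], params$M4plus
          )
        }
      }
      if (params$plus_group) {
        N[A, y + 1L] <- N[A, y + 1L] +
          adult_transition(prev[[as.character(max(ages))]], F[A, y], params$M4plus)
      }
    }
  }

  fished <- ages >= params$fish_min_age
  C <- matrix(0, A, Y, dimnames = dn)
  C[fished, ] <- cod_catch(N[fished, , drop = FALSE], F[fished, , drop = FALSE], params$M4plus)
  G <- vapply(seq_len(Y), function(y) {
    mature_biomass(
      stats::setNames(N[, y], ages), stats::setNames(W[, y], ages),
      ages = params$biomass_ages,
      P = if (params$mature_weighting) stats::setNames(P[, y], ages) else NULL
    )
  }, numeric(1))
  names(G) <- yrs

  landed <- names(params$sigma_L_a)
  surveyed <- names(params$q_a)
  obs_noise_l <- if (obs_noise) {
    list(
      L = matrix(stats::rnorm(length(landed) * Y), length(landed), Y),
      I = matrix(stats::rnorm(length(surveyed) * Y), length(surveyed), Y),
      xi = stats::rnorm(Y)
    )
  } else {
    NULL
  }
  obs <- apply_observation_model(C, N, params, obs_noise_l)
  noise$obs <- obs_noise_l

  structure(
    list(
      N = N, N_e = N_e, N_l = N_l, N_z = N_z, SSB = SSB,
      f = stats::setNames(f, yrs), F = F, C = C, G = G,
      L = obs$L, I = obs$I, years = years, noise = noise,
      params = params, biology = biology
    ),
    class = "cod_sim"
  )
}
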