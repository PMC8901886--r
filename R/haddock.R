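#' Spawning stock biomass for one year
#'
#' `SSB = sum_a N_a * P_a * W_a`, the total weight of mature fish.
#'
#' @param N abundance-at-age (individuals).
#' @param P maturity proportion-at-age, in [0, 1].
#' @param W weight-at-age (kg).
#' @return spawning biomass in kg (non-negative scalar).
#' @examples
#' compute_ssb(c(100, 50, 10) * 1e3, c(0, 0.5, 1), c(0.5, 1, 2)) # 45000
#' @export
compute_ssb <- function(N, P, W) {
  if (length(N) != length(P) || length(N) != length(W)) {
    stop("N, P, W must cover the same age range")
  }
  sum(N * P * W)
}

#' Temperature-dependent fecundity series
#'
#' `phi_y = phi * delta_T * exp(T_phi * (T_y - Tbar))` with `Tbar` the
#' mean of the temperature series and
#' `delta_T = Y / sum_y exp(T_phi * (T_y - Tbar))` the correction that
#' makes the mean over years of `phi_y` equal `phi` exactly.
#'
#' @param phi mean fecundity (eggs per gram of spawning biomass).
#' @param T_phi temperature coefficient (per degree C).
#' @param T temperature by year (degrees C), length >= 1.
#' @return numeric vector `phi_y`, same length and names as `T`.
#' @export
fecundity_series <- function(phi, T_phi, T) {
  if (!length(T)) stop("empty temperature series")
  ex <- exp(T_phi * (T - mean(T)))
  delta_T <- length(T) / sum(ex)
  phi * delta_T * ex
}

#' Stochastic Beverton-Holt-type recruitment
#'
#' `ln N0 = ln(SSB * phi_y) - m_e - sigma_phi^2/2 + sigma_phi * noise`.
#' The `-sigma_phi^2/2` term is the lognormal mean correction, so that
#' `E[N0] = SSB * phi_y * exp(-m_e)` when the noise is averaged out.
#'
#' @param SSB spawning biomass in grams (the fecundity unit is eggs per
#'   gram).
#' @param phi_y fecundity for the year (eggs per gram).
#' @param m_e instantaneous egg-to-0-group mortality.
#' @param sigma_phi process SD on the log scale.
#' @param noise standard-normal draw, or 0 for the deterministic skeleton.
#' @return age-0 abundance (individuals).
#' @export
recruit <- function(SSB, phi_y, m_e, sigma_phi, noise = 0) {
  if (SSB < 0 || phi_y < 0 || m_e < 0 || sigma_phi < 0) {
    stop("SSB, phi_y, m_e and sigma_phi must be >= 0")
  }
  if (SSB == 0) {
    return(0)
  }
  exp(log(SSB * phi_y) - m_e - sigma_phi^2 / 2 + sigma_phi * noise)
}

#' Juvenile natural mortality with predation and density dependence
#'
#' For an age `a < 4`:
#' `M_ay = m_a * delta_a * exp(g_a * G_y) * (1 + D_a * N_ay)` with
#' `delta_a = Y / sum_y exp(g_a * G_y)`.  With `D_a = 0` the mean over
#' years of `M_ay` equals `m_a` exactly, by construction of `delta_a`.
#'
#' @param a age (must be < 4; older ages take the fixed `M4plus`).
#' @param m_a baseline mortality for this age (per year).
#' @param g_a predation coefficient (per metric ton of predator biomass).
#' @param D_a density-dependence coefficient (per individual).
#' @param G predator biomass by year (metric tons).
#' @param N_a abundance of this age by year (same length as `G`).
#' @return mortality `M_ay` by year.
#' @export
natural_mortality <- function(a, m_a, g_a, D_a, G, N_a) {
  if (a >= 4) stop("natural_mortality() is for ages < 4; use M4plus for ages 4+")
  if (length(G) != length(N_a)) stop("G and N_a must cover the same years")
  ex <- exp(g_a * G)
  delta_a <- length(G) / sum(ex)
  m_a * delta_a * ex * (1 + D_a * N_a)
}

#' Fishing mortality from an effort random walk
#'
#' Log effort follows `e_{y+1} = e_y + sigma_F * increment_y`;
#' `F_ay = f_a * exp(e_y)` for selected ages, 0 below them.
#'
#' @param f_a selectivity (natural scale) named by age; ages absent from
#'   `f_a` get `F = 0`.
#' @param e0 initial log effort.
#' @param sigma_F increment SD (>= 0).
#' @param increments standard-normal draws (length `Y - 1`), or zeros.
#' @param ages ages of the returned matrix rows (default: the ages named
#'   in `f_a`).
#' @return list with `F` (ages x years matrix) and `e` (log effort by year).
#' @export
fishing_mortality_series <- function(f_a, e0, sigma_F, increments,
                                     ages = as.integer(names(f_a))) {
  if (sigma_F < 0) stop("sigma_F must be >= 0")
  e <- e0 + c(0, cumsum(sigma_F * increments))
  sel <- stats::setNames(rep(0, length(ages)), ages)
  sel[names(f_a)] <- f_a
  F <- outer(sel, exp(e))
  dimnames(F) <- list(age = ages, year = seq_along(e))
  list(F = F, e = e)
}

#' Survival to the next age and year
#'
#' `N_{a+1,y+1} = N_ay * exp(-Z_ay)` with total mortality `Z = M + F`.
#'
#' @param N abundance (individuals).
#' @param Z total mortality (per year, >= 0).
#' @return surviving abundance, strictly <= `N`.
#' @export
advance_age <- function(N, Z) {
  if (any(Z < 0)) stop("Z must be >= 0")
  N * exp(-Z)
}

#' Baranov catch equation
#'
#' `C = F / (F + M) * N * (1 - exp(-(F + M)))`: the fishery's share of a
#' cohort's deaths under continuous competing risks.  The `F = M = 0`
#' limit returns 0.
#'
#' @param N abundance (individuals).
#' @param F fishing mortality (per year).
#' @param M natural mortality (per year).  For fished haddock ages the
#'   model uses the fixed adult `M4plus` here (as the catch equation is
#'   written), unless configured age-specific.
#' @return catch in individuals, `0 <= C <= N`, nondecreasing in `F`.
#' @export
baranov_catch <- function(N, F, M) {
  if (any(N < 0) || any(F < 0) || any(M < 0)) stop("N, F, M must be >= 0")
  Z <- F + M
  frac <- ifelse(Z > 0, F / Z, 0)
  frac * N * (1 - exp(-Z))
}

#' Lognormal observation model: landings and survey indices
#'
#' Landings: `L_ay = C_ay * exp(eps_L - sigma_L_a^2/2)` with
#' `eps_L ~ N(0, sigma_L_a^2)`, so `E[L] = C`.  Indices:
#' `I_ay = q_a * N_ay * exp(eps_I + xi_y)` with `eps_I ~ N(0, sigma_I_a^2)`
#' and the year effect `xi_y ~ N(0, sigma_xi^2)` shared across ages within
#' a year (correlated observation errors).
#'
#' @param C latent catch matrix (ages x years; rownames are ages).
#' @param N latent abundance matrix (ages x years; rownames are ages).
#' @param params a [haddock_params()] or [cod_params()] (the two species
#'   share this observation model).
#' @param noise list with standard-normal draws `L` (dim of the landed
#'   block), `I` (dim of the surveyed block) and `xi` (one per year), or
#'   `NULL` for noise-free output.
#' @return list with matrices `L` (landed ages x years) and `I`
#'   (surveyed ages x years).
#' @export
apply_observation_model <- function(C, N, params, noise = NULL) {
  landed <- names(params$sigma_L_a)
  surveyed <- names(params$q_a)
  CL <- C[landed, , drop = FALSE]
  NI <- N[surveyed, , drop = FALSE]
  ny <- ncol(NI)
  if (is.null(noise)) {
    noise <- list(
      L = array(0, dim(CL)), I = array(0, dim(NI)), xi = rep(0, ny)
    )
  }
  sL <- params$sigma_L_a
  sI <- params$sigma_I_a[surveyed]
  L <- CL * exp(sL * noise$L - 0.5 * sL^2)
  xi <- params$sigma_xi * noise$xi
  I <- NI * params$q_a[surveyed] *
    exp(sI * noise$I + matrix(xi, nrow(NI), ny, byrow = TRUE))
  dimnames(L) <- dimnames(CL)
  dimnames(I) <- dimnames(NI)
  list(L = L, I = I)
}

#' Forward-simulate the haddock life cycle
#'
#' Runs, for each year in order: spawning biomass (ages 1+), recruitment
#' of age 0 from the same year's SSB, natural and fishing mortality,
#' Baranov catch, then survival into the next year.  The observation
#' model is applied to the finished latent matrices.  Noise draws are
#' consumed in a fixed order (recruitment series, effort increments,
#' landings block, index block, year effects) so a seed fully determines
#' the run.
#'
#' @param params a [haddock_params()].
#' @param biology a [haddock_biology()] covering the simulated years.
#' @param n_init abundance at ages `1:max(ages)` in the first year.
#' @param years calendar years to simulate (defaults to the biology years).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param e0 initial log fishing effort.
#' @param process_noise,obs_noise logical switches; with both `FALSE` the
#'   run is the deterministic skeleton and repeated runs are identical.
#' @param delta_a optional fixed predation-correction factors (named by
#'   age).  By default the corrections are computed from the supplied
#'   `G_y` series so the mean predation factor is one over the simulated
#'   years (the model definition over the estimation period); a hindcast
#'   under counterfactual predator biomass must instead freeze them at
#'   their baseline values, otherwise the scenario contrast is
#'   re-normalized away.
#' @return list of class `haddock_sim` with elements `N`, `M`, `F`, `Z`,
#'   `C` (ages x years matrices), `SSB`, `e`, `phi_y` (by year), the
#'   observations `L`, `I`, and the consumed `noise`.
#' @export
simulate_haddock <- function(params, biology, n_init,
                             years = as.integer(names(biology$T_y)),
                             seed = NULL, e0 = 0,
                             process_noise = TRUE, obs_noise = TRUE,
                             delta_a = NULL) {
  stopifnot(inherits(params, "haddock_params"), inherits(biology, "haddock_biology"))
  if (!is.null(seed)) set.seed(seed)
  ages <- params$ages
  A <- length(ages)
  Y <- length(years)
  yrs <- as.character(years)
  if (!all(yrs %in% rownames(biology$W))) stop("biology does not cover the requested years")
  if (length(n_init) != A - 1L) stop("n_init must give ages 1:", max(ages), " for the first year")
  if (any(n_init < 0)) stop("initial abundances must be >= 0")

  W <- t(biology$W[yrs, as.character(ages), drop = FALSE])
  P <- t(biology$P[yrs, as.character(ages), drop = FALSE])
  T_y <- biology$T_y[yrs]
  G_y <- biology$G_y[yrs]

  noise <- list(
    rec = if (process_noise) stats::rnorm(Y) else rep(0, Y),
    eff = if (process_noise) stats::rnorm(Y - 1L) else rep(0, Y - 1L)
  )

  phi_y <- fecundity_series(params$phi, params$T_phi, T_y)
  fm <- fishing_mortality_series(params$f_a, e0, params$sigma_F, noise$eff, ages)
  F <- fm$F
  if (params$sigma_w > 0) {
    noise$w <- if (process_noise) stats::rnorm(A * Y) else rep(0, A * Y)
    F <- F * exp(params$sigma_w * matrix(noise$w, A, Y) - params$sigma_w^2 / 2)
  }

  dn <- list(age = as.character(ages), year = yrs)
  N <- matrix(NA_real_, A, Y, dimnames = dn)
  M <- matrix(params$M4plus, A, Y, dimnames = dn)
  C <- matrix(0, A, Y, dimnames = dn)
  SSB <- stats::setNames(numeric(Y), yrs)
  young <- as.integer(names(params$m_a))
  if (is.null(delta_a)) {
    # unbiasedness corrections over the simulated years, one per predated age
    delta_a <- vapply(
      names(params$g_a),
      function(a) Y / sum(exp(params$g_a[[a]] * G_y)), numeric(1)
    )
  } else {
    if (!all(names(params$g_a) %in% names(delta_a))) {
      stop("delta_a must cover every age with a predation coefficient")
    }
    delta_a <- delta_a[names(params$g_a)]
  }

  N[-1L, 1L] <- n_init
  for (y in seq_len(Y)) {
    SSB[y] <- compute_ssb(N[-1L, y], P[-1L, y], W[-1L, y])
    N[1L, y] <- recruit(
      1000 * SSB[y], phi_y[y], params$m_e, params$sigma_phi,
      noise$rec[y]
    )
    for (a in union(young, as.integer(names(params$g_a)))) {
      i <- match(a, ages)
      aa <- as.character(a)
      base <- if (a %in% young) params$m_a[[aa]] else params$M4plus
      g <- if (aa %in% names(params$g_a)) params$g_a[[aa]] else 0
      d <- if (aa %in% names(delta_a)) delta_a[[aa]] else 1
      dd <- if (aa %in% names(params$D_a)) params$D_a[[aa]] else 0
      M[i, y] <- base * d * exp(g * G_y[y]) * (1 + dd * N[i, y])
    }
    if (y < Y) {
      surv <- advance_age(N[, y], M[, y] + F[, y])
      N[-1L, y + 1L] <- surv[-A]
      if (params$plus_group) N[A, y + 1L] <- N[A, y + 1L] + surv[A]
    }
  }
  fished <- ages >= params$fished_min_age
  Mcatch <- if (params$catch_M == "M4plus") {
    matrix(params$M4plus, sum(fished), Y)
  } else {
    M[fished, , drop = FALSE]
  }
  C[fished, ] <- baranov_catch(N[fished, , drop = FALSE], F[fished, , drop = FALSE], Mcatch)

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
      N = N, M = M, F = F, Z = M + F, C = C, SSB = SSB,
      e = stats::setNames(fm$e, yrs), phi_y = phi_y,
      L = obs$L, I = obs$I, years = years, noise = noise,
      params = params, biology = biology
    ),
    class = "haddock_sim"
  )
}
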