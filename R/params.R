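#' Haddock life-cycle parameters
#'
#' All process and observation parameters of the haddock model.  Ages are
#' 0-based; the model tracks ages `0:max(ages)` with age `max(ages)`
#' terminal by default (no plus-group accumulation).  Conventions:
#'
#' * recruitment: `ln N0 ~ N(ln(SSB_g * phi_y) - m_e - sigma_phi^2/2, sigma_phi^2)`
#'   with `SSB_g` the spawning biomass in grams and `phi` in eggs per gram;
#' * juvenile natural mortality (ages < 4):
#'   `M_ay = m_a * delta_a * exp(g_a * G_y) * (1 + D_a * N_ay)` with
#'   `delta_a = Y / sum_y exp(g_a * G_y)` so the predation factor averages
#'   to one over the years;
#' * fishing: `F_ay = f_a * exp(e_y)` for ages >= `fished_min_age`, where
#'   `e_y` is a Gaussian random walk with increment SD `sigma_F`;
#' * catches: Baranov equation, with the fixed adult mortality `M4plus`
#'   in the denominator by default (`catch_M = "M4plus"`).
#'
#' @param ages integer vector of tracked ages, starting at 0.
#' @param phi mean fecundity, eggs per gram of spawning biomass.
#' @param T_phi temperature coefficient on fecundity (per degree C).
#' @param m_e instantaneous egg-to-0-group mortality.
#' @param sigma_phi recruitment process SD (log scale).
#' @param m_a baseline natural mortality for ages < 4 (per year), named by age.
#' @param M4plus natural mortality for ages >= 4 (per year).
#' @param g_a predation coefficient for ages <= 4 (per metric ton of
#'   predator biomass), named by age; may be negative.
#' @param D_a density-dependence coefficient for ages < 4 (per individual),
#'   named by age.
#' @param f_a fishing selectivity (natural scale) for ages >=
#'   `fished_min_age`, named by age.
#' @param sigma_F SD of the log-effort random-walk increments.
#' @param q_a survey catchability by age (ages >= 1), named by age.
#' @param sigma_L_a landings observation SD (log scale); scalar or named by
#'   fished age.
#' @param sigma_I_a index observation SD (log scale); scalar or named by
#'   surveyed age.
#' @param sigma_xi SD of the correlated year effect shared across ages
#'   within a survey year.
#' @param fished_min_age youngest age vulnerable to the fishery (default 3).
#' @param catch_M `"M4plus"` (as the catch equation is printed) or
#'   `"age_specific"` to use `M_ay` for young fished ages instead.
#' @param plus_group if `TRUE`, survivors of the oldest age accumulate in
#'   it instead of leaving the model.
#' @param sigma_w optional extra lognormal noise SD on `F_ay` (default 0).
#' @return an object of class `haddock_params`.
#' @export
haddock_params <- function(ages, phi, T_phi, m_e, sigma_phi, m_a, M4plus,
                           g_a, D_a, f_a, sigma_F, q_a,
                           sigma_L_a, sigma_I_a, sigma_xi,
                           fished_min_age = 3L, catch_M = c("M4plus", "age_specific"),
                           plus_group = FALSE, sigma_w = 0) {
  ages <- as.integer(ages)
  stopifnot(ages[1] == 0L, !is.unsorted(ages, strictly = TRUE))
  catch_M <- match.arg(catch_M)
  young <- ages[ages < 4L & ages < max(ages)]
  pred_ages <- ages[ages <= 4L & ages < max(ages)]
  fished <- ages[ages >= fished_min_age]
  surveyed <- ages[ages >= 1L]
  m_a <- named_by_age(m_a, young, "m_a")
  g_a <- named_by_age(g_a, pred_ages, "g_a")
  D_a <- named_by_age(D_a, young, "D_a")
  f_a <- named_by_age(f_a, fished, "f_a")
  q_a <- named_by_age(q_a, surveyed, "q_a")
  sigma_L_a <- named_by_age(sigma_L_a, fished, "sigma_L_a")
  sigma_I_a <- named_by_age(sigma_I_a, surveyed, "sigma_I_a")
  chk_nonneg(c(
    phi = phi, m_e = m_e, sigma_phi = sigma_phi, M4plus = M4plus,
    sigma_F = sigma_F, sigma_xi = sigma_xi, sigma_w = sigma_w
  ))
  chk_nonneg(m_a)
  chk_nonneg(sigma_L_a)
  chk_nonneg(sigma_I_a)
  if (any(q_a <= 0)) stop("q_a must be > 0")
  if (any(f_a < 0)) stop("f_a must be >= 0")
  structure(
    list(
      ages = ages, phi = phi, T_phi = T_phi, m_e = m_e,
      sigma_phi = sigma_phi, m_a = m_a, M4plus = M4plus, g_a = g_a,
      D_a = D_a, f_a = f_a, sigma_F = sigma_F, q_a = q_a,
      sigma_L_a = sigma_L_a, sigma_I_a = sigma_I_a, sigma_xi = sigma_xi,
      fished_min_age = as.integer(fished_min_age), catch_M = catch_M,
      plus_group = plus_group, sigma_w = sigma_w
    ),
    class = "haddock_params"
  )
}

#' Cod life-cycle parameters
#'
#' The cod model tracks eggs, larvae, 0-group and ages `1:max(ages)`.
#' Early life: `N_e = SSB_kg * tau * exp(sigma_sp * eps)`,
#' `N_l = N_e * exp(-t_e * M_e)`, `N_z = N_l * exp(-t_l * M_l + psi_l * T_l)`.
#' Juvenile transitions (into ages `1:juv_max_age`) carry the inter-cohort
#' (cannibalism) term: `N_a = N_prev / (1 + beta_a * N_prev) * exp(-M_j)`.
#' Transitions from `fish_min_age` upward use `exp(-(F + M4plus))` with
#' `F_ay = exp(f_a + f_y)` and `f_y` a Gaussian random walk.
#'
#' @param ages integer vector of tracked ages, starting at 1.
#' @param tau mean fecundity, eggs per kg of spawning biomass.
#' @param sigma_sp spawning process SD (log scale).
#' @param M_e egg daily mortality (per day).
#' @param t_e egg-to-larva duration (days).
#' @param M_l larval daily mortality (per day).
#' @param t_l larva-to-0-group duration (days).
#' @param psi_l larval temperature coefficient (per degree C).
#' @param M_j juvenile annual mortality (per year).
#' @param beta_a inter-cohort interaction strength (per individual), named
#'   by destination age `1:juv_max_age`.
#' @param M4plus adult natural mortality (per year).
#' @param f_a log-scale fishing selectivity for ages >= `fish_min_age`,
#'   named by age.
#' @param sigma_f SD of the log-effort random-walk increments.
#' @param q_a,sigma_L_a,sigma_I_a,sigma_xi observation parameters, as for
#'   [haddock_params()] (surveyed ages are `ages`; landed ages are the
#'   fished ages).
#' @param fish_min_age youngest age vulnerable to the fishery (default 4).
#' @param juv_max_age oldest age reached through the juvenile transition
#'   (default 4).
#' @param biomass_ages ages summed in the predator-biomass covariate
#'   `G_y` (default `3:12`, clipped to the tracked ages).
#' @param mature_weighting if `TRUE`, weight the biomass covariate by
#'   maturity (mature biomass); default `FALSE` (total biomass ages 3-12).
#' @param plus_group as for [haddock_params()].
#' @return an object of class `cod_params`.
#' @export
cod_params <- function(ages, tau, sigma_sp, M_e, t_e, M_l, t_l, psi_l, M_j,
                       beta_a, M4plus, f_a, sigma_f, q_a,
                       sigma_L_a, sigma_I_a, sigma_xi,
                       fish_min_age = 4L, juv_max_age = 4L,
                       biomass_ages = 3:12, mature_weighting = FALSE,
                       plus_group = FALSE) {
  ages <- as.integer(ages)
  stopifnot(ages[1] == 1L, !is.unsorted(ages, strictly = TRUE))
  if (t_e < 0 || t_l < 0) stop("stage durations must be >= 0")
  juv_ages <- ages[ages <= juv_max_age]
  fished <- ages[ages >= fish_min_age]
  if (!length(fished)) stop("no tracked age reaches fish_min_age")
  beta_a <- named_by_age(beta_a, juv_ages, "beta_a")
  f_a <- named_by_age(f_a, fished, "f_a")
  q_a <- named_by_age(q_a, ages, "q_a")
  sigma_L_a <- named_by_age(sigma_L_a, fished, "sigma_L_a")
  sigma_I_a <- named_by_age(sigma_I_a, ages, "sigma_I_a")
  chk_nonneg(c(
    tau = tau, sigma_sp = sigma_sp, M_e = M_e, M_l = M_l, M_j = M_j,
    M4plus = M4plus, sigma_f = sigma_f, sigma_xi = sigma_xi
  ))
  chk_nonneg(beta_a)
  chk_nonneg(sigma_L_a)
  chk_nonneg(sigma_I_a)
  if (any(q_a <= 0)) stop("q_a must be > 0")
  biomass_ages <- intersect(as.integer(biomass_ages), ages)
  structure(
    list(
      ages = ages, tau = tau, sigma_sp = sigma_sp, M_e = M_e, t_e = t_e,
      M_l = M_l, t_l = t_l, psi_l = psi_l, M_j = M_j, beta_a = beta_a,
      M4plus = M4plus, f_a = f_a, sigma_f = sigma_f, q_a = q_a,
      sigma_L_a = sigma_L_a, sigma_I_a = sigma_I_a, sigma_xi = sigma_xi,
      fish_min_age = as.integer(fish_min_age),
      juv_max_age = as.integer(juv_max_age),
      biomass_ages = biomass_ages, mature_weighting = mature_weighting,
      plus_group = plus_group
    ),
    class = "cod_params"
  )
}

# recycle a scalar over ages or check the names of an age-indexed vector
named_by_age <- function(x, ages, what) {
  if (!length(ages)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(ages)), ages))
  }
  if (is.null(names(x))) {
    if (length(x) != length(ages)) {
      stop(what, ": expected length ", length(ages), " (ages ",
        paste(range(ages), collapse = "-"), "), got ", length(x))
    }
    return(stats::setNames(as.numeric(x), ages))
  }
  miss <- setdiff(as.character(ages), names(x))
  if (length(miss)) stop(what, ": missing ages ", paste(miss, collapse = ", "))
  stats::setNames(as.numeric(x[as.character(ages)]), ages)
}

chk_nonneg <- function(x) {
  bad <- which(x < 0 | is.na(x))
  if (length(bad)) {
    nm <- if (!is.null(names(x))) names(x)[bad[1]] else deparse(substitute(x))
    stop("parameter must be >= 0: ", nm)
  }
  invisible(TRUE)
}

#' Biology inputs for the haddock model
#'
#' @param W,P weight-at-age (kg) and maturity [age_year_table()]s on the
#'   same year/age grid.
#' @param T_y winter (December-February) temperature by year, named
#'   numeric vector (degrees C).
#' @param G_y predator (cod) biomass by year, named numeric vector
#'   (metric tons).
#' @return an object of class `haddock_biology`.
#' @export
haddock_biology <- function(W, P, T_y, G_y) {
  stopifnot(inherits(W, "age_year_table"), inherits(P, "age_year_table"))
  if (!identical(dim(W), dim(P)) || !identical(rownames(W), rownames(P))) {
    stop("W and P must share the same year/age grid")
  }
  if (any(P < 0 | P > 1, na.rm = TRUE)) stop("maturity P must lie in [0, 1]")
  if (any(W <= 0, na.rm = TRUE)) stop("weights W must be > 0")
  yrs <- rownames(W)
  for (s in list(T_y = T_y, G_y = G_y)) {
    if (!all(yrs %in% names(s))) stop("T_y and G_y must cover the years of W/P")
  }
  structure(list(W = W, P = P, T_y = T_y[yrs], G_y = G_y[yrs]),
    class = "haddock_biology"
  )
}

#' Biology inputs for the cod model
#'
#' @param W,P weight-at-age (kg) and maturity [age_year_table()]s.
#' @param T_l summer (June-August) larval-season temperature by year,
#'   named numeric vector (degrees C).
#' @return an object of class `cod_biology`.
#' @export
cod_biology <- function(W, P, T_l) {
  stopifnot(inherits(W, "age_year_table"), inherits(P, "age_year_table"))
  if (!identical(dim(W), dim(P)) || !identical(rownames(W), rownames(P))) {
    stop("W and P must share the same year/age grid")
  }
  if (any(P < 0 | P > 1, na.rm = TRUE)) stop("maturity P must lie in [0, 1]")
  if (any(W <= 0, na.rm = TRUE)) stop("weights W must be > 0")
  yrs <- rownames(W)
  if (!all(yrs %in% names(T_l))) stop("T_l must cover the years of W/P")
  structure(list(W = W, P = P, T_l = T_l[yrs]), class = "cod_biology")
}
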