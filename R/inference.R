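## Bayesian estimation of the life-cycle state-space models.
##
## The joint posterior is over (a configurable subset of) the species
## parameters plus the latent process innovations, in the non-centred
## parameterization: recruitment/spawning innovations and effort
## random-walk increments are sampled as standard normals and the latent
## abundance states are reconstructed deterministically from them.  The
## correlated survey year effect xi_y is marginalized analytically
## (compound-symmetry covariance across ages within a year).

# parameter id codes shared with src/haddock_logpost.cpp
.hd_ids <- c(
  phi = 1, T_phi = 2, m_e = 3, sigma_phi = 4, m_a = 5, M4plus = 6,
  g_a = 7, D_a = 8, f_a = 9, sigma_F = 10, q_a = 11, sigma_L_a = 12,
  sigma_I_a = 13, sigma_xi = 14, e0 = 15
)
.cod_ids <- c(
  tau = 1, sigma_sp = 2, M_e = 3, t_e = 4, M_l = 5, t_l = 6, psi_l = 7,
  M_j = 8, beta_a = 9, M4plus = 10, f_a = 11, sigma_f = 12, q_a = 13,
  sigma_L_a = 14, sigma_I_a = 15, sigma_xi = 16, f0 = 17
)
.age_vector_params <- c(
  "m_a", "g_a", "D_a", "f_a", "q_a", "sigma_L_a", "sigma_I_a", "beta_a"
)

#' Declare a prior for one estimable parameter
#'
#' Families: `"normal"` and `"uniform"` are placed on the sampling scale
#' (after the transform), `"halfnormal"` on the natural value with the
#' log-transform Jacobian included.  Positive parameters (catchabilities,
#' SDs) are sampled on the log scale via `transform = "log"`.
#'
#' @param param parameter name as in [haddock_params()] / [cod_params()]
#'   (e.g. `"T_phi"`, `"q_a"`, `"sigma_I_a"`, `"e0"`/`"f0"` for the
#'   initial log effort).
#' @param age for age-indexed parameters: a single age, or `NA` to tie
#'   one sampled value across all applicable ages.
#' @param family prior family.
#' @param p1,p2 hyperparameters: mean/sd (normal), bounds (uniform),
#'   scale (halfnormal, `p2` unused).
#' @param transform `"identity"` or `"log"`.
#' @param init optional initial value on the sampling scale.
#' @return one-row data frame; combine with [lc_priors()].
#' @export
lc_prior <- function(param, age = NA,
                     family = c("normal", "uniform", "halfnormal"),
                     p1, p2 = NA, transform = c("identity", "log"),
                     init = NA) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (family == "normal" && (is.na(p2) || p2 <= 0)) stop("normal prior needs sd p2 > 0")
  if (family == "uniform" && (is.na(p2) || p2 <= p1)) stop("uniform prior needs p1 < p2")
  if (family == "halfnormal" && p1 <= 0) stop("halfnormal prior needs scale p1 > 0")
  data.frame(
    param = param, age = as.integer(age), family = family,
    p1 = p1, p2 = p2, transform = transform, init = init,
    stringsAsFactors = FALSE
  )
}

#' Combine prior declarations into a prior configuration
#'
#' @param ... one-row data frames from [lc_prior()].
#' @return data frame of class `lc_priors`; one row per sampled
#'   parameter (duplicated param/age combinations are rejected).
#' @export
lc_priors <- function(...) {
  df <- do.call(rbind, list(...))
  key <- paste(df$param, df$age)
  if (anyDuplicated(key)) stop("duplicate prior for ", key[duplicated(key)][1])
  class(df) <- c("lc_priors", "data.frame")
  df
}

#' MCMC settings
#'
#' Desk-scale defaults (3 chains, 2000 warm-up sweeps, 2000 retained
#' sweeps); `profile = "full"` switches to the long protocol
#' (3 chains, 250,000 burn-in, 250,000 posterior iterations thinned by
#' 1000).
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param warmup adaptation/burn-in sweeps, discarded.
#' @param iter post-warmup sweeps.
#' @param thin keep every `thin`-th sweep.
#' @param seed integer seed; chain `c` uses `seed + 7919 * c`.
#' @param jitter SD of the overdispersion added to the initial values of
#'   each chain (sampling scale).
#' @param profile `"desk"` or `"full"`.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3L, warmup = 2000L, iter = 2000L,
                          thin = 1L, seed = 1L, jitter = 0.5,
                          profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    warmup <- 250000L
    iter <- 250000L
    thin <- 1000L
  }
  s <- list(
    chains = as.integer(chains), warmup = as.integer(warmup),
    iter = as.integer(iter), thin = as.integer(thin),
    seed = as.integer(seed), jitter = jitter, profile = profile
  )
  if (any(unlist(s[1:5]) < 1L)) stop("chains, warmup, iter, thin, seed must be positive integers")
  structure(s, class = "mcmc_settings")
}

# pad an age-named parameter vector to the full tracked-age length
.pad_ages <- function(x, ages) {
  out <- stats::setNames(rep(0, length(ages)), ages)
  out[names(x)] <- x
  out
}

#' Build the estimation model for one species
#'
#' Assembles data matrices, baseline parameter values, the estimation
#' map (which entries of the parameter set are sampled, with priors) and
#' the latent-innovation layout into an `lc_model` object whose joint
#' density [log_posterior()] evaluates.
#'
#' @param data list (or `observed_dataset`) with `I` and `L`
#'   ([age_year_table()]s of survey indices and landings), `W`, `P`
#'   (biology tables), `T` (temperature by year, named), `n_init`
#'   (first-year abundance at ages 1+), and for haddock `G` (predator
#'   biomass covariate by year).
#' @param params baseline [haddock_params()] or [cod_params()]; entries
#'   not listed in `priors` are held fixed at these values.
#' @param priors an [lc_priors()] configuration.
#' @param species `"haddock"` or `"cod"`.
#' @param estimate_latents sample the process innovations (default) or
#'   hold them at `u_rec0`/`u_eff0`.
#' @param u_rec0,u_eff0 fixed innovation values when not sampled.
#' @return list of class `lc_model` with the evaluation environment
#'   (`env`), sampled-quantity names, initial values and dimensions.
#' @export
build_model <- function(data, params, priors, species = c("haddock", "cod"),
                        estimate_latents = TRUE, u_rec0 = NULL, u_eff0 = NULL) {
  species <- match.arg(species)
  stopifnot(inherits(priors, "lc_priors"))
  ids <- if (species == "haddock") .hd_ids else .cod_ids
  ages <- params$ages
  A <- length(ages)
  yrs <- names(data$T)
  Y <- length(yrs)
  if (Y < 2L) stop("need at least two years of data")
  for (nm in c("I", "L", "W", "P")) {
    tab <- data[[nm]]
    if (!inherits(tab, "age_year_table")) stop("data$", nm, " must be an age_year_table")
    if (!all(yrs %in% rownames(tab))) stop("data$", nm, " does not cover the temperature years")
  }
  if (any(!is.finite(unlist(data$T)))) stop("non-finite temperature data")

  # observations padded onto the full age grid, ages x years, NA = missing
  to_grid <- function(tab) {
    out <- matrix(NA_real_, A, Y, dimnames = list(ages, yrs))
    keep <- intersect(colnames(tab), as.character(ages))
    out[keep, ] <- t(tab[yrs, keep, drop = FALSE])
    out
  }
  Iobs <- to_grid(data$I)
  Lobs <- to_grid(data$L)
  if (any(Iobs <= 0, na.rm = TRUE) || any(Lobs <= 0, na.rm = TRUE)) {
    stop("observed indices and landings must be positive (use NA for missing)")
  }
  surveyed <- as.character(ages) %in% names(params$q_a) &
    as.character(ages) %in% colnames(data$I)
  landed <- as.character(ages) %in% names(params$sigma_L_a) &
    as.character(ages) %in% colnames(data$L)
  Iobs[!surveyed, ] <- NA_real_
  Lobs[!landed, ] <- NA_real_

  first_age <- if (species == "haddock") 0L else 1L
  n_init <- data$n_init
  if (length(n_init) != A - (species == "haddock")) {
    stop("n_init must give first-year abundance at ages ", first_age + 1L, ":", max(ages))
  }

  # estimation map: one row per (theta, parameter slot) assignment
  scalar_ok <- setdiff(names(ids), .age_vector_params)
  map <- matrix(integer(0), 0, 3)
  prior_mat <- matrix(numeric(0), 0, 4)
  theta_names <- character(0)
  theta_init <- numeric(0)
  assigns <- list()
  fam_code <- c(normal = 0, uniform = 1, halfnormal = 2)
  domain <- function(p) {
    # ages over which an age-vector parameter is defined
    switch(p,
      m_a = names(params$m_a), g_a = names(params$g_a),
      D_a = names(params$D_a), f_a = names(params$f_a),
      q_a = names(params$q_a), sigma_L_a = names(params$sigma_L_a),
      sigma_I_a = names(params$sigma_I_a), beta_a = names(params$beta_a)
    )
  }
  for (k in seq_len(nrow(priors))) {
    p <- priors$param[k]
    if (!p %in% names(ids)) stop("unknown parameter '", p, "' for species ", species)
    tr <- match(priors$transform[k], c("identity", "log")) - 1L
    ti <- length(theta_names) # 0-based theta index
    if (p %in% .age_vector_params) {
      dom <- domain(p)
      tie <- is.na(priors$age[k])
      sel <- if (tie) dom else as.character(priors$age[k])
      if (!all(sel %in% dom)) {
        stop(p, ": age ", priors$age[k], " outside its domain (", paste(dom, collapse = ","), ")")
      }
      rows <- match(sel, as.character(ages)) - 1L
      map <- rbind(map, cbind(ti, ids[[p]], rows))
      label <- if (tie) sub("_a$", "", p) else paste0(sub("_a$", "", p), "[", sel, "]")
      assigns[[ti + 1L]] <- list(param = p, ages = sel)
    } else {
      if (!p %in% scalar_ok) stop(p, " is not a scalar parameter")
      if (!is.na(priors$age[k])) stop(p, " takes no age")
      map <- rbind(map, cbind(ti, ids[[p]], 0L))
      label <- p
      assigns[[ti + 1L]] <- list(param = p, ages = NULL)
    }
    init <- priors$init[k]
    if (is.na(init)) {
      init <- switch(priors$family[k],
        normal = priors$p1[k],
        uniform = (priors$p1[k] + priors$p2[k]) / 2,
        halfnormal = if (tr == 1L) log(priors$p1[k] / 2) else priors$p1[k] / 2
      )
    }
    prior_mat <- rbind(prior_mat, c(fam_code[[priors$family[k]]], priors$p1[k], priors$p2[k], tr))
    theta_names <- c(theta_names, label)
    theta_init <- c(theta_init, init)
  }
  storage.mode(map) <- "integer"

  est_u_rec <- estimate_latents
  est_u_eff <- estimate_latents && length(params[[if (species == "haddock") "f_a" else "f_a"]]) > 0
  if (is.null(u_rec0)) u_rec0 <- rep(0, Y)
  if (is.null(u_eff0)) u_eff0 <- rep(0, Y - 1L)
  u_names <- c(
    if (est_u_rec) paste0("u_rec[", yrs, "]"),
    if (est_u_eff) paste0("u_eff[", yrs[-1], "]")
  )

  env <- list(
    A = A, Y = Y, ages = as.integer(ages),
    W = t(data$W[yrs, as.character(ages), drop = FALSE]),
    P = t(data$P[yrs, as.character(ages), drop = FALSE]),
    T = as.numeric(data$T[yrs]),
    logI = log(Iobs), logL = log(Lobs),
    n_init = as.numeric(n_init),
    surveyed = surveyed, landed = landed,
    map = map, prior = prior_mat,
    est_u_rec = est_u_rec, est_u_eff = est_u_eff,
    u_rec0 = as.numeric(u_rec0), u_eff0 = as.numeric(u_eff0)
  )
  if (species == "haddock") {
    if (is.null(data$G)) stop("haddock model needs the predator biomass covariate data$G")
    if (params$sigma_w > 0) stop("estimation assumes sigma_w = 0 (deterministic F given effort)")
    env <- c(env, list(
      G = as.numeric(data$G[yrs]),
      fished_min_age = params$fished_min_age,
      catch_M_age_specific = params$catch_M == "age_specific",
      plus_group = params$plus_group,
      phi = params$phi, T_phi = params$T_phi, m_e = params$m_e,
      sigma_phi = params$sigma_phi, M4plus = params$M4plus,
      sigma_F = params$sigma_F, sigma_xi = params$sigma_xi, e0 = 0,
      m_a = unname(.pad_ages(params$m_a, ages)),
      g = unname(.pad_ages(params$g_a, ages)),
      D = unname(.pad_ages(params$D_a, ages)),
      f = unname(.pad_ages(params$f_a, ages)),
      q = unname(.pad_ages(params$q_a, ages)),
      sigma_L = unname(.pad_ages(params$sigma_L_a, ages)),
      sigma_I = unname(.pad_ages(params$sigma_I_a, ages)),
      has_m = as.character(ages) %in% names(params$m_a),
      has_g = as.character(ages) %in% names(params$g_a),
      has_D = as.character(ages) %in% names(params$D_a)
    ))
  } else {
    env <- c(env, list(
      T_l = as.numeric(data$T[yrs]),
      fish_min_age = params$fish_min_age,
      plus_group = params$plus_group,
      tau = params$tau, sigma_sp = params$sigma_sp, M_e = params$M_e,
      t_e = params$t_e, M_l = params$M_l, t_l = params$t_l,
      psi_l = params$psi_l, M_j = params$M_j, M4plus = params$M4plus,
      sigma_f = params$sigma_f, sigma_xi = params$sigma_xi, f0 = 0,
      beta = unname(.pad_ages(params$beta_a, ages)),
      f = unname(.pad_ages(params$f_a, ages)),
      q = unname(.pad_ages(params$q_a, ages)),
      sigma_L = unname(.pad_ages(params$sigma_L_a, ages)),
      sigma_I = unname(.pad_ages(params$sigma_I_a, ages)),
      is_juv = as.character(ages) %in% names(params$beta_a)
    ))
  }

  structure(
    list(
      species = species, env = env, params = params,
      theta_names = c(theta_names, u_names),
      theta_init = c(theta_init, rep(0, length(u_names))),
      n_par = length(theta_names), n_latent = length(u_names),
      transforms = prior_mat[, 4], assigns = assigns,
      years = as.integer(yrs)
    ),
    class = "lc_model"
  )
}

#' Joint log-posterior density
#'
#' Evaluates the sum of (a) the standard-normal densities of the latent
#' process innovations, (b) the lognormal landings likelihood with
#' mean-one correction, (c) the survey-index likelihood with the
#' correlated year effect marginalized, and (d) the configured priors,
#' at a point `theta` = (sampled parameters, innovations).  Returns
#' `-Inf` outside the support.
#'
#' @param theta numeric vector on the sampling scale, laid out as
#'   `model$theta_names`.
#' @param model an [build_model()] object.
#' @return scalar log density.
#' @export
log_posterior <- function(theta, model) {
  stopifnot(inherits(model, "lc_model"))
  if (model$species == "haddock") {
    haddock_logpost_cpp(theta, model$env)
  } else {
    cod_logpost_r(theta, model$env)
  }
}

# R implementation of the cod joint log-posterior (same layout contract
# as the compiled haddock density)
cod_logpost_r <- function(theta, m) {
  n_theta <- nrow(m$prior)
  need <- n_theta + if (m$est_u_rec) m$Y else 0
  need <- need + if (m$est_u_eff) m$Y - 1L else 0
  if (length(theta) != need) stop("theta has length ", length(theta), ", expected ", need)
  if (any(!is.finite(theta))) return(-Inf)

  v <- list(
    tau = m$tau, sigma_sp = m$sigma_sp, M_e = m$M_e, t_e = m$t_e,
    M_l = m$M_l, t_l = m$t_l, psi_l = m$psi_l, M_j = m$M_j,
    M4plus = m$M4plus, sigma_f = m$sigma_f, sigma_xi = m$sigma_xi,
    f0 = m$f0, beta = m$beta, f = m$f, q = m$q,
    sigma_L = m$sigma_L, sigma_I = m$sigma_I
  )
  slot <- c(
    "tau", "sigma_sp", "M_e", "t_e", "M_l", "t_l", "psi_l", "M_j",
    "beta", "M4plus", "f", "sigma_f", "q", "sigma_L", "sigma_I",
    "sigma_xi", "f0"
  )
  lp <- 0
  if (nrow(m$map)) {
    for (k in seq_len(nrow(m$map))) {
      ti <- m$map[k, 1] + 1L
      s <- slot[m$map[k, 2]]
      val <- if (m$prior[ti, 4] == 1) exp(theta[ti]) else theta[ti]
      if (s %in% c("beta", "f", "q", "sigma_L", "sigma_I")) {
        v[[s]][m$map[k, 3] + 1L] <- val
      } else {
        v[[s]] <- val
      }
    }
  }
  for (ti in seq_len(n_theta)) {
    th <- theta[ti]
    fam <- m$prior[ti, 1]
    p1 <- m$prior[ti, 2]
    p2 <- m$prior[ti, 3]
    if (fam == 0) {
      lp <- lp + stats::dnorm(th, p1, p2, log = TRUE)
    } else if (fam == 1) {
      if (th < p1 || th > p2) return(-Inf)
      lp <- lp - log(p2 - p1)
    } else {
      val <- if (m$prior[ti, 4] == 1) exp(th) else th
      if (val < 0) return(-Inf)
      lp <- lp + log(2) + stats::dnorm(val, 0, p1, log = TRUE)
      if (m$prior[ti, 4] == 1) lp <- lp + th
    }
  }

  Y <- m$Y
  A <- m$A
  off <- n_theta
  u_sp <- if (m$est_u_rec) theta[off + seq_len(Y)] else m$u_rec0
  if (m$est_u_rec) off <- off + Y
  u_eff <- if (m$est_u_eff) theta[off + seq_len(Y - 1L)] else m$u_eff0
  if (m$est_u_rec) lp <- lp + sum(stats::dnorm(u_sp, log = TRUE))
  if (m$est_u_eff) lp <- lp + sum(stats::dnorm(u_eff, log = TRUE))

  fy <- v$f0 + c(0, cumsum(v$sigma_f * u_eff))
  fished <- m$ages >= m$fish_min_age
  F <- matrix(0, A, Y)
  F[fished, ] <- exp(outer(v$f[fished], fy, "+"))

  N <- matrix(0, A, Y)
  N[, 1] <- m$n_init
  N_z <- numeric(Y)
  PW <- m$P * m$W
  juv <- which(m$is_juv)
  adu <- which(!m$is_juv)
  sjuv <- exp(-v$M_j)
  early <- exp(-v$t_e * v$M_e - v$t_l * v$M_l + v$psi_l * m$T_l) *
    v$tau * exp(v$sigma_sp * u_sp)
  for (y in seq_len(Y)) {
    N_z[y] <- sum(N[, y] * PW[, y]) * early[y]
    if (y < Y) {
      prev <- c(N_z[y], N[-A, y]) # source cohort for each destination age
      nxt <- numeric(A)
      nxt[juv] <- prev[juv] / (1 + v$beta[juv] * prev[juv]) * sjuv
      nxt[adu] <- prev[adu] * exp(-(F[adu - 1L, y] + v$M4plus))
      if (m$plus_group) {
        nxt[A] <- nxt[A] + N[A, y] * exp(-(F[A, y] + v$M4plus))
      }
      N[, y + 1] <- nxt
    }
  }

  Z <- F + v$M4plus
  C <- ifelse(Z > 0, F / Z, 0) * N * (1 - exp(-Z))
  # landings
  for (i in which(m$landed)) {
    obs <- m$logL[i, ]
    ok <- is.finite(obs)
    if (!any(ok)) next
    if (any(C[i, ok] <= 0) || v$sigma_L[i] <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(
      obs[ok], log(C[i, ok]) - 0.5 * v$sigma_L[i]^2, v$sigma_L[i],
      log = TRUE
    ))
  }
  # indices with marginalized year effect
  xi2 <- v$sigma_xi^2
  ok <- m$surveyed & is.finite(m$logI)
  if (any(N[ok] <= 0) || any(v$sigma_I[m$surveyed] <= 0)) {
    return(-Inf)
  }
  if (xi2 == 0) {
    lp <- lp + sum(stats::dnorm(
      m$logI[ok], log(v$q * N)[ok],
      matrix(v$sigma_I, A, Y)[ok],
      log = TRUE
    ))
  } else {
    for (y in seq_len(Y)) {
      i <- which(ok[, y])
      if (!length(i)) next
      r <- m$logI[i, y] - log(v$q[i] * N[i, y])
      s2 <- v$sigma_I[i]^2
      cc <- 1 + xi2 * sum(1 / s2)
      quad <- sum(r^2 / s2) - xi2 * sum(r / s2)^2 / cc
      lp <- lp - 0.5 * (length(i) * log(2 * pi) + sum(log(s2)) + log(cc) + quad)
    }
  }
  lp
}

#' Adaptive Metropolis-within-Gibbs sampler
#'
#' Componentwise Gaussian random-walk Metropolis with per-coordinate
#' proposal scales adapted during warm-up toward a 0.44 acceptance rate
#' (Robbins-Monro on the log scale), frozen afterwards.  Chains start
#' from `init` plus independent overdispersion.  For a haddock
#' [build_model()] object the sweep loop runs in compiled code; any
#' other target (including the cod model) uses the R loop — both paths
#' implement the identical algorithm.
#'
#' @param target an `lc_model` (its [log_posterior()] is the target and
#'   `model$theta_init` the centre of the start distribution), or a
#'   function of `theta` returning the log target density.
#' @param init initial value (sampling scale); required when `target`
#'   is a function.
#' @param settings an [mcmc_settings()].
#' @param scale0 initial proposal SD per coordinate.
#' @return list of class `posterior_draws`: `draws` array (iterations x
#'   chains x quantities), `lp` matrix, `accept` rates, `scales`,
#'   `settings`.
#' @export
lc_mcmc <- function(target, init = NULL, settings = mcmc_settings(), scale0 = 0.1) {
  stopifnot(inherits(settings, "mcmc_settings"))
  is_model <- inherits(target, "lc_model")
  if (is_model && is.null(init)) init <- target$theta_init
  if (is.null(init)) stop("init is required when target is a function")
  lpfun <- if (is_model) function(theta) log_posterior(theta, target) else target
  use_cpp <- is_model && target$species == "haddock"
  d <- length(init)
  n_keep <- settings$iter %/% settings$thin
  if (n_keep < 2L) stop("iter/thin must allow at least 2 retained sweeps")
  draws <- array(NA_real_, c(n_keep, settings$chains, d))
  lp_keep <- matrix(NA_real_, n_keep, settings$chains)
  acc_tot <- matrix(0, settings$chains, d)
  scales <- matrix(NA_real_, settings$chains, d)

  for (ch in seq_len(settings$chains)) {
    set.seed(settings$seed + 7919L * ch)
    theta <- init + settings$jitter * stats::rnorm(d)
    lp <- lpfun(theta)
    tries <- 0L
    while (!is.finite(lp) && tries < 100L) {
      theta <- init + settings$jitter * stats::rnorm(d)
      lp <- lpfun(theta)
      tries <- tries + 1L
    }
    if (!is.finite(lp)) stop("could not find a finite starting point for chain ", ch)

    if (use_cpp) {
      res <- haddock_mcmc_chain_cpp(
        target$env, theta, settings$warmup, settings$iter, settings$thin, scale0
      )
      draws[, ch, ] <- res$draws
      lp_keep[, ch] <- res$lp
      acc_tot[ch, ] <- res$accept * settings$iter
      scales[ch, ] <- res$scales
      next
    }

    ls <- rep(log(scale0), d)
    kept <- 0L
    total <- settings$warmup + settings$iter
    for (t in seq_len(total)) {
      step <- 1 / max(10, t)^0.6
      for (j in seq_len(d)) {
        prop <- theta
        prop[j] <- theta[j] + exp(ls[j]) * stats::rnorm(1L)
        lpp <- lpfun(prop)
        acc <- is.finite(lpp) && (lpp - lp > log(stats::runif(1L)))
        if (acc) {
          theta <- prop
          lp <- lpp
        }
        if (t <= settings$warmup) {
          ls[j] <- ls[j] + step * ((acc) - 0.44)
        } else {
          acc_tot[ch, j] <- acc_tot[ch, j] + acc
        }
      }
      if (t > settings$warmup && (t - settings$warmup) %% settings$thin == 0L) {
        kept <- kept + 1L
        draws[kept, ch, ] <- theta
        lp_keep[kept, ch] <- lp
      }
    }
    scales[ch, ] <- exp(ls)
  }
  structure(
    list(
      draws = draws, lp = lp_keep,
      accept = acc_tot / settings$iter, scales = scales,
      settings = settings
    ),
    class = "posterior_draws"
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat: with `m` chains of length `n`, within-chain
#' variance `W`, between-chain variance `B`, the statistic is
#' `sqrt(((n-1)/n * W + B/n) / W)`; values near 1 indicate the chains
#' sample the same distribution, and the convergence rule used throughout
#' the package is R-hat < 1.1.
#'
#' @param x draws for one quantity: iterations x chains matrix.
#' @return scalar R-hat.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2L) stop("rhat needs at least 2 chains")
  if (n < 4L) stop("rhat needs at least 4 draws per chain")
  W <- mean(apply(x, 2, stats::var))
  B_n <- stats::var(colMeans(x)) # = B/n
  if (W == 0) {
    return(if (B_n == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B_n) / W)
}

# crude effective sample size: pooled chains, initial-positive-sequence
# truncation of the autocorrelation sum
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (stats::var(as.vector(x)) == 0) {
    return(n * m)
  }
  rho <- rowMeans(vapply(
    seq_len(m),
    function(ch) {
      stats::acf(x[, ch], lag.max = min(n - 1L, 100L), plot = FALSE)$acf[-1, 1, 1]
    },
    numeric(min(n - 1L, 100L))
  ))
  s <- 0
  for (t in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  min(n * m, n * m / (1 + 2 * s))
}

#' Posterior summary table
#'
#' Median, mean, SD and central 95% credibility bounds per sampled
#' quantity, over pooled post-warm-up draws, plus R-hat and a crude
#' effective sample size per quantity.
#'
#' @param draws a `posterior_draws` object (from [lc_mcmc()]), with
#'   quantity names in `dimnames(draws$draws)[[3]]`, or a plain
#'   iterations x chains x quantities array.
#' @return data frame with one row per quantity.
#' @export
posterior_summary <- function(draws) {
  a <- if (inherits(draws, "posterior_draws")) draws$draws else draws
  if (!length(a)) stop("empty draws")
  qn <- dimnames(a)[[3]]
  if (is.null(qn)) qn <- paste0("theta[", seq_len(dim(a)[3]), "]")
  out <- do.call(rbind, lapply(seq_len(dim(a)[3]), function(k) {
    x <- a[, , k]
    pooled <- as.vector(x)
    qs <- stats::quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(
      param = qn[k], median = qs[2], mean = mean(pooled),
      sd = stats::sd(pooled), q2.5 = qs[1], q97.5 = qs[3],
      rhat = rhat(x), ess = ess_basic(x), stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(
    "posterior_draws: %d iterations x %d chains x %d quantities\n",
    d[1], d[2], d[3]
  ))
  invisible(x)
}
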