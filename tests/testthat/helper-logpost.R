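# Independent R implementation of the haddock joint log-posterior, used
# as the oracle for the compiled density.  Written from the model
# definition (not from the C++ code): the year-effect covariance is
# inverted with solve()/determinant() instead of the rank-one update,
# and the forward model is assembled with matrix operations.

ref_haddock_logpost <- function(theta, model) {
  m <- model$env
  A <- m$A
  Y <- m$Y
  # unpack mapped parameters
  v <- list(
    phi = m$phi, T_phi = m$T_phi, m_e = m$m_e, sigma_phi = m$sigma_phi,
    M4plus = m$M4plus, sigma_F = m$sigma_F, sigma_xi = m$sigma_xi,
    e0 = m$e0, m_a = m$m_a, g = m$g, D = m$D, f = m$f, q = m$q,
    sigma_L = m$sigma_L, sigma_I = m$sigma_I
  )
  slot <- c(
    "phi", "T_phi", "m_e", "sigma_phi", "m_a", "M4plus", "g", "D", "f",
    "sigma_F", "q", "sigma_L", "sigma_I", "sigma_xi", "e0"
  )
  vec_slots <- c("m_a", "g", "D", "f", "q", "sigma_L", "sigma_I")
  lp <- 0
  for (k in seq_len(nrow(m$map))) {
    ti <- m$map[k, 1] + 1L
    s <- slot[m$map[k, 2]]
    val <- if (m$prior[ti, 4] == 1) exp(theta[ti]) else theta[ti]
    if (s %in% vec_slots) v[[s]][m$map[k, 3] + 1L] <- val else v[[s]] <- val
  }
  for (ti in seq_len(nrow(m$prior))) {
    th <- theta[ti]
    fam <- m$prior[ti, 1]
    p1 <- m$prior[ti, 2]
    p2 <- m$prior[ti, 3]
    if (fam == 0) {
      lp <- lp + dnorm(th, p1, p2, log = TRUE)
    } else if (fam == 1) {
      if (th < p1 || th > p2) {
        return(-Inf)
      }
      lp <- lp - log(p2 - p1)
    } else {
      val <- if (m$prior[ti, 4] == 1) exp(th) else th
      if (val < 0) {
        return(-Inf)
      }
      lp <- lp + log(2) + dnorm(val, 0, p1, log = TRUE)
      if (m$prior[ti, 4] == 1) lp <- lp + th
    }
  }
  off <- nrow(m$prior)
  u_rec <- if (m$est_u_rec) theta[off + seq_len(Y)] else m$u_rec0
  if (m$est_u_rec) off <- off + Y
  u_eff <- if (m$est_u_eff) theta[off + seq_len(Y - 1)] else m$u_eff0
  if (m$est_u_rec) lp <- lp + sum(dnorm(u_rec, log = TRUE))
  if (m$est_u_eff) lp <- lp + sum(dnorm(u_eff, log = TRUE))

  # deterministic structure
  ex <- exp(v$T_phi * (m$T - mean(m$T)))
  phi_y <- v$phi * (Y / sum(ex)) * ex
  e <- v$e0 + c(0, cumsum(v$sigma_F * u_eff))
  F <- outer(ifelse(m$ages >= m$fished_min_age, v$f, 0), exp(e))
  delta <- rep(1, A)
  for (a in which(m$has_g)) {
    s <- sum(exp(v$g[a] * m$G))
    if (!is.finite(s) || s <= 0) {
      return(-Inf)
    }
    delta[a] <- Y / s
  }

  N <- matrix(0, A, Y)
  M <- matrix(v$M4plus, A, Y)
  N[-1, 1] <- m$n_init
  for (y in seq_len(Y)) {
    ssb <- sum(N[-1, y] * m$P[-1, y] * m$W[-1, y])
    N[1, y] <- if (ssb > 0) {
      exp(log(1000 * ssb * phi_y[y]) - v$m_e - v$sigma_phi^2 / 2 +
        v$sigma_phi * u_rec[y])
    } else {
      0
    }
    for (a in seq_len(A)) {
      base <- if (m$has_m[a]) v$m_a[a] else v$M4plus
      if (m$has_g[a]) base <- base * delta[a] * exp(v$g[a] * m$G[y])
      if (m$has_D[a]) base <- base * (1 + v$D[a] * N[a, y])
      M[a, y] <- base
    }
    if (y < Y) {
      surv <- N[, y] * exp(-(M[, y] + F[, y]))
      N[-1, y + 1] <- surv[-A]
      if (m$plus_group) N[A, y + 1] <- N[A, y + 1] + surv[A]
    }
  }
  Mc <- if (m$catch_M_age_specific) M else matrix(v$M4plus, A, Y)
  Z <- F + Mc
  C <- ifelse(Z > 0, F / Z, 0) * N * (1 - exp(-Z))

  for (a in which(m$landed)) {
    obs <- m$logL[a, ]
    okk <- is.finite(obs)
    if (!any(okk)) next
    if (any(C[a, okk] <= 0)) {
      return(-Inf)
    }
    lp <- lp + sum(dnorm(obs[okk], log(C[a, okk]) - 0.5 * v$sigma_L[a]^2,
      v$sigma_L[a],
      log = TRUE
    ))
  }
  for (y in seq_len(Y)) {
    i <- which(m$surveyed & is.finite(m$logI[, y]))
    if (!length(i)) next
    if (any(N[i, y] <= 0)) {
      return(-Inf)
    }
    r <- m$logI[i, y] - log(v$q[i] * N[i, y])
    S <- diag(v$sigma_I[i]^2, length(i)) + v$sigma_xi^2
    lp <- lp - 0.5 * (length(i) * log(2 * pi) +
      as.numeric(determinant(S, logarithm = TRUE)$modulus) +
      drop(r %*% solve(S, r)))
  }
  lp
}
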