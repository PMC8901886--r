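test_that("spawning biomass is the maturity-weighted weight sum", {
  expect_equal(
    compute_ssb(c(100, 50, 10) * 1e3, c(0, 0.5, 1), c(0.5, 1, 2)),
    45e3
  )
  expect_equal(compute_ssb(c(1e5, 2e5), c(0, 0), c(1, 2)), 0)
  expect_equal(compute_ssb(1, 1, 2.7), 2.7)
  expect_error(compute_ssb(1:3, 1:2, 1:3), "age range")
})

test_that("fecundity correction makes the mean over years exact", {
  expect_equal(fecundity_series(100, 0.5, rep(3.2, 7)), rep(100, 7))
  expect_equal(fecundity_series(100, 0, c(1, 5, 9)), rep(100, 3))
  # direct evaluation of the formula on a scaled series
  T <- c(-1, 0, 1)
  phi_y <- fecundity_series(100, 0.5, T)
  ex <- exp(0.5 * (T - mean(T)))
  expect_equal(phi_y, 100 * (3 / sum(ex)) * ex)
  expect_equal(mean(phi_y), 100, tolerance = 1e-13)
  # property: unbiased for arbitrary series and coefficients
  set.seed(42)
  for (i in 1:20) {
    T <- rnorm(sample(3:40, 1), mean = 4, sd = 2)
    T_phi <- runif(1, -1, 1)
    expect_lt(abs(mean(fecundity_series(7.7, T_phi, T)) - 7.7), 1e-12)
  }
  expect_error(fecundity_series(100, 0.5, numeric(0)), "empty")
})

test_that("recruitment follows the corrected lognormal", {
  expect_equal(recruit(1e6, 1, log(10), 0), 1e5)
  expect_equal(
    recruit(2e6, 3, 1, 0.5, noise = 0),
    2e6 * 3 * exp(-1) * exp(-0.125)
  )
  expect_equal(recruit(0, 1, 1, 0.5), 0)
  expect_error(recruit(-1, 1, 1, 0.5), ">= 0")
  expect_error(recruit(1, 1, 1, -0.5), ">= 0")
})

test_that("juvenile mortality has the unbiased predation factor", {
  yrs <- 10
  G <- runif(yrs, 500, 2500)
  expect_equal(
    natural_mortality(1, 0.6, 0, 0, G, rep(1e5, yrs)),
    rep(0.6, yrs)
  )
  # unbiasedness: mean over years equals the baseline when D = 0
  set.seed(7)
  for (i in 1:20) {
    G <- runif(sample(3:30, 1), 0, 3000)
    g <- runif(1, -1e-3, 1e-3)
    M <- natural_mortality(0, 1.1, g, 0, G, rep(0, length(G)))
    expect_lt(abs(mean(M) - 1.1), 1e-12)
  }
  # plug-in: craft G so the predation factor is 1.2 in year 1, then the
  # density term doubles it
  G <- c(log(1.5), 0) # with g = 1: delta = 2/(1.5+1), factor_1 = 1.2
  M <- natural_mortality(2, 0.3, 1, 1e-6, G, c(1e6, 0))
  expect_equal(M[1], 0.72)
  expect_error(natural_mortality(4, 0.3, 0, 0, G, c(1, 1)), "ages < 4")
})

test_that("effort random walk drives fishing mortality", {
  fm <- fishing_mortality_series(c(`3` = 0.2), e0 = 0, sigma_F = 0, increments = rep(0, 4))
  expect_equal(unname(fm$F["3", ]), rep(0.2, 5))
  fm <- fishing_mortality_series(c(`3` = 0.2), 0, 0.1, increments = c(1, -1))
  expect_equal(fm$e, c(0, 0.1, 0))
  fm <- fishing_mortality_series(c(`3` = 0.5, `4` = 0.8), 0, 0.1, c(1, -1), ages = 0:4)
  expect_equal(unname(fm$F["0", ]), rep(0, 3)) # unselected age
  expect_equal(unname(fm$F["4", 2]), 0.8 * exp(0.1))
  expect_error(fishing_mortality_series(c(`3` = 0.2), 0, -1, 0), ">= 0")
})

test_that("cohorts decay exponentially and Baranov splits them exactly", {
  expect_equal(advance_age(1000, 0), 1000)
  expect_equal(advance_age(1000, 0.5), 1000 * exp(-0.5), tolerance = 1e-10)
  expect_lt(advance_age(1000, 50), 1e-15)
  expect_error(advance_age(1000, -0.1), ">= 0")

  expect_equal(baranov_catch(1000, 0, 0.2), 0)
  expect_equal(baranov_catch(1000, 0.2, 0.2), 0.5 * 1000 * (1 - exp(-0.4)))
  expect_equal(baranov_catch(1000, 1e6, 0.2), 1000, tolerance = 1e-3)
  expect_equal(baranov_catch(1000, 0, 0), 0) # no division by zero
  # monotone nondecreasing in F, bounded by total deaths
  Fs <- seq(0, 5, by = 0.05)
  C <- baranov_catch(1000, Fs, 0.3)
  expect_true(all(diff(C) >= 0))
  expect_true(all(C <= 1000 * (1 - exp(-(Fs + 0.3)))))
  # conservation: catch + natural deaths + survivors = cohort
  for (Fv in c(0, 0.1, 1, 10)) {
    for (Mv in c(0.05, 0.4)) {
      Z <- Fv + Mv
      C <- baranov_catch(1000, Fv, Mv)
      D <- if (Z > 0) Mv / Z * 1000 * (1 - exp(-Z)) else 0
      expect_lt(abs(C + D + 1000 * exp(-Z) - 1000), 1e-12 * 1000)
    }
  }
})

test_that("observation model is exact with noise off and shares the year effect", {
  sc <- lc_scenario("tiny")
  p <- sc$haddock
  A <- length(p$ages)
  N <- matrix(1e5 * (1:A), A, 3, dimnames = list(p$ages, 2000:2002))
  C <- N * 0.1
  p0 <- p
  p0$sigma_L_a[] <- 0 # with all SDs zero the tables are exact
  p0$sigma_I_a[] <- 0
  p0$sigma_xi <- 0
  obs <- apply_observation_model(C, N, p0)
  expect_equal(obs$L, C[names(p$sigma_L_a), ])
  expect_equal(obs$I, N[names(p$q_a), ] * p$q_a)
  # shared year effect: with sigma_I = 0, sigma_xi > 0 the log-residual
  # is identical across ages within a year
  p$sigma_I_a[] <- 0
  p$sigma_xi <- 0.3
  noise <- list(
    L = matrix(0, length(p$sigma_L_a), 3),
    I = matrix(rnorm(length(p$q_a) * 3), length(p$q_a), 3),
    xi = c(1, -0.5, 2)
  )
  obs <- apply_observation_model(C, N, p, noise)
  r <- log(obs$I) - log(N[names(p$q_a), ] * p$q_a)
  expect_equal(r[1, ], r[3, ])
  expect_equal(unname(r[1, ]), 0.3 * noise$xi)
})

test_that("noise-free simulator reduces to pure survival and is deterministic", {
  sc <- lc_scenario("tiny")
  p <- sc$haddock
  p$g_a[] <- 0
  p$D_a[] <- 0
  p$f_a[] <- 0
  ds <- tiny_dataset()
  bio <- haddock_biology(ds$haddock$W, ds$haddock$P, ds$haddock$T, ds$haddock$G)
  sim <- simulate_haddock(p, bio, sc$init_had,
    process_noise = FALSE, obs_noise = FALSE
  )
  # each cohort decays geometrically by its age-specific mortality
  ages <- p$ages
  for (y in 1:5) {
    for (a in ages[-length(ages)]) {
      m <- if (a < 4) p$m_a[[as.character(a)]] else p$M4plus
      expect_equal(
        sim$N[as.character(a + 1), y + 1],
        sim$N[as.character(a), y] * exp(-m)
      )
    }
  }
  # determinism: same seed, identical output
  s1 <- simulate_haddock(sc$haddock, bio, sc$init_had, seed = 99)
  s2 <- simulate_haddock(sc$haddock, bio, sc$init_had, seed = 99)
  expect_identical(s1, s2)
})

test_that("a full tiny run satisfies the state invariants in every cell", {
  ds <- tiny_dataset()
  sim <- ds$truth$haddock
  expect_true(all(sim$N >= 0))
  expect_true(all(sim$C >= 0))
  expect_equal(sim$Z, sim$M + sim$F)
  fished <- as.integer(rownames(sim$N)) >= sim$params$fished_min_age
  expect_true(all(sim$C[fished, ] <= sim$N[fished, ]))
  expect_true(all(sim$I >= 0))
  expect_true(all(sim$L >= 0))
  # compensatory density dependence: dM/dN >= 0 for D >= 0
  p <- sim$params
  expect_true(all(p$D_a >= 0))
})
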