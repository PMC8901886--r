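test_that("cod spawning biomass shares the haddock kernel", {
  expect_equal(cod_ssb(c(0, 0), c(0, 0), c(1, 2)), 0)
  expect_equal(cod_ssb(2, 0.5, 3), 3)
  N <- runif(5, 0, 1e6)
  P <- runif(5)
  W <- runif(5, 0.1, 5)
  expect_identical(cod_ssb(N, P, W), compute_ssb(N, P, W))
})

test_that("early life stages chain eggs -> larvae -> 0-group", {
  sc <- lc_scenario("tiny")
  p <- sc$cod
  p$t_e <- 30
  p$M_e <- 0.1
  el <- early_life(1e9 / p$tau, p, T_l = 0, noise = 0)
  expect_equal(el[["N_e"]], 1e9)
  expect_equal(el[["N_l"]], 1e9 * exp(-3))
  p$psi_l <- 0
  p$t_l <- 60
  p$M_l <- 0.05
  el <- early_life(1e9 / p$tau, p, T_l = 12, noise = 0)
  expect_equal(el[["N_z"]], el[["N_l"]] * exp(-3))
  # noise off, sigma_sp irrelevant at noise = 0
  p$sigma_sp <- 0
  expect_equal(early_life(123, p, 5)[["N_e"]], 123 * p$tau)
  # warmer larval season raises 0-group survival when psi_l > 0
  p$psi_l <- 0.12
  z <- vapply(c(4, 6, 8, 10), function(T) early_life(1e5, p, T)[["N_z"]], numeric(1))
  expect_true(all(diff(z) > 0))
  expect_error(
    {
      p$t_e <- -1
      early_life(1, p, 5)
    },
    "durations"
  )
})

test_that("inter-cohort density dependence is compensatory and saturating", {
  expect_equal(juvenile_transition(1000, 0, 0.5), 1000 * exp(-0.5))
  expect_equal(juvenile_transition(1000, 0.001, 0.5), 500 * exp(-0.5))
  # saturation at exp(-M_j)/beta
  expect_equal(juvenile_transition(1e9, 1e-3, 0.5), exp(-0.5) / 1e-3, tolerance = 1e-5)
  # increasing and concave in N_prev; realized survival decreasing
  N <- seq(1, 1e6, length.out = 200)
  out <- juvenile_transition(N, 2e-6, 0.4)
  expect_true(all(diff(out) > 0))
  expect_true(all(diff(diff(out)) < 1e-12))
  expect_true(all(diff(out / N) < 0))
  expect_error(juvenile_transition(-1, 0, 0.5), ">= 0")
})

test_that("adult transition equals the shared survival kernel", {
  expect_equal(adult_transition(1000, 0.3, 0.2), 1000 * exp(-0.5), tolerance = 1e-10)
  expect_equal(adult_transition(1000, 0, 0), 1000)
  expect_equal(adult_transition(777, 0.25, 0.2), advance_age(777, 0.45))
})

test_that("cod fishing mortality uses log selectivity plus effort", {
  fm <- cod_fishing_mortality(c(`4` = -1), f0 = 0.5, sigma_f = 0, increments = 0)
  expect_equal(unname(fm$F["4", 1]), exp(-0.5))
  fm <- cod_fishing_mortality(c(`4` = -1), 0, 0, rep(0, 5))
  expect_equal(length(unique(fm$F["4", ])), 1L)
  fm <- cod_fishing_mortality(c(`4` = -1), 0.3, 1, increments = c(0.2, -0.2))
  expect_equal(fm$f, c(0.3, 0.5, 0.3))
  expect_equal(unname(cod_catch(1000, 0.2, 0.2)), baranov_catch(1000, 0.2, 0.2))
  expect_equal(cod_catch(1000, 0, 0.2), 0)
})

test_that("predator biomass covariate sums ages 3-12 in metric tons", {
  N <- stats::setNames(rep(0, 13), 1:13)
  W <- stats::setNames(rep(2, 13), 1:13)
  expect_equal(mature_biomass(N, W), 0)
  N["5"] <- 1e6
  expect_equal(mature_biomass(N, W), 2000)
  expect_error(mature_biomass(N[1:4], W[1:4]), "missing")
  # maturity weighting can only shrink it
  P <- stats::setNames(runif(13), 1:13)
  expect_lte(mature_biomass(N, W, P = P), mature_biomass(N, W))
})

test_that("deterministic cod simulator is a Leslie-type survival chain", {
  sc <- lc_scenario("tiny")
  p <- sc$cod
  p$beta_a[] <- 0
  p$psi_l <- 0
  p$f_a[] <- -Inf # no fishing
  ds <- tiny_dataset()
  bio <- cod_biology(ds$cod$W, ds$cod$P, ds$cod$T)
  sim <- suppressWarnings(
    simulate_cod(p, bio, sc$init_cod, process_noise = FALSE, obs_noise = FALSE)
  )
  for (y in 1:5) {
    for (a in p$ages[-length(p$ages)]) {
      expected <- if (a + 1 <= p$juv_max_age) exp(-p$M_j) else exp(-p$M4plus)
      expect_equal(
        sim$N[as.character(a + 1), y + 1] / sim$N[as.character(a), y],
        expected
      )
    }
    # egg -> larva -> 0-group ordering without a positive temperature boost
    expect_lte(sim$N_z[y], sim$N_l[y])
    expect_lte(sim$N_l[y], sim$N_e[y])
  }
  # fixed seed reproducibility of the stochastic run
  s1 <- simulate_cod(sc$cod, bio, sc$init_cod, seed = 4)
  s2 <- simulate_cod(sc$cod, bio, sc$init_cod, seed = 4)
  expect_identical(s1, s2)
})

test_that("a long cod run satisfies the state invariants in every cell", {
  ds <- generate_dataset(lc_scenario("paper", 12))
  sim <- ds$truth$cod
  expect_identical(dim(sim$N), c(13L, 54L))
  expect_true(all(sim$N >= 0))
  expect_true(all(sim$C >= 0))
  expect_true(all(sim$C <= sim$N))
  expect_true(all(sim$G >= 0))
  expect_true(all(sim$N_e >= sim$N_l))
  expect_true(all(sim$I >= 0))
  # cohort conservation through the Baranov split at fished ages
  fished <- as.integer(rownames(sim$N)) >= sim$params$fish_min_age
  F <- sim$F[fished, ]
  Z <- F + sim$params$M4plus
  N <- sim$N[fished, ]
  D <- sim$params$M4plus / Z * N * (1 - exp(-Z))
  expect_equal(sim$C[fished, ] + D + N * exp(-Z), N, tolerance = 1e-12)
})
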