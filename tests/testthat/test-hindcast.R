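test_that("scenario grids validate and default to the 0.5-1.5 range", {
  scens <- build_scenarios(c(0.5, 1.0, 1.5), draws = 10)
  expect_length(scens, 3)
  expect_equal(vapply(scens, `[[`, numeric(1), "Fm"), c(0.5, 1, 1.5))
  expect_error(build_scenarios(numeric(0)), "empty")
  expect_error(build_scenarios(c(1, 1)), "duplicate")
  expect_error(build_scenarios(c(-0.5, 1)), "> 0")
  expect_error(build_scenarios(1, draws = 0), "draws")
})

test_that("the identity scenario reproduces the baseline run bit-exactly", {
  sc <- lc_scenario("tiny", 3)
  ds <- tiny_dataset(3)
  cb <- cod_biology(ds$cod$W, ds$cod$P, ds$cod$T)
  id <- build_scenarios(1, draws = 1)[[1]]
  # deterministic skeleton: identity multiplier equals a plain simulation
  hc <- hindcast_cod(sc$cod, id, cb, sc$init_cod, seed = 5, process_noise = FALSE)
  base <- simulate_cod(sc$cod, cb, sc$init_cod,
    process_noise = FALSE, obs_noise = FALSE
  )
  expect_identical(unname(hc$G[1, ]), unname(base$G))
  # stochastic runs: repeated calls with the same seed are identical
  id2 <- build_scenarios(1, draws = 5)[[1]]
  h1 <- hindcast_cod(sc$cod, id2, cb, sc$init_cod, seed = 5)
  h2 <- hindcast_cod(sc$cod, id2, cb, sc$init_cod, seed = 5)
  expect_identical(h1, h2)
})

test_that("ensemble summaries collapse correctly and match the sort oracle", {
  one <- matrix(3.3, 1, 4, dimnames = list(NULL, 2000:2003))
  s <- summarize_ensemble(one)
  expect_equal(s$by_year$lo95, rep(3.3, 4))
  expect_equal(s$by_year$hi95, rep(3.3, 4))
  expect_equal(s$variability, 0)
  two <- rbind(rep(0, 3), rep(100, 3))
  colnames(two) <- 2000:2002
  expect_equal(summarize_ensemble(two)$by_year$mean, rep(50, 3))
  set.seed(4)
  e5 <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(NULL, 2000:2005))
  s5 <- summarize_ensemble(e5)
  for (j in 1:6) {
    expect_equal(s5$by_year$lo95[j], sort_quantile(e5[, j], 0.025))
    expect_equal(s5$by_year$hi95[j], sort_quantile(e5[, j], 0.975))
  }
  expect_error(summarize_ensemble(matrix(0, 0, 0)), "empty")
})

test_that("without predation the haddock hindcast ignores the scenario", {
  sc <- lc_scenario("tiny", 3)
  ds <- tiny_dataset(3)
  hb <- haddock_biology(ds$haddock$W, ds$haddock$P, ds$haddock$T, ds$haddock$G)
  p <- sc$haddock
  p$g_a[] <- 0
  scen <- build_scenarios(1, draws = 4)[[1]]
  G1 <- matrix(1000, 4, 20, dimnames = list(NULL, names(hb$T_y)))
  G2 <- matrix(3000, 4, 20, dimnames = list(NULL, names(hb$T_y)))
  h1 <- hindcast_haddock(p, G1, scen, hb, sc$init_had, seed = 8)
  h2 <- hindcast_haddock(p, G2, scen, hb, sc$init_had, seed = 8)
  expect_identical(h1$abundance, h2$abundance)
  expect_identical(nrow(h1$abundance), 4L) # ensemble size equals draws
})

test_that("harvest intensity moves the two species in opposite directions", {
  sc <- lc_scenario("tiny", 3)
  ds <- tiny_dataset(3)
  cb <- cod_biology(ds$cod$W, ds$cod$P, ds$cod$T)
  hb <- haddock_biology(ds$haddock$W, ds$haddock$P, ds$haddock$T, ds$haddock$G)
  hc <- lc_hindcast(
    sc$cod, sc$haddock, build_scenarios(c(0.5, 1.5), draws = 25),
    cb, hb, sc$init_cod, sc$init_had,
    seed = 21
  )
  cod_mean <- vapply(hc$scenarios, function(s) mean(s$cod_biomass$by_year$mean), numeric(1))
  had_mean <- vapply(hc$scenarios, function(s) mean(s$had_abundance$by_year$mean), numeric(1))
  expect_lt(cod_mean[2], cod_mean[1]) # heavier cod harvest, less cod
  expect_gt(had_mean[2], had_mean[1]) # released predation, more haddock
  # envelope sanity: lower <= mean <= upper everywhere
  for (s in hc$scenarios) {
    b <- s$had_abundance$by_year
    expect_true(all(b$lo95 <= b$mean + 1e-9 & b$mean <= b$hi95 + 1e-9))
  }
})

test_that("absolute-F mode imposes a flat fishing mortality", {
  sc <- lc_scenario("tiny", 3)
  ds <- tiny_dataset(3)
  cb <- cod_biology(ds$cod$W, ds$cod$P, ds$cod$T)
  sc_abs <- build_scenarios(0.9, mode = "absolute", draws = 1)[[1]]
  hc <- hindcast_cod(sc$cod, sc_abs, cb, sc$init_cod, seed = 2, process_noise = FALSE)
  # heavier flat F than the baseline 0.25-0.4 selectivity: less biomass
  base <- simulate_cod(sc$cod, cb, sc$init_cod, process_noise = FALSE, obs_noise = FALSE)
  expect_lt(hc$G[1, ncol(hc$G)], base$G[length(base$G)])
})
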