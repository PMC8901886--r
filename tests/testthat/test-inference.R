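test_that("compiled joint density matches an independent R implementation", {
  sc <- lc_scenario("tiny", 6)
  ds <- tiny_dataset(6)
  model <- build_model(
    ds$haddock, sc$haddock, recovery_priors_haddock(ds$haddock), "haddock"
  )
  set.seed(33)
  for (i in 1:12) {
    theta <- model$theta_init + 0.3 * rnorm(length(model$theta_init))
    expect_equal(
      log_posterior(theta, model),
      ref_haddock_logpost(theta, model),
      tolerance = 1e-10
    )
  }
  # also with a correlated year effect and a masked cell
  sc2 <- lc_scenario("tiny", 6)
  sc2$haddock$sigma_xi <- 0.15
  ds2 <- generate_dataset(sc2)
  ds2$haddock$I[3, 2] <- NA
  ds2$haddock$L[5, 1] <- NA
  m2 <- build_model(
    ds2$haddock, sc2$haddock, recovery_priors_haddock(ds2$haddock), "haddock"
  )
  for (i in 1:6) {
    theta <- m2$theta_init + 0.3 * rnorm(length(m2$theta_init))
    expect_equal(
      log_posterior(theta, m2),
      ref_haddock_logpost(theta, m2),
      tolerance = 1e-10
    )
  }
})

test_that("masked observations contribute exactly zero likelihood terms", {
  sc <- lc_scenario("tiny", 6)
  ds <- tiny_dataset(6)
  model <- build_model(
    ds$haddock, sc$haddock, recovery_priors_haddock(ds$haddock), "haddock"
  )
  theta <- model$theta_init
  lp_full <- log_posterior(theta, model)
  # the parameter values theta encodes (prior-centre initials)
  p0 <- sc$haddock
  p0$T_phi <- 0
  p0$g_a["0"] <- 0
  p0$q_a[c("1", "2", "3")] <- 1
  sigI0 <- 0.5 # halfnormal(1) initial on the natural scale
  # latent states implied by theta (innovations all zero, e0 = 0)
  sim <- simulate_haddock(
    p0,
    haddock_biology(ds$haddock$W, ds$haddock$P, ds$haddock$T, ds$haddock$G),
    ds$haddock$n_init,
    e0 = 0, process_noise = FALSE, obs_noise = FALSE
  )
  # with sigma_xi = 0, each masked index cell removes one independent
  # lognormal term
  dsm <- ds$haddock
  cells <- cbind(c(2, 7, 11), c(1, 3, 5)) # (year-row, age-col) of I
  removed <- 0
  for (k in seq_len(nrow(cells))) {
    yr <- rownames(dsm$I)[cells[k, 1]]
    ag <- colnames(dsm$I)[cells[k, 2]]
    removed <- removed + dnorm(
      log(dsm$I[yr, ag]), log(p0$q_a[[ag]] * sim$N[ag, yr]), sigI0,
      log = TRUE
    )
    dsm$I[yr, ag] <- NA
  }
  mm <- build_model(dsm, sc$haddock, recovery_priors_haddock(dsm), "haddock")
  expect_equal(log_posterior(theta, mm) - lp_full, -removed, tolerance = 1e-8)
})

test_that("likelihood peaks at the truth for a near-noise-free system", {
  # zero process noise (latent trajectory deterministic at truth), tiny
  # observation noise so the likelihood is sharply peaked
  sc <- quiet_scenario(9, process_sd = 0, obs_sd = 0.01)
  ds <- generate_dataset(sc)
  pr <- lc_priors(lc_prior("T_phi", family = "normal", p1 = 0, p2 = 1))
  model <- build_model(ds$haddock, sc$haddock, pr, "haddock")
  truth <- model$theta_init
  truth[1] <- sc$haddock$T_phi
  lp_truth <- log_posterior(truth, model)
  expect_true(is.finite(lp_truth))
  for (j in c(1, 5, 20)) {
    pert <- truth
    pert[j] <- pert[j] + 1
    expect_gt(lp_truth, log_posterior(pert, model))
  }
})

test_that("R-hat matches the closed-form potential scale reduction", {
  set.seed(1)
  x <- matrix(rnorm(2000), 500, 4)
  # direct evaluation of the formula on crafted chains
  n <- nrow(x)
  W <- mean(apply(x, 2, var))
  B_n <- var(colMeans(x))
  expect_equal(rhat(x), sqrt(((n - 1) / n * W + B_n) / W))
  # identical copies of one sequence: R-hat ~ 1
  y <- matrix(rep(rnorm(300), 3), 300, 3)
  expect_lt(abs(rhat(y) - 1), 0.01)
  # chains offset by a large constant diverge
  z <- cbind(rnorm(100), rnorm(100) + 10)
  expect_gt(rhat(z), 1.1)
  # location invariance
  expect_equal(rhat(x + 5), rhat(x))
  expect_error(rhat(matrix(1:10, 10, 1)), "2 chains")
  expect_error(rhat(matrix(1:6, 3, 2)), "4 draws")
})

test_that("posterior summaries match a sort-based quantile oracle", {
  set.seed(2)
  a <- array(rnorm(5 * 3 * 2), c(5, 3, 2), dimnames = list(NULL, NULL, c("a", "b")))
  s <- posterior_summary(a)
  for (k in 1:2) {
    pooled <- as.vector(a[, , k])
    expect_equal(s$q2.5[k], sort_quantile(pooled, 0.025))
    expect_equal(s$median[k], sort_quantile(pooled, 0.5))
    expect_equal(s$q97.5[k], sort_quantile(pooled, 0.975))
  }
  # constant draws
  cst <- array(7, c(10, 2, 1), dimnames = list(NULL, NULL, "c"))
  sc_ <- posterior_summary(cst)
  expect_equal(sc_$median, 7)
  expect_equal(sc_$sd, 0)
  expect_equal(sc_$rhat, 1)
  expect_error(posterior_summary(array(0, c(0, 0, 0))), "empty")
})

test_that("prior and settings constructors validate their inputs", {
  expect_error(lc_prior("T_phi", family = "normal", p1 = 0), "sd")
  expect_error(lc_prior("q_a", family = "uniform", p1 = 2, p2 = 1), "p1 < p2")
  expect_error(lc_prior("sigma_I_a", family = "halfnormal", p1 = -1), "> 0")
  expect_error(
    lc_priors(
      lc_prior("T_phi", family = "normal", p1 = 0, p2 = 1),
      lc_prior("T_phi", family = "normal", p1 = 0, p2 = 2)
    ),
    "duplicate"
  )
  expect_error(mcmc_settings(chains = 0), "positive")
  s <- mcmc_settings(profile = "full")
  expect_equal(s$warmup, 250000L)
  expect_equal(s$iter, 250000L)
  expect_equal(s$thin, 1000L)
})

test_that("model building rejects inconsistent inputs", {
  sc <- lc_scenario("tiny", 6)
  ds <- tiny_dataset(6)
  pr <- recovery_priors_haddock(ds$haddock)
  bad <- ds$haddock
  bad$G <- NULL
  expect_error(build_model(bad, sc$haddock, pr, "haddock"), "covariate")
  bad2 <- ds$haddock
  bad2$n_init <- bad2$n_init[-1]
  expect_error(build_model(bad2, sc$haddock, pr, "haddock"), "n_init")
  expect_error(
    build_model(
      ds$haddock, sc$haddock,
      lc_priors(lc_prior("beta_a", age = 1, family = "normal", p1 = 0, p2 = 1)),
      "haddock"
    ),
    "unknown parameter"
  )
  expect_error(
    build_model(
      ds$haddock, sc$haddock,
      lc_priors(lc_prior("g_a", age = 9, family = "normal", p1 = 0, p2 = 1)),
      "haddock"
    ),
    "outside its domain"
  )
})

test_that("short haddock fits are reproducible and fully diagnosed", {
  sc <- lc_scenario("tiny", 6)
  ds <- tiny_dataset(6)
  st <- mcmc_settings(chains = 2, warmup = 300, iter = 300, seed = 5)
  f1 <- lc_fit(ds$haddock, "haddock", sc$haddock, recovery_priors_haddock(ds$haddock), st)
  f2 <- lc_fit(ds$haddock, "haddock", sc$haddock, recovery_priors_haddock(ds$haddock), st)
  expect_equal(f1$summary, f2$summary)
  s <- summary(f1, latents = TRUE)
  expect_true(all(is.finite(s$rhat))) # R-hat defined for every quantity
  expect_equal(nrow(s), length(f1$model$theta_names))
  expect_s3_class(f1, "lc_fit")
  expect_named(coef(f1), f1$model$theta_names[seq_len(f1$model$n_par)])
  # posterior_params substitutes draws into the baseline parameter set
  pp <- posterior_params(f1, 3, seed = 1)
  expect_length(pp, 3)
  expect_s3_class(pp[[1]], "haddock_params")
  expect_false(identical(pp[[1]]$q_a, pp[[2]]$q_a))
})

test_that("the cod model fits end to end and reports diagnostics", {
  sc <- lc_scenario("tiny", 6)
  ds <- tiny_dataset(6)
  pr <- lc_priors(
    lc_prior("psi_l", family = "normal", p1 = 0, p2 = 0.5),
    lc_prior("q_a", age = 2, transform = "log", family = "normal", p1 = 0, p2 = 1.5),
    lc_prior("f0", family = "normal", p1 = 0, p2 = 2)
  )
  fit <- lc_fit(
    ds$cod, "cod", sc$cod, pr,
    mcmc_settings(chains = 2, warmup = 120, iter = 120, seed = 2)
  )
  s <- summary(fit, latents = TRUE)
  expect_true(all(is.finite(s$rhat)))
  expect_equal(fit$model$n_par, 3L)
  expect_true(is.logical(fit$converged))
})

test_that("cod and haddock densities share the additivity contract", {
  # with flat (wide) priors, log-posterior differences equal
  # log-likelihood differences: changing only a prior-free latent must
  # move the posterior by exactly the latent's own N(0,1) term plus the
  # induced likelihood change; verified against the R reference
  sc <- lc_scenario("tiny", 6)
  ds <- tiny_dataset(6)
  model <- build_model(
    ds$haddock, sc$haddock, recovery_priors_haddock(ds$haddock), "haddock"
  )
  th <- model$theta_init
  th2 <- th
  j <- model$n_par + 3L # a recruitment innovation
  th2[j] <- th2[j] + 0.7
  expect_equal(
    log_posterior(th2, model) - log_posterior(th, model),
    ref_haddock_logpost(th2, model) - ref_haddock_logpost(th, model),
    tolerance = 1e-10
  )
})
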