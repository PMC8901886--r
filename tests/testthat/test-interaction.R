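test_that("predation summaries classify effect signs from the interval", {
  G <- rep(1000, 7)
  zero <- matrix(0, 200, 1, dimnames = list(NULL, "g[2]"))
  s <- predation_summary(zero, G)
  expect_equal(s$mean, 0)
  expect_equal(c(s$lo95, s$hi95), c(0, 0))
  expect_equal(s$classification, "not significant")
  pos <- matrix(abs(rnorm(200, 3e-4, 5e-5)), 200, 1, dimnames = list(NULL, "g[0]"))
  expect_equal(predation_summary(pos, G)$classification, "positive")
  neg <- matrix(-abs(rnorm(200, 2e-4, 2e-5)), 200, 1, dimnames = list(NULL, "g[3]"))
  expect_equal(predation_summary(neg, G)$classification, "negative")
  expect_error(predation_summary(matrix(0, 5, 1), G), "g\\[<age>\\]")
})

test_that("predation quantiles match a sort oracle on crafted draws", {
  set.seed(11)
  draws <- matrix(rnorm(100, 1e-4, 1e-4), 100, 1, dimnames = list(NULL, "g[1]"))
  G <- runif(10, 800, 1200)
  s <- predation_summary(draws, G)
  eff <- draws[, 1] * mean(G)
  expect_equal(s$lo95, sort_quantile(eff, 0.025))
  expect_equal(s$hi95, sort_quantile(eff, 0.975))
  expect_equal(s$mean, mean(eff))
})

test_that("weighted smooths recover a linear signal and reject a null", {
  x <- seq(-2, 2, length.out = 30)
  r <- weighted_smooth(1 + 2 * x, rep(0.1, 30), x)
  expect_gt(r$deviance_percent, 99.9)
  set.seed(3)
  rn <- weighted_smooth(rnorm(100), rep(1, 100), rnorm(100))
  expect_lt(rn$deviance_percent, 10)
  expect_true(is.finite(rn$gcv))
})

test_that("only relative weights matter and covariate scale is irrelevant", {
  set.seed(5)
  x <- runif(25, 0, 10)
  y <- sin(x / 2) + rnorm(25, 0, 0.1)
  se <- runif(25, 0.05, 0.5)
  r1 <- weighted_smooth(y, se, x)
  r2 <- weighted_smooth(y, 2 * se, x) # doubling all SEs
  expect_equal(r1$deviance_percent, r2$deviance_percent, tolerance = 1e-8)
  expect_equal(r1$gcv, r2$gcv, tolerance = 1e-8)
  r3 <- weighted_smooth(y, se, 100 * x - 7) # affine covariate rescaling
  expect_equal(r1$deviance_percent, r3$deviance_percent, tolerance = 1e-4)
})

test_that("weighting pays off when noise concentrates in uncertain points", {
  set.seed(8)
  x <- seq(0, 1, length.out = 40)
  se <- rep(0.05, 40)
  se[seq(1, 40, by = 4)] <- 1 # every fourth point is poorly estimated
  y <- 2 * x + rnorm(40, 0, se)
  dev_w <- weighted_smooth(y, se, x)$deviance_percent
  dev_u <- weighted_smooth(y, rep(1, 40), x)$deviance_percent
  expect_gt(dev_w, dev_u)
})

test_that("degenerate smooth inputs are rejected", {
  expect_error(weighted_smooth(1:5, rep(1, 5), 1:5), "at least 8")
  expect_error(weighted_smooth(1:10, rep(0, 10), 1:10), "> 0")
  expect_error(weighted_smooth(rnorm(10), rep(1, 10), rep(2, 10)), "zero variance")
  expect_error(weighted_smooth(1:10, rep(1, 9), 1:10), "lengths")
})

test_that("the deviance table is ordered and round-trips through CSV", {
  x <- seq(-1, 1, length.out = 20)
  mk <- function(resp, cov) {
    weighted_smooth(x + rnorm(20, 0, 0.2), rep(0.2, 20), x,
      response_label = resp, covariate_label = cov
    )
  }
  set.seed(2)
  tab <- deviance_table(list(
    mk("log N age-1", "temperature"), mk("log N age-0", "intercohort"),
    mk("log N age-0", "temperature")
  ))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$response, c("log N age-0", "log N age-0", "log N age-1"))
  expect_equal(tab$covariate[1:2], c("intercohort", "temperature"))
  single <- deviance_table(list(mk("a", "b")))
  expect_equal(nrow(single), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$deviance_percent, tab$deviance_percent)
  expect_error(deviance_table(list()), "no reports")
})

test_that("the inter-cohort covariate tracks the preceding cohort", {
  ds <- tiny_dataset(3)
  cs <- ds$truth$cod
  g1 <- intercohort_series(cs, age = 1)
  expect_true(is.na(g1[1]))
  b1 <- cs$params$beta_a[["1"]]
  expect_equal(unname(g1[5]), unname(b1 * cs$N_z[4]))
  g2 <- intercohort_series(cs, age = 2)
  expect_equal(unname(g2[5]), unname(cs$params$beta_a[["2"]] * cs$N["1", 4]))
  expect_error(intercohort_series(cs, age = 6), "no inter-cohort")
})
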