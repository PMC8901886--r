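# Shared fixtures: tiny synthetic datasets are generated once per run
# and memoized, since several test files exercise the same system.

.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function(seed = 1L) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_dataset(lc_scenario("tiny", seed))
  }
  .fixture_env[[key]]
}

# a quietened variant of the tiny scenario: process SDs and observation
# SDs set separately (zero process noise makes the latent trajectory
# deterministic; a small positive observation SD keeps the lognormal
# likelihood well defined)
quiet_scenario <- function(seed = 1L, process_sd = 0, obs_sd = 0) {
  sc <- lc_scenario("tiny", seed)
  for (nm in c("sigma_phi", "sigma_F", "sigma_xi")) sc$haddock[[nm]] <- process_sd
  sc$haddock$sigma_L_a[] <- obs_sd
  sc$haddock$sigma_I_a[] <- obs_sd
  for (nm in c("sigma_sp", "sigma_f", "sigma_xi")) sc$cod[[nm]] <- process_sd
  sc$cod$sigma_L_a[] <- obs_sd
  sc$cod$sigma_I_a[] <- obs_sd
  sc
}

# type-7 quantile computed from first principles (sort-based oracle)
sort_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
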