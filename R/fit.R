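#' Fit a life-cycle state-space model
#'
#' The package's central fitting function: assembles the model for one
#' species from observed survey indices, landings, biology tables and
#' temperature (plus the predator-biomass covariate for haddock),
#' samples the joint posterior over the configured parameters and the
#' latent process innovations with the adaptive Metropolis-within-Gibbs
#' sampler, and returns a classed fit with convergence diagnostics.
#' Convergence is flagged by the R-hat < 1.1 rule over the model
#' parameters.
#'
#' @param data an `observed_dataset` (see [generate_dataset()]) or a
#'   list with elements `I`, `L`, `W`, `P`, `T`, `n_init` (and `G` for
#'   haddock).
#' @param species `"haddock"` or `"cod"`.
#' @param params baseline [haddock_params()] or [cod_params()]; entries
#'   without a prior are held fixed at these values.
#' @param priors an [lc_priors()] configuration of the sampled entries.
#' @param settings an [mcmc_settings()].
#' @param ... passed to [build_model()].
#' @return object of class `lc_fit`: the model, the `posterior_draws`
#'   (on the natural parameter scale), the summary table, and the
#'   `converged` flag.
#' @seealso [posterior_summary()], [posterior_params()], [lc_hindcast()]
#' @export
lc_fit <- function(data, species = c("haddock", "cod"), params, priors,
                   settings = mcmc_settings(), ...) {
  species <- match.arg(species)
  model <- build_model(data, params, priors, species, ...)
  t0 <- proc.time()[["elapsed"]]
  raw <- lc_mcmc(model, settings = settings)
  elapsed <- proc.time()[["elapsed"]] - t0

  # natural-scale draws: invert the log transform on mapped parameters
  draws <- raw$draws
  for (k in seq_len(model$n_par)) {
    if (model$transforms[k] == 1) draws[, , k] <- exp(draws[, , k])
  }
  dimnames(draws) <- list(NULL, NULL, model$theta_names)
  raw$draws <- draws

  smry <- posterior_summary(raw)
  par_rows <- seq_len(model$n_par)
  converged <- all(smry$rhat[par_rows] < 1.1)

  structure(
    list(
      species = species, model = model, draws = raw, summary = smry,
      converged = converged, settings = settings, elapsed = elapsed
    ),
    class = "lc_fit"
  )
}

#' @export
print.lc_fit <- function(x, ...) {
  d <- dim(x$draws$draws)
  cat(sprintf(
    "Life-cycle state-space model fit (%s)\n  %d sampled parameters + %d latent innovations, %d years\n  %d chains x %d retained draws; max R-hat (parameters) = %.3f -> %s\n",
    x$species, x$model$n_par, x$model$n_latent,
    length(x$model$years), d[2], d[1],
    max(x$summary$rhat[seq_len(x$model$n_par)]),
    if (x$converged) "converged (R-hat < 1.1)" else "NOT converged"
  ))
  print(x$summary[seq_len(x$model$n_par), c("param", "median", "sd", "q2.5", "q97.5", "rhat")],
    row.names = FALSE, digits = 4
  )
  invisible(x)
}

#' @export
summary.lc_fit <- function(object, latents = FALSE, ...) {
  s <- object$summary
  if (!latents) s <- s[seq_len(object$model$n_par), ]
  s
}

#' @export
coef.lc_fit <- function(object, ...) {
  s <- object$summary[seq_len(object$model$n_par), ]
  stats::setNames(s$median, s$param)
}

#' @export
plot.lc_fit <- function(x, pars = NULL, ...) {
  nm <- dimnames(x$draws$draws)[[3]]
  if (is.null(pars)) pars <- nm[seq_len(min(x$model$n_par, 6L))]
  idx <- match(pars, nm)
  if (anyNA(idx)) stop("unknown parameter(s): ", paste(pars[is.na(idx)], collapse = ", "))
  old <- graphics::par(mfrow = c(length(idx), 1), mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (k in idx) {
    graphics::matplot(x$draws$draws[, , k],
      type = "l", lty = 1,
      ylab = nm[k], xlab = "", main = ""
    )
  }
  invisible(x)
}

#' Parameter sets sampled from a fitted posterior
#'
#' Draws `n` parameter vectors from the pooled post-warm-up posterior
#' and substitutes them into the baseline parameter object, giving
#' ready-to-simulate [haddock_params()] / [cod_params()] sets for the
#' hindcast engine (process innovations are resampled fresh by the
#' simulators, not reused).
#'
#' @param fit an [lc_fit()] object.
#' @param n number of parameter sets.
#' @param seed optional seed for the draw selection.
#' @return list of `n` parameter objects, with the selected draw indices
#'   as attribute `"idx"`.
#' @export
posterior_params <- function(fit, n, seed = NULL) {
  stopifnot(inherits(fit, "lc_fit"))
  if (!is.null(seed)) set.seed(seed)
  a <- fit$draws$draws
  d <- dim(a)
  flat <- matrix(a, d[1] * d[2], d[3])
  idx <- sample.int(nrow(flat), n, replace = n > nrow(flat))
  out <- lapply(idx, function(i) {
    p <- fit$model$params
    for (k in seq_len(fit$model$n_par)) {
      as_ <- fit$model$assigns[[k]]
      val <- flat[i, k]
      if (is.null(as_$ages)) {
        if (as_$param %in% c("e0", "f0")) {
          attr(p, "e0") <- val # initial log effort rides along as an attribute
        } else {
          p[[as_$param]] <- val
        }
      } else {
        p[[as_$param]][as_$ages] <- val
      }
    }
    p
  })
  attr(out, "idx") <- idx
  out
}
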