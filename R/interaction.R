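## Stage-specific interaction analyses: posterior summaries of the
## cod-on-haddock predation effect by age, and error-weighted smooth
## regressions of stage-specific log-abundance on temperature or on the
## realized cod inter-cohort interaction strength.

#' Predation-effect summary by haddock age
#'
#' For each age with a predation coefficient, summarizes the posterior
#' distribution of `g_a` multiplied by the overall (mean) cod biomass:
#' posterior mean, central 95% credibility bounds, and a sign
#' classification — `"positive"`/`"negative"` when the interval excludes
#' zero, `"not significant"` when it contains zero.
#'
#' @param draws matrix of posterior draws with one column per predation
#'   coefficient, named `g[<age>]` (as produced by [lc_fit()]), or an
#'   `lc_fit` object.
#' @param G cod biomass series (metric tons); its mean scales the
#'   coefficients.
#' @return data frame of class `effect_summary`: age, mean, lo95, hi95,
#'   classification.
#' @export
predation_summary <- function(draws, G) {
  if (inherits(draws, "lc_fit")) {
    a <- draws$draws$draws
    nm <- dimnames(a)[[3]]
    cols <- grep("^g\\[", nm)
    if (!length(cols)) stop("fit contains no sampled predation coefficients g[age]")
    draws <- do.call(cbind, lapply(cols, function(k) as.vector(a[, , k])))
    colnames(draws) <- nm[cols]
  }
  draws <- as.matrix(draws)
  if (is.null(colnames(draws))) stop("draw columns must be named g[<age>]")
  ages <- suppressWarnings(as.integer(sub("^g\\[(\\d+)\\]$", "\\1", colnames(draws))))
  if (!length(ages) || anyNA(ages)) stop("draw columns must be named g[<age>]")
  Gbar <- mean(G)
  out <- do.call(rbind, lapply(seq_along(ages), function(j) {
    eff <- draws[, j] * Gbar
    qs <- stats::quantile(eff, c(0.025, 0.975), names = FALSE)
    cls <- if (qs[1] > 0) {
      "positive"
    } else if (qs[2] < 0) {
      "negative"
    } else {
      "not significant"
    }
    data.frame(
      age = ages[j], mean = mean(eff), lo95 = qs[1], hi95 = qs[2],
      classification = cls, stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$age), ]
  rownames(out) <- NULL
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' Error-weighted smooth regression of abundance on a covariate
#'
#' Fits a penalized regression smooth (thin-plate spline, basis
#' dimension capped at `k`) of an estimated log-abundance series on a
#' covariate, weighting observations inversely to their squared standard
#' errors, the way stage-specific abundance estimates with
#' heterogeneous posterior uncertainty are regressed on temperature or
#' on the cod inter-cohort interaction term.  Reports the percentage of
#' deviance explained and the generalized cross-validation score.
#'
#' @param response estimated log-abundance by year.
#' @param se standard errors of the response (> 0); weights are
#'   proportional to `1/se^2` (normalized to mean one, so rescaling all
#'   SEs by a constant leaves the fit unchanged).
#' @param covariate covariate by year (temperature, or the realized
#'   inter-cohort mortality effect `beta_a * N_{a-1,y-1}`).
#' @param k smooth basis dimension (default 5, suited to short
#'   assessment series).
#' @param response_label,covariate_label labels carried into reports.
#' @param level pointwise confidence level of the reported band.
#' @return object of class `smooth_fit_report`: deviance percentage, GCV
#'   score, the fitted [mgcv::gam()] object, and the fitted curve with
#'   band.
#' @export
weighted_smooth <- function(response, se, covariate, k = 5,
                            response_label = "log N",
                            covariate_label = "covariate",
                            level = 0.975) {
  n <- length(response)
  if (n < 8L) stop("need at least 8 points for a penalized smooth")
  if (length(se) != n || length(covariate) != n) stop("response, se, covariate lengths differ")
  if (any(se <= 0)) stop("standard errors must be > 0")
  if (stats::var(covariate) == 0) stop("covariate has zero variance")
  w <- 1 / se^2
  w <- w / mean(w)
  df <- data.frame(y = response, x = covariate, w = w)
  fit <- mgcv::gam(y ~ s(x, k = k), data = df, weights = w, method = "GCV.Cp")
  dev_pct <- 100 * (1 - fit$deviance / fit$null.deviance)
  xs <- seq(min(covariate), max(covariate), length.out = 100)
  pr <- mgcv::predict.gam(fit, newdata = data.frame(x = xs), se.fit = TRUE)
  z <- stats::qnorm((1 + level) / 2)
  structure(
    list(
      response_label = response_label, covariate_label = covariate_label,
      deviance_percent = dev_pct, gcv = as.numeric(fit$gcv.ubre),
      n = n, k = k, fit = fit,
      curve = data.frame(
        x = xs, fit = as.numeric(pr$fit),
        lo = as.numeric(pr$fit - z * pr$se.fit),
        hi = as.numeric(pr$fit + z * pr$se.fit)
      )
    ),
    class = "smooth_fit_report"
  )
}

#' @export
print.smooth_fit_report <- function(x, ...) {
  cat(sprintf(
    "weighted smooth: %s ~ s(%s), n = %d\n  deviance explained = %.2f%%, GCV = %.4g\n",
    x$response_label, x$covariate_label, x$n, x$deviance_percent, x$gcv
  ))
  invisible(x)
}

#' Deviance table across stage-specific smooth fits
#'
#' Assembles [weighted_smooth()] reports into the standard layout: one
#' row per (response, covariate) pair with percent deviance explained
#' and the GCV score, ordered by response label then covariate.
#'
#' @param reports list of `smooth_fit_report`s.
#' @return data frame with columns response, covariate,
#'   deviance_percent, gcv.
#' @export
deviance_table <- function(reports) {
  if (!length(reports)) stop("no reports")
  df <- do.call(rbind, lapply(reports, function(r) {
    stopifnot(inherits(r, "smooth_fit_report"))
    data.frame(
      response = r$response_label, covariate = r$covariate_label,
      deviance_percent = r$deviance_percent, gcv = r$gcv,
      stringsAsFactors = FALSE
    )
  }))
  df <- df[order(df$response, df$covariate), ]
  rownames(df) <- NULL
  df
}

#' Realized inter-cohort interaction covariate
#'
#' The year-varying strength of cod cannibalism on a cohort entering age
#' `a`: `beta_a * N_{a-1, y-1}` (the increase in juvenile log-mortality
#' caused by the preceding cohort's abundance).  This is the covariate
#' regressed against haddock stage abundances.
#'
#' @param cod_sim a `cod_sim` (or the `truth$cod` entry of a dataset).
#' @param age destination age of the transition (1 to `juv_max_age`).
#' @return named vector by year (first year `NA`: no preceding cohort).
#' @export
intercohort_series <- function(cod_sim, age = 1L) {
  p <- cod_sim$params
  if (!as.character(age) %in% names(p$beta_a)) {
    stop("age ", age, " has no inter-cohort coefficient")
  }
  yrs <- colnames(cod_sim$N)
  prev <- if (age == 1L) cod_sim$N_z else cod_sim$N[as.character(age - 1L), ]
  out <- c(NA_real_, p$beta_a[[as.character(age)]] * prev[-length(prev)])
  stats::setNames(out, yrs)
}
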