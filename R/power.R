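#' Configuration for the equivalence-power simulation
#'
#' Collects every symbol of the a-priori power model
#' `cobbAngle = mu + beta * isClin + pat_effect + rater_effect + rep_effect`
#' for the balanced raters x images x repetitions design. Defaults mirror
#' a pragmatic a-priori design: grand mean 30 degrees, 16 raters
#' (6 clinicians, 10 students), 7 patient images, 3 repetitions, 500
#' simulations, 90\% confidence interval checked against the +/- 5 degree
#' equivalence band.
#'
#' @param beta clinician-minus-student difference (degrees).
#' @param pat_sd,rater_sd,rep_sd effect-size standard deviations (degrees).
#' @param mu grand mean coronal Cobb angle (degrees).
#' @param n_raters,n_clinicians,n_images,n_reps design counts
#'   (`n_clinicians <= n_raters`).
#' @param n_sims Monte-Carlo replicates.
#' @param ci_level confidence level of the equivalence interval.
#' @param equivalence_bounds closed equivalence band (degrees).
#' @param seed integer seed.
#' @return a `power_sim_config` list.
#' @export
power_sim_config <- function(beta = 1.5, pat_sd = 3, rater_sd = 1.2,
                             rep_sd = 1.2, mu = 30, n_raters = 16,
                             n_clinicians = 6, n_images = 7, n_reps = 3,
                             n_sims = 500, ci_level = 0.90,
                             equivalence_bounds = c(-5, 5), seed = 1) {
  stopifnot(pat_sd >= 0, rater_sd >= 0, rep_sd >= 0,
            ci_level > 0, ci_level < 1,
            equivalence_bounds[1] < equivalence_bounds[2],
            n_clinicians <= n_raters, n_raters >= 2, n_images >= 1,
            n_reps >= 1, n_sims >= 1)
  structure(list(beta = beta, pat_sd = pat_sd, rater_sd = rater_sd,
                 rep_sd = rep_sd, mu = mu, n_raters = n_raters,
                 n_clinicians = n_clinicians, n_images = n_images,
                 n_reps = n_reps, n_sims = n_sims, ci_level = ci_level,
                 equivalence_bounds = equivalence_bounds, seed = seed),
            class = "power_sim_config")
}

#' Empirical power of the equivalence-CI decision rule
#'
#' Simulates the full factorial design, fits
#' `cobbAngle ~ isClin + patID + repID + (1 | raterID)` by REML, computes
#' the `ci_level` confidence interval for the clinician-student coefficient
#' and counts the fraction of simulations whose interval lies inside the
#' equivalence band.
#'
#' Two reading choices are exposed. `patient_effect`: the patient effect can
#' be drawn once per image (`"per_image"`, where the fixed image factor
#' absorbs it exactly and the patient spread cannot influence the result)
#' or independently per observation (`"per_observation"`, the default,
#' which keeps the residual well defined and makes the stated patient-SD
#' range a real sensitivity axis). `ci_method`: `"profile"` (default) uses
#' the profile-likelihood interval -- what `confint()` on an `lmer` fit
#' computes by default, and the appropriate choice here because the
#' clinician-student contrast is identified from only 16 raters, so Wald
#' intervals built on the plug-in rater variance are anticonservative --
#' while `"wald"` uses the normal approximation.
#'
#' @param config a [power_sim_config()].
#' @param patient_effect `"per_observation"` (default) or `"per_image"`.
#' @param ci_method `"profile"` (default) or `"wald"`.
#' @return list with `power` (fraction in `[0, 1]`), `n_sims`,
#'   `n_nonconverged`, and the `config`. A warning reports non-convergence
#'   above 5\%.
#' @export
power_simulation <- function(config,
                             patient_effect = c("per_observation", "per_image"),
                             ci_method = c("profile", "wald")) {
  stopifnot(inherits(config, "power_sim_config"))
  patient_effect <- match.arg(patient_effect)
  ci_method <- match.arg(ci_method)
  d <- expand.grid(raterID = factor(seq_len(config$n_raters)),
                   patID = factor(seq_len(config$n_images)),
                   repID = factor(seq_len(config$n_reps)))
  d$isClin <- as.numeric(as.integer(d$raterID) <= config$n_clinicians)
  n <- nrow(d)
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  lo <- config$equivalence_bounds[1]; hi <- config$equivalence_bounds[2]
  fm <- NULL; inside <- 0L; bad <- 0L
  with_seed(config$seed, {
    for (s in seq_len(config$n_sims)) {
      rater_e <- stats::rnorm(config$n_raters, 0, config$rater_sd)[as.integer(d$raterID)]
      pat_e <- if (patient_effect == "per_image")
        stats::rnorm(config$n_images, 0, config$pat_sd)[as.integer(d$patID)]
      else stats::rnorm(n, 0, config$pat_sd)
      y <- config$mu + config$beta * d$isClin + pat_e + rater_e +
        stats::rnorm(n, 0, config$rep_sd)
      fm <- tryCatch(suppressWarnings(suppressMessages(
        if (is.null(fm))
          lme4::lmer(y ~ isClin + patID + repID + (1 | raterID), data = d,
                     REML = TRUE,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore"))
        else lme4::refit(fm, y))), error = function(e) NULL)
      if (is.null(fm)) { bad <- bad + 1L; next }
      ci <- if (ci_method == "wald") {
        est <- lme4::fixef(fm)[["isClin"]]
        se <- sqrt(as.matrix(stats::vcov(fm))["isClin", "isClin"])
        c(est - z * se, est + z * se)
      } else {
        cim <- tryCatch(suppressWarnings(suppressMessages(
          stats::confint(fm, parm = "isClin", level = config$ci_level,
                         method = "profile", quiet = TRUE))),
          error = function(e) NULL)
        if (is.null(cim)) { bad <- bad + 1L; next }
        as.numeric(cim)
      }
      if (ci[1] >= lo && ci[2] <= hi) inside <- inside + 1L
    }
  })
  if (bad > 0.05 * config$n_sims)
    warning(sprintf("non-convergence rate %.1f%% exceeds 5%%",
                    100 * bad / config$n_sims))
  list(power = inside / (config$n_sims - bad),
       n_sims = config$n_sims, n_nonconverged = bad, config = config)
}

#' Power over a grid of effect-size corners
#'
#' Runs [power_simulation()] at every combination of the supplied
#' parameter values (by default the 16 corners of the plausible effect-size
#' ranges: patient SD 3--6.7, rater SD 1.2--1.6, repetition SD 1.2--1.6
#' and clinician-student difference 1.5--3 degrees), with per-corner seeds
#' derived from the root seed.
#'
#' @param pat_sd,rater_sd,rep_sd,beta numeric vectors of corner values
#'   (degrees).
#' @param seed root integer seed.
#' @param n_sims simulations per corner (default 500).
#' @param ... further arguments to [power_sim_config()] or
#'   [power_simulation()] (`patient_effect`, `ci_method`).
#' @return data frame with one row per corner: the four parameters,
#'   `power` (\%), and `n_nonconverged`.
#' @export
power_grid <- function(pat_sd = c(3, 6.7), rater_sd = c(1.2, 1.6),
                       rep_sd = c(1.2, 1.6), beta = c(1.5, 3),
                       seed = 1, n_sims = 500, ...) {
  dots <- list(...)
  sim_args <- dots[names(dots) %in% c("patient_effect", "ci_method")]
  cfg_args <- dots[!names(dots) %in% c("patient_effect", "ci_method")]
  g <- expand.grid(pat_sd = pat_sd, rater_sd = rater_sd, rep_sd = rep_sd,
                   beta = beta)
  g$power <- NA_real_; g$n_nonconverged <- NA_integer_
  for (i in seq_len(nrow(g))) {
    cfg <- do.call(power_sim_config, c(list(
      beta = g$beta[i], pat_sd = g$pat_sd[i], rater_sd = g$rater_sd[i],
      rep_sd = g$rep_sd[i], n_sims = n_sims,
      seed = derive_seed(seed, i)), cfg_args))
    res <- do.call(power_simulation, c(list(cfg), sim_args))
    g$power[i] <- 100 * res$power
    g$n_nonconverged[i] <- res$n_nonconverged
  }
  g
}
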