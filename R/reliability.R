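#' Fit a random-intercept linear mixed-effects model to rating records
#'
#' Thin, contract-checked wrapper around [lme4::lmer()] (REML) for the
#' models used throughout the reliability analysis: a response with fixed
#' covariates and one or two crossed random intercepts. Fixed-effect
#' standard errors are Wald. When the data admit an exact linear fit (zero
#' residual variance, e.g. deterministic synthetic ratings) a mixed model
#' is not estimable; the fit then degenerates to ordinary least squares
#' with all variance components zero, which preserves the noise-free limit
#' (coefficients recovered exactly).
#'
#' @param records data frame of rating records.
#' @param response response column name.
#' @param fixed_effects character vector of fixed-effect column names (may
#'   be empty for an intercept-only mean structure).
#' @param random_intercepts character vector of grouping column names (each
#'   must have >= 2 levels).
#' @return a `spinalign_lmm` list: `coefficients` (data frame with
#'   `term`, `estimate`, `se`), `variance_components` (named, degrees^2),
#'   `residual_variance`, `log_likelihood`, `converged`, `messages`, and
#'   `model` (the underlying fit).
#' @export
fit_lmm <- function(records, response, fixed_effects = character(),
                    random_intercepts = character()) {
  stopifnot(response %in% names(records),
            all(fixed_effects %in% names(records)),
            all(random_intercepts %in% names(records)))
  if (response %in% c(fixed_effects, random_intercepts))
    stop("response must not appear among the effects", call. = FALSE)
  use <- stats::complete.cases(records[, c(response, fixed_effects,
                                           random_intercepts), drop = FALSE])
  d <- records[use, , drop = FALSE]
  for (g in random_intercepts) {
    d[[g]] <- factor(d[[g]])
    if (nlevels(d[[g]]) < 2)
      stop("random grouping '", g, "' needs >= 2 levels", call. = FALSE)
  }
  fx <- if (length(fixed_effects)) paste(fixed_effects, collapse = " + ") else "1"
  # exact-fit degenerate path: residual variance 0 breaks REML
  ols <- stats::lm(stats::reformulate(if (length(fixed_effects)) fixed_effects
                                      else "1", response), data = d)
  if (length(random_intercepts) == 0 ||
      stats::sigma(ols) < 1e-8 * max(1, stats::sd(d[[response]]))) {
    sm <- suppressWarnings(summary(ols))$coefficients
    return(structure(list(
      coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                                se = sm[, 2], row.names = NULL),
      variance_components = stats::setNames(rep(0, length(random_intercepts)),
                                            random_intercepts),
      residual_variance = stats::sigma(ols)^2,
      log_likelihood = as.numeric(stats::logLik(ols)),
      converged = TRUE, messages = "degenerate fit: ordinary least squares",
      model = ols), class = "spinalign_lmm"))
  }
  rnd <- paste(sprintf("(1 | %s)", random_intercepts), collapse = " + ")
  form <- stats::as.formula(paste(response, "~", fx, "+", rnd))
  msgs <- character()
  fm <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  conv <- length(fm@optinfo$conv$lme4) == 0
  vc <- as.data.frame(lme4::VarCorr(fm))
  vcomp <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                           vc$grp[vc$grp != "Residual"])
  se <- sqrt(diag(as.matrix(stats::vcov(fm))))
  structure(list(
    coefficients = data.frame(term = names(lme4::fixef(fm)),
                              estimate = unname(lme4::fixef(fm)),
                              se = unname(se), row.names = NULL),
    variance_components = vcomp[random_intercepts],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    log_likelihood = as.numeric(stats::logLik(fm)),
    converged = conv, messages = msgs, model = fm),
    class = "spinalign_lmm")
}

#' @exportS3Method base::print
print.spinalign_lmm <- function(x, ...) {
  cat("<spinalign_lmm>\n")
  print(x$coefficients, digits = 4)
  cat("variance components (deg^2):",
      paste(sprintf("%s=%.3g", names(x$variance_components),
                    x$variance_components), collapse = ", "),
      sprintf("residual=%.3g\n", x$residual_variance))
  invisible(x)
}

#' Equivalence decision from a fixed-effect confidence interval
#'
#' Builds the normal-approximation confidence interval
#' `estimate +/- z * se` for one coefficient (by default the
#' clinician-vs-student indicator) and declares equivalence when the
#' interval lies inside the closed equivalence band.
#'
#' @param fit a `spinalign_lmm` from [fit_lmm()].
#' @param ci_level confidence level (default 0.90).
#' @param bounds equivalence bounds in degrees (default `c(-5, 5)`).
#' @param term coefficient name (default `"is_clinician"`).
#' @return list with `equivalent` (logical), `ci` (length 2), `estimate`,
#'   `ci_level`, `bounds`.
#' @export
interclass_equivalence <- function(fit, ci_level = 0.90, bounds = c(-5, 5),
                                   term = "is_clinician") {
  stopifnot(inherits(fit, "spinalign_lmm"), ci_level > 0, ci_level < 1,
            length(bounds) == 2, bounds[1] < bounds[2])
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1)
    stop("coefficient '", term, "' not found in the fit", call. = FALSE)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- c(row$estimate - z * row$se, row$estimate + z * row$se)
  list(equivalent = ci[1] >= bounds[1] && ci[2] <= bounds[2],
       ci = ci, estimate = row$estimate, ci_level = ci_level, bounds = bounds)
}

# ICC from the crossed-model variance components
icc_from_components <- function(v_pat, v_rater, v_res) {
  (v_pat + v_rater) / (v_pat + v_rater + v_res)
}

#' Interrater ICC from the crossed patient x rater mixed model
#'
#' Fits `angle ~ is_clinician + (1 | patient_id) + (1 | rater_id)` and
#' reports the adjusted ICC over all random effects,
#' `(s2_pat + s2_rater) / (s2_pat + s2_rater + s2_res)` (the fixed rater
#' class is excluded from the denominator; set `adjusted = FALSE` to add
#' the fixed-effect variance to the denominator). The confidence interval
#' is a seeded parametric bootstrap: responses are simulated from the
#' fitted model, refitted, and the percentile interval of the ICC taken.
#' Perfect-agreement data (zero rater and residual variance) short-circuit
#' to ICC 1.
#'
#' @param records rating records with columns `angle_deg`, `is_clinician`,
#'   `patient_id`, `rater_id`; >= 2 patients and >= 2 raters.
#' @param n_boot bootstrap draws (default 500).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @param adjusted report the adjusted ICC (default) or include the
#'   fixed-effect variance in the denominator.
#' @return list with `icc`, `ci_low`, `ci_high`, `method`,
#'   `variance_components`, `fit`.
#' @export
icc_crossed <- function(records, n_boot = 500, ci_level = 0.95, seed = 1,
                        adjusted = TRUE) {
  stopifnot(length(unique(records$patient_id)) >= 2,
            length(unique(records$rater_id)) >= 2)
  fit <- fit_lmm(records, "angle_deg", "is_clinician",
                 c("patient_id", "rater_id"))
  v_pat <- fit$variance_components[["patient_id"]]
  v_rat <- fit$variance_components[["rater_id"]]
  v_res <- fit$residual_variance
  tot <- v_pat + v_rat + v_res
  if (tot < 1e-12) {
    # deterministic limit: all variation is between patients (or none);
    # perfect repeatability means ICC 1 by convention
    if (stats::sd(records$angle_deg) < 1e-10)
      stop("ICC undefined: no variance in the ratings", call. = FALSE)
    return(list(icc = 1, ci_low = 1, ci_high = 1,
                method = "crossed_random_effects",
                variance_components = c(patient = v_pat, rater = v_rat,
                                        residual = v_res), fit = fit))
  }
  denom_extra <- if (adjusted) 0 else {
    mm <- fit$coefficients
    b <- mm$estimate[mm$term == "is_clinician"]
    if (length(b)) stats::var(b * records$is_clinician) else 0
  }
  icc <- (v_pat + v_rat) / (tot + denom_extra)
  boot <- rep(NA_real_, n_boot)
  if (inherits(fit$model, "merMod")) {
    with_seed(derive_seed(seed, 77), {
      sims <- stats::simulate(fit$model, nsim = n_boot)
      for (b_i in seq_len(n_boot)) {
        bf <- tryCatch(suppressWarnings(suppressMessages(
          lme4::refit(fit$model, sims[[b_i]]))), error = function(e) NULL)
        if (is.null(bf)) next
        vc <- as.data.frame(lme4::VarCorr(bf))
        s <- stats::setNames(vc$vcov, vc$grp)
        boot[b_i] <- icc_from_components(s[["patient_id"]], s[["rater_id"]],
                                         s[["Residual"]])
      }
    })
  } else boot <- rep(icc, n_boot)
  a <- (1 - ci_level) / 2
  ci <- stats::quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(icc = unname(icc), ci_low = ci[1], ci_high = ci[2],
       method = "crossed_random_effects",
       variance_components = c(patient = v_pat, rater = v_rat, residual = v_res),
       fit = fit)
}

#' Single-rater test-retest ICC(2,1), absolute agreement
#'
#' Shrout--Fleiss ICC(2,1) from the two-way ANOVA mean squares of a
#' complete targets x repetitions matrix:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`, with the
#' F-based confidence interval of McGraw & Wong.
#'
#' @param mat numeric matrix, rows = targets (patients), columns =
#'   repetitions; complete, >= 2 rows and >= 2 columns.
#' @param ci_level confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `method`, and the mean
#'   squares `msr`, `msc`, `mse`.
#' @export
icc2_per_rater <- function(mat, ci_level = 0.95) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix has missing cells", call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 targets and >= 2 repetitions", call. = FALSE)
  gm <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((mat - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom <= 0) 0 else (msr - mse) / denom
  # McGraw & Wong F-based interval for ICC(A,1)
  alpha <- 1 - ci_level
  if (mse <= 0 && msc <= 0) {            # exact repetitions: no dispersion
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc) + .Machine$double.eps)
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc) + .Machine$double.eps)
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(max(-1, lower), min(1, upper))
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2],
       method = "icc2_single_absolute", msr = msr, msc = msc, mse = mse)
}

#' Pairwise line distance between repeated ISL drawings
#'
#' Resamples each repetition on the common height grid and, for every pair
#' of repetitions, summarizes the pointwise transverse distance
#' `sqrt(dx^2 + dz^2)` by its RMSE (`n` denominator) and SD (`n - 1`).
#'
#' @param lines list of >= 2 [polyline3d()] repetitions of one drawn line.
#' @param n_grid comparison samples (default 100).
#' @return data frame with one row per unordered pair: `rep_a`, `rep_b`,
#'   `rmse`, `sd`.
#' @export
line_repetition_stats <- function(lines, n_grid = 100) {
  if (length(lines) < 2) stop("need >= 2 repetitions", call. = FALSE)
  lo <- max(vapply(lines, function(l) min(l$y), 0))
  hi <- min(vapply(lines, function(l) max(l$y), 0))
  yg <- seq(lo, hi, length.out = n_grid)
  rs <- lapply(lines, function(l)
    cbind(interp_at(l$y, l$x, yg), interp_at(l$y, l$z, yg)))
  pairs <- utils::combn(length(lines), 2)
  out <- apply(pairs, 2, function(p) {
    d <- sqrt(rowSums((rs[[p[1]]] - rs[[p[2]]])^2))
    c(rmse = sqrt(mean(d^2)), sd = stats::sd(d))
  })
  data.frame(rep_a = pairs[1, ], rep_b = pairs[2, ],
             rmse = out["rmse", ], sd = out["sd", ])
}

#' Intrarater agreement summaries from rating records
#'
#' For every rater x patient (x curvature) cell with `k` repetitions the
#' angle-based agreement is the median of the `choose(k, 2)` pairwise
#' absolute Cobb-angle differences (for the 3-repetition design: the median
#' of 3 pairwise differences, `mad_pairwise`). Cell values are pooled as
#' median (IQR) per rater class and overall.
#'
#' @param records rating records (one curvature or several).
#' @return list with `per_cell` (data frame of rater x patient x curvature
#'   MADs) and `pooled` (data frame of median and IQR by rater class and
#'   curvature).
#' @export
intrarater_summaries <- function(records) {
  sp <- split(records,
              list(records$rater_id, records$patient_id, records$curvature),
              drop = TRUE)
  cells <- lapply(sp, function(g) {
    if (nrow(g) < 2) stop("need >= 2 repetitions per rater x patient", call. = FALSE)
    dif <- abs(as.numeric(stats::dist(g$angle_deg)))
    data.frame(rater_id = g$rater_id[1], is_clinician = g$is_clinician[1],
               patient_id = g$patient_id[1], curvature = g$curvature[1],
               mad_pairwise = stats::median(dif))
  })
  per_cell <- do.call(rbind, cells)
  rownames(per_cell) <- NULL
  pool <- function(d, label) if (nrow(d) == 0) NULL else data.frame(
    group = label, curvature = sort(unique(d$curvature)),
    median_mad = vapply(split(d$mad_pairwise, d$curvature), stats::median, 0),
    iqr_mad = vapply(split(d$mad_pairwise, d$curvature), iqr_of, 0),
    row.names = NULL)
  pooled <- rbind(
    pool(per_cell[per_cell$is_clinician == 1, ], "clinicians"),
    pool(per_cell[per_cell$is_clinician == 0, ], "students"),
    pool(per_cell, "all"))
  list(per_cell = per_cell, pooled = pooled)
}

#' Pearson validation correlation with Fisher-z confidence interval
#'
#' Correlates two paired angle series (e.g. centerline-derived Cobb angles
#' against an external manual reference), with the 95\% CI from the Fisher
#' z-transform, plus the median difference (IQR) of `a - b`.
#'
#' @param angles_a,angles_b paired numeric vectors, `n >= 4`, finite.
#' @param ci_level confidence level (default 0.95).
#' @return list with `pcc`, `ci_low`, `ci_high`, `median_diff`, `iqr_diff`,
#'   `n`.
#' @export
validation_correlation <- function(angles_a, angles_b, ci_level = 0.95) {
  stopifnot(length(angles_a) == length(angles_b), length(angles_a) >= 4)
  stop_if_not_finite(c(angles_a, angles_b), "angles")
  if (stats::sd(angles_a) < 1e-12 || stats::sd(angles_b) < 1e-12)
    stop("zero variance: correlation undefined", call. = FALSE)
  n <- length(angles_a)
  r <- stats::cor(angles_a, angles_b)
  z <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r)))
  hz <- stats::qnorm(1 - (1 - ci_level) / 2) / sqrt(n - 3)
  d <- angles_a - angles_b
  list(pcc = r, ci_low = tanh(z - hz), ci_high = tanh(z + hz),
       median_diff = stats::median(d), iqr_diff = iqr_of(d), n = n)
}

#' Normal Q-Q points and reference line for angle errors
#'
#' Sample order statistics against standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`, with the least-squares Q-Q line and the
#' correlation of the Q-Q points (a numeric normality diagnostic).
#'
#' @param errors numeric vector, `n >= 10`.
#' @return list with `theoretical`, `sample`, `slope`, `intercept`,
#'   `correlation`.
#' @export
qq_points <- function(errors) {
  stopifnot(length(errors) >= 10)
  stop_if_not_finite(errors, "errors")
  n <- length(errors)
  th <- stats::qnorm((seq_len(n) - 0.5) / n)
  sm <- sort(errors)
  fit <- stats::lm(sm ~ th)
  list(theoretical = th, sample = sm,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = stats::cor(th, sm))
}
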