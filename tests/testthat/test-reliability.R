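make_sim_records <- function(n_pat = 7, n_raters = 16, n_clin = 6, n_rep = 3,
                             pat_sd = 6, rater_sd = 1.5, res_sd = 2,
                             beta = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(patient_id = sprintf("P%d", seq_len(n_pat)),
                   rater_id = sprintf("R%02d", seq_len(n_raters)),
                   repetition = seq_len(n_rep))
  d$is_clinician <- as.integer(as.integer(factor(d$rater_id)) <= n_clin)
  pat_e <- rnorm(n_pat, 0, pat_sd)
  rat_e <- rnorm(n_raters, 0, rater_sd)
  d$angle_deg <- 30 + beta * d$is_clinician +
    pat_e[as.integer(factor(d$patient_id))] +
    rat_e[as.integer(factor(d$rater_id))] + rnorm(nrow(d), 0, res_sd)
  d$curvature <- "coronal"
  d
}

test_that("deterministic data give exact coefficients and zero variances", {
  d <- make_sim_records(pat_sd = 0, rater_sd = 0, res_sd = 0, beta = 2)
  fit <- fit_lmm(d, "angle_deg", "is_clinician", "rater_id")
  b <- fit$coefficients
  expect_equal(b$estimate[b$term == "is_clinician"], 2, tolerance = 1e-10)
  expect_equal(unname(fit$variance_components), 0)
  expect_equal(fit$residual_variance, 0, tolerance = 1e-12)
})

test_that("REML variance components match closed-form balanced one-way ANOVA", {
  # 4 raters x 5 observations; expected components from mean squares:
  # sigma2_between = (MSB - MSW) / n, sigma2_within = MSW
  set.seed(9)
  d <- data.frame(rater_id = rep(sprintf("R%d", 1:4), each = 5))
  d$angle_deg <- 30 + rep(rnorm(4, 0, 3), each = 5) + rnorm(20, 0, 1)
  g_mean <- mean(d$angle_deg)
  means <- tapply(d$angle_deg, d$rater_id, mean)
  msb <- 5 * sum((means - g_mean)^2) / 3
  msw <- sum((d$angle_deg - means[d$rater_id])^2) / 16
  fit <- fit_lmm(d, "angle_deg", character(), "rater_id")
  expect_equal(unname(fit$variance_components["rater_id"]),
               max(0, (msb - msw) / 5), tolerance = 1e-6)
  expect_equal(fit$residual_variance, msw, tolerance = 1e-6)
})

test_that("the fixed-effect estimate is unbiased over repeated simulation", {
  ests <- vapply(1:100, function(s) {
    d <- make_sim_records(n_pat = 4, n_raters = 8, n_clin = 4, n_rep = 2,
                          pat_sd = 0, rater_sd = 1.5, res_sd = 1.5,
                          beta = 1.5, seed = 100 + s)
    fit <- fit_lmm(d, "angle_deg", "is_clinician", "rater_id")
    fit$coefficients$estimate[fit$coefficients$term == "is_clinician"]
  }, 0)
  # Monte-Carlo error of the mean at 100 draws
  se_mc <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1.5), 4 * se_mc)
})

test_that("equivalence is decided by CI inclusion with a closed boundary", {
  fake <- structure(list(coefficients = data.frame(
    term = "is_clinician", estimate = -0.15,
    se = (1.9 + 2.2) / 2 / qnorm(0.95))), class = "spinalign_lmm")
  # CI ~ [-2.2, 1.9] inside [-5, 5]
  eq <- interclass_equivalence(fake)
  expect_true(eq$equivalent)
  expect_equal(eq$ci, c(-2.2, 1.9), tolerance = 1e-10)
  fake2 <- structure(list(coefficients = data.frame(
    term = "is_clinician", estimate = -2.5, se = 3.5 / qnorm(0.95))),
    class = "spinalign_lmm")
  expect_false(interclass_equivalence(fake2)$equivalent)  # CI [-6, 1]
  fake3 <- structure(list(coefficients = data.frame(
    term = "is_clinician", estimate = 0, se = 5 / qnorm(0.95))),
    class = "spinalign_lmm")
  expect_true(interclass_equivalence(fake3)$equivalent)   # exactly [-5, 5]
})

test_that("crossed ICC approaches its structural limits", {
  # patient-only structure: ICC near 1
  d <- make_sim_records(pat_sd = 6, rater_sd = 0, res_sd = 0.01, seed = 3)
  r <- icc_crossed(d, n_boot = 50, seed = 3)
  expect_gt(r$icc, 0.99)
  # pure noise: ICC near 0
  d0 <- make_sim_records(pat_sd = 0, rater_sd = 0, res_sd = 2, seed = 4)
  r0 <- icc_crossed(d0, n_boot = 50, seed = 4)
  expect_lt(r0$icc, 0.15)
})

test_that("crossed ICC recovers the generating variance ratio", {
  # sigma_pat 6, sigma_rater 1.5, sigma_eps 2 -> ICC = 38.25/42.25 = 0.905
  d <- make_sim_records(seed = 7)
  r <- icc_crossed(d, n_boot = 200, seed = 7)
  expect_gt(r$ci_high, 38.25 / 42.25 - 0.25)
  expect_lt(r$ci_low, 38.25 / 42.25)
  expect_equal(r$icc, 38.25 / 42.25, tolerance = 0.12)
})

test_that("ICC(2,1) matches a hand ANOVA decomposition", {
  mat <- matrix(c(9, 10, 11,
                  14, 15, 17,
                  20, 22, 21,
                  30, 28, 29), 4, 3, byrow = TRUE)
  n <- 4; k <- 3
  gm <- mean(mat)
  msr <- k * sum((rowMeans(mat) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(mat) - gm)^2) / (k - 1)
  mse <- (sum((mat - gm)^2) - (n - 1) * msr - (k - 1) * msc) /
    ((n - 1) * (k - 1))
  expected <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  r <- icc2_per_rater(mat)
  expect_equal(r$icc, expected, tolerance = 1e-10)
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
})

test_that("ICC(2,1) limits: identical columns give 1, heavy noise gives ~0", {
  base <- c(10, 15, 20, 30, 40, 25, 18)
  expect_equal(icc2_per_rater(cbind(base, base, base))$icc, 1)
  set.seed(11)
  noise_icc <- vapply(c(1, 10, 100), function(s)
    icc2_per_rater(cbind(base + rnorm(7, 0, s), base + rnorm(7, 0, s),
                         base + rnorm(7, 0, s)))$icc, 0)
  expect_true(all(diff(noise_icc) < 0))
  expect_lt(noise_icc[3], 0.2)
  expect_error(icc2_per_rater(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("intrarater pairwise summaries match hand computations", {
  rec <- data.frame(patient_id = "P1", rater_id = "R01", is_clinician = 1,
                    repetition = 1:3, curvature = "coronal",
                    angle_deg = c(30, 34, 32), reference_deg = 31,
                    presentation_order = 1:3)
  s <- intrarater_summaries(rec)
  expect_equal(s$per_cell$mad_pairwise, 2)  # pairwise diffs {4, 2, 2}
  # three parallel line repetitions offset 0/1/2 mm: pairwise RMSE {1,1,2}
  y <- seq(0, 100, length.out = 20)
  lines <- lapply(c(0, 1, 2), function(o)
    polyline3d(y * 0 + o, y, y * 0, label = "ISL"))
  lr <- line_repetition_stats(lines)
  expect_equal(sort(lr$rmse), c(1, 1, 2), tolerance = 1e-10)
  expect_equal(median(lr$rmse), 1)
  expect_equal(lr$sd, rep(0, 3), tolerance = 1e-10)
})

test_that("validation correlation matches definitional arithmetic", {
  expect_equal(validation_correlation(1:10, 2 * (1:10) + 1)$pcc, 1)
  expect_equal(validation_correlation(1:10, -(1:10))$pcc, -1)
  r <- validation_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$pcc, 0.6, tolerance = 1e-12)
  # CI agrees with the textbook Fisher-z interval (cor.test oracle)
  set.seed(2)
  a <- rnorm(30); b <- a + rnorm(30)
  ct <- cor.test(a, b)
  v <- validation_correlation(a, b)
  expect_equal(c(v$ci_low, v$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-6)
  expect_error(validation_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("Q-Q points are calibrated for normal input", {
  p <- (seq_len(50) - 0.5) / 50
  exact <- qnorm(p)
  q <- qq_points(exact)
  expect_equal(q$slope, 1, tolerance = 1e-6)
  expect_equal(q$intercept, 0, tolerance = 1e-6)
  set.seed(6)
  qn <- qq_points(rnorm(336))
  expect_gt(qn$correlation, 0.99)
  # heavy tails reduce the Q-Q correlation below the normal case
  qt2 <- qq_points(rt(336, df = 2))
  expect_lt(qt2$correlation, qn$correlation)
})
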