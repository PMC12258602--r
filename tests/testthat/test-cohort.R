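test_that("biplanar projection drops one axis per view and round-trips", {
  m <- spine_model()
  mk <- make_markers(m)
  pr <- project_biplanar(markers = mk)
  expect_equal(pr$frontal$x, mk$x)
  expect_equal(pr$frontal$y, mk$y)
  expect_equal(pr$lateral$z, mk$z)
  expect_true(all(pr$frontal$label == pr$lateral$label))
  # noiseless reconstruction recovers the markers exactly
  for (i in seq_len(nrow(mk))) {
    rec <- reconstruct_marker_3d(c(pr$frontal$x[i], pr$frontal$y[i]),
                                 c(pr$lateral$z[i], pr$lateral$y[i]))
    expect_equal(rec$point, c(mk$x[i], mk$y[i], mk$z[i]))
  }
  expect_error(project_biplanar(markers = NULL), "non-empty")
})

test_that("reconstruction error under view jitter is bounded per axis", {
  set.seed(5)
  m <- spine_model()
  mk <- make_markers(m)
  pr <- project_biplanar(markers = mk)
  jit <- function(v) v + runif(length(v), -1, 1)
  fx <- jit(pr$frontal$x); fy <- jit(pr$frontal$y)
  lz <- jit(pr$lateral$z); ly <- jit(pr$lateral$y)
  for (i in seq_len(nrow(mk))) {
    rec <- reconstruct_marker_3d(c(fx[i], fy[i]), c(lz[i], ly[i]))$point
    expect_lte(abs(rec[1] - mk$x[i]), 1 + 1e-12)
    expect_lte(abs(rec[2] - mk$y[i]), 1 + 1e-12)  # mean of two <= 1 mm errors
    expect_lte(abs(rec[3] - mk$z[i]), 1 + 1e-12)
  }
})

test_that("posture perturbation is the identity at zero and bows as stated", {
  m <- spine_model()
  crv <- sample_curves(m, 120)
  same <- perturb_posture(crv, 0, 0)
  expect_equal(as.matrix(same$ISL[, 1:3]), as.matrix(crv$ISL[, 1:3]),
               tolerance = 1e-10)
  # quadratic bow: closed-form RMSE c * sqrt(8/15) against the unperturbed
  bowed <- perturb_posture(crv$outline, 0, 5)
  yg <- seq(5, 445, length.out = 200)
  ae <- alignment_error(lateral_outline(bowed, yg),
                        lateral_outline(crv$outline, yg))
  expect_equal(ae$rmse, 5 * sqrt(8 / 15), tolerance = 0.05)
  expect_error(perturb_posture(crv, 35, 0), "lean out of range")
})

test_that("posture alignment error grows monotonically with lean", {
  m <- spine_model()
  outl <- sample_curves(m, 150)$outline
  yg <- seq(10, 440, length.out = 150)
  ref <- lateral_outline(outl, yg)
  rmse <- vapply(c(0, 1, 2, 4), function(lean) {
    p <- perturb_posture(outl, lean, 0)
    yg2 <- seq(max(min(p$y), 10), min(max(p$y), 440), length.out = 150)
    alignment_error(lateral_outline(p, yg2), ref)$rmse
  }, 0)
  expect_true(all(diff(rmse) > 0))
})

test_that("the rater simulation produces the full factorial of records", {
  cfg <- cohort_config(seed = 3)
  spines <- generate_cohort(cfg)
  prof <- make_rater_profiles(seed = 3)
  rec <- simulate_raters(cfg, spines, prof, curvatures = "coronal")
  expect_equal(nrow(rec), 7 * 16 * 3)            # 336 coronal records
  expect_equal(length(unique(rec$rater_id)), 16)
  expect_equal(sum(rec$is_clinician == 1) / 3 / 7, 6)
  # 21 presented image sets per rater session, each order a permutation
  one <- rec[rec$rater_id == rec$rater_id[1], ]
  expect_equal(nrow(one), 21)
  expect_setequal(one$presentation_order, 1:21)
  # reference angles equal the generator ground truth
  refs <- vapply(spines, implied_cobb, 0)
  names(refs) <- vapply(spines, function(s) s$patient_id, "")
  expect_equal(unname(refs[rec$patient_id]), rec$reference_deg)
})

test_that("record counts scale with the design for any configuration", {
  cfg <- cohort_config(n_patients = 3,
                       severity_counts = c(normal = 1, mild = 1,
                                           moderate = 1, severe = 0),
                       n_clinicians = 2, n_students = 3, n_repetitions = 2,
                       seed = 8)
  spines <- generate_cohort(cfg)
  prof <- make_rater_profiles(2, 3, seed = 8)
  rec <- simulate_raters(cfg, spines, prof,
                         curvatures = c("coronal", "kyphotic"))
  expect_equal(nrow(rec), 3 * 5 * 2 * 2)
  expect_equal(sum(rec$curvature == "coronal"), 3 * 5 * 2)
})

test_that("the cohort is reproducible from its seed", {
  cfg <- cohort_config(seed = 42)
  r1 <- simulate_raters(cfg, generate_cohort(cfg),
                        make_rater_profiles(seed = 42))
  r2 <- simulate_raters(cfg, generate_cohort(cfg),
                        make_rater_profiles(seed = 42))
  expect_identical(r1, r2)
  cfg2 <- cohort_config(seed = 43)
  r3 <- simulate_raters(cfg2, generate_cohort(cfg),
                        make_rater_profiles(seed = 42))
  expect_false(isTRUE(all.equal(r1$angle_deg, r3$angle_deg)))
  expect_equal(r1$reference_deg[order(r1$patient_id, r1$rater_id, r1$repetition)],
               r3$reference_deg[order(r3$patient_id, r3$rater_id, r3$repetition)])
})

test_that("noise-free raters reproduce the reference angles exactly", {
  cfg <- cohort_config(n_patients = 2,
                       severity_counts = c(normal = 1, mild = 1,
                                           moderate = 0, severe = 0),
                       n_clinicians = 1, n_students = 1, n_repetitions = 2,
                       seed = 2)
  spines <- generate_cohort(cfg)
  prof <- make_rater_profiles(1, 1, bias_sd = 0, annotation_noise_sd = 0,
                              seed = 2)
  rec <- simulate_raters(cfg, spines, prof, n_control_points = 25)
  expect_equal(rec$angle_deg, rec$reference_deg, tolerance = 0.02)
})

test_that("coronal SPL-ISL correlation is perfect without rotation coupling", {
  for (seed in 1:4) {
    m <- generate_spine(sample(c("mild", "moderate", "severe"), 1),
                        seed = seed, axial_rotation_gain = 0)
    crv <- sample_curves(m, 100)
    expect_equal(line_correlation(crv$SPL, crv$ISL, "coronal"), 1,
                 tolerance = 1e-9)
  }
})

test_that("polyline and record CSV round-trips preserve the data", {
  m <- generate_spine("mild", seed = 4)
  crv <- sample_curves(m, 40)
  f <- tempfile(fileext = ".csv")
  write_polyline_csv(list(ISL = crv$ISL, SPL = crv$SPL), f)
  back <- read_polyline_csv(f)
  expect_equal(back$ISL$x, crv$ISL$x, tolerance = 1e-9)
  expect_equal(back$SPL$z, crv$SPL$z, tolerance = 1e-9)
  cfg <- cohort_config(seed = 6)
  rec <- simulate_raters(cfg, generate_cohort(cfg), make_rater_profiles(seed = 6))
  f2 <- tempfile(fileext = ".csv")
  write_records_csv(rec, f2)
  rec2 <- read_records_csv(f2)
  expect_equal(rec2$angle_deg, rec$angle_deg, tolerance = 1e-9)
  expect_equal(rec2$patient_id, rec$patient_id)
  unlink(c(f, f2))
})
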