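test_that("smoothing reproduces a straight line and respects the y range", {
  l <- make_line3d(30)
  sm <- smooth_line(l)
  expect_equal(sm$x, 0.1 * sm$y + 2, tolerance = 1e-6)
  expect_equal(sm$z, -0.05 * sm$y - 1, tolerance = 1e-6)
  expect_equal(range(sm$y), range(l$y))
  expect_error(smooth_line(polyline3d(1:3, 1:3, 1:3)), ">= 4")
})

test_that("smoothing suppresses annotation jitter below the raw noise level", {
  set.seed(2)
  y <- seq(0, 300, length.out = 50)
  truth <- 15 * sin(2 * pi * y / 300)
  noisy <- polyline3d(truth + rnorm(50), y, rep(0, 50))
  sm <- smooth_line(noisy, n_out = 50)
  rmse <- sqrt(mean((sm$x - 15 * sin(2 * pi * sm$y / 300))^2))
  expect_lt(rmse, 1)
})

test_that("coronal Cobb equals the central angle of sampled arcs", {
  for (a in c(5, 10, 20, 40, 60, 80))
    expect_equal(cobb_coronal(make_arc(a))$angle, a, tolerance = 0.2)
  # straight vertical line
  y <- seq(0, 400, length.out = 50)
  expect_equal(cobb_coronal(plane_curve(rep(0, 50), y, "coronal"))$angle, 0,
               tolerance = 1e-8)
})

test_that("coronal Cobb of the sinusoid matches the closed form", {
  expect_equal(cobb_coronal(make_sinusoid(15, 300))$angle,
               2 * atan(2 * pi * 15 / 300) * 180 / pi, tolerance = 0.1)
  # endpoint levels sit at the tangent-angle extrema (inflections)
  cc <- cobb_coronal(make_sinusoid(15, 300))
  off <- abs(cc$endpoint_levels - round(cc$endpoint_levels / 150) * 150)
  expect_lt(max(off), 2)
})

test_that("sagittal angles recover arc central angles at the level span", {
  m <- spine_model(kyphosis_angle = 35, lordosis_angle = 45)
  sag <- project_plane(sample_curves(m, 300)$ISL, "sagittal")
  ang <- sagittal_angles(sag, spine_levels(m))
  expect_equal(ang$kyphotic, 35, tolerance = 0.5)
  expect_equal(ang$lordotic, 45, tolerance = 0.5)
  # straight line
  flat <- plane_curve(rep(1, 60), seq(0, 450, length.out = 60), "sagittal")
  ang0 <- sagittal_angles(flat, spine_levels(m))
  expect_equal(ang0$kyphotic, 0, tolerance = 1e-8)
  expect_equal(ang0$lordotic, 0, tolerance = 1e-8)
  expect_error(sagittal_angles(flat, c(T1 = 500, T12 = 150, L1 = 150,
                                       L5_lower = 0)), "outside")
})

test_that("lateral outline recovers curves and surfaces", {
  m <- spine_model()
  outl <- sample_curves(m, 120)$outline
  yg <- seq(10, 440, length.out = 60)
  pc <- lateral_outline(outl, yg)
  expect_equal(pc$u, spinalign:::interp_at(outl$y, outl$z, yg))
  # extruded surface: lateral sweep of the outline profile
  surf <- do.call(rbind, lapply(seq(-80, 80, by = 8), function(dx)
    cbind(outl$x + dx, outl$y, outl$z)))
  pc2 <- lateral_outline(surf, yg)
  expect_equal(pc2$u, pc$u, tolerance = 1)
  # 10% missing height band is interpolated without error
  surf_gap <- surf[surf[, 2] < 200 | surf[, 2] > 245, ]
  expect_silent(lateral_outline(surf_gap, yg))
  # > 20% empty bins is an error
  surf_big_gap <- surf[surf[, 2] < 150 | surf[, 2] > 320, ]
  expect_error(lateral_outline(surf_big_gap, yg), "empty")
})

test_that("alignment error matches closed forms for simple offsets", {
  y <- seq(0, 400, length.out = 200)
  base <- plane_curve(10 * sin(y / 60), y, "sagittal")
  expect_equal(alignment_error(base, base)$rmse, 0)
  shifted <- plane_curve(base$u + 5, y, "sagittal")
  ae <- alignment_error(shifted, base)
  expect_equal(ae$rmse, 5, tolerance = 1e-10)
  expect_equal(ae$sd, 0, tolerance = 1e-10)
  ramp <- plane_curve(base$u + seq(0, 10, length.out = 200), y, "sagittal")
  ae <- alignment_error(ramp, base)
  expect_equal(ae$rmse, sqrt(25 + 100 / 12), tolerance = 0.02)
  expect_equal(ae$sd, sqrt(100 / 12), tolerance = 0.02)
})

test_that("alignment error is symmetric and shift-invariant along y", {
  set.seed(8)
  y <- seq(0, 400, length.out = 150)
  a <- plane_curve(10 * sin(y / 50) + rnorm(150), y, "sagittal")
  b <- plane_curve(10 * sin(y / 50) + rnorm(150), y, "sagittal")
  e1 <- alignment_error(a, b); e2 <- alignment_error(b, a)
  expect_equal(e1$rmse, e2$rmse)
  expect_equal(e1$sd, e2$sd)
  a2 <- plane_curve(a$u, y + 37, "sagittal")
  b2 <- plane_curve(b$u, y + 37, "sagittal")
  e3 <- alignment_error(a2, b2)
  expect_equal(e3$rmse, e1$rmse, tolerance = 1e-10)
  expect_error(alignment_error(a, plane_curve(b$u, y + 380, "sagittal")),
               "overlap")
})

test_that("line correlation handles identity, mirror and zero variance", {
  m <- generate_spine("moderate", seed = 1)
  isl <- sample_curves(m, 100)$ISL
  for (pl in c("coronal", "sagittal")) {
    expect_equal(line_correlation(isl, isl, pl, procrustes = FALSE), 1)
    expect_equal(line_correlation(isl, isl, pl, procrustes = TRUE), 1,
                 tolerance = 1e-9)
  }
  mirror <- polyline3d(-isl$x, isl$y, isl$z)
  expect_equal(line_correlation(isl, mirror, "coronal"), -1)
  straight <- polyline3d(rep(0, 100), isl$y, rep(0, 100))
  expect_error(line_correlation(straight, isl, "coronal"), "zero variance")
})

test_that("Pearson option is invariant to affine rescaling of a coordinate", {
  m <- generate_spine("moderate", seed = 6)
  crv <- sample_curves(m, 90)
  r0 <- line_correlation(crv$SPL, crv$ISL, "coronal")
  scaled <- polyline3d(3.2 * crv$ISL$x + 14, crv$ISL$y, crv$ISL$z)
  expect_equal(line_correlation(crv$SPL, scaled, "coronal"), r0,
               tolerance = 1e-12)
})

test_that("Procrustes correlation is invariant to rigid pre-transforms", {
  m <- generate_spine("moderate", seed = 2)
  crv <- sample_curves(m, 120)
  r0 <- line_correlation(crv$SPL, crv$ISL, "coronal", procrustes = TRUE)
  set.seed(3)
  for (rep in 1:5) {
    tf <- rigid_transform(
      spinalign:::rotation_about(1, runif(1, -20, 20)) %*%
        spinalign:::rotation_about(2, runif(1, -20, 20)) %*%
        spinalign:::rotation_about(3, runif(1, -20, 20)),
      rnorm(3, sd = 40))
    moved <- apply_transform(crv$ISL, tf)
    expect_equal(line_correlation(crv$SPL, moved, "coronal", procrustes = TRUE),
                 r0, tolerance = 1e-6)
  }
})
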