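#' Parametric single-curve scoliotic spine model
#'
#' Ground truth for one synthetic patient. The coronal deviation of the
#' internal spinal line (ISL) is a single-period sinusoid of amplitude
#' `coronal_amplitude` and wavelength `coronal_wavelength`, which gives the
#' implied coronal Cobb angle the closed form
#' `2 * atan(2 * pi * A / lambda)` (the tangent-angle difference between
#' consecutive inflections of the sinusoid). The sagittal profile is built
#' from two tangent circular arcs (thoracic kyphosis, lumbar lordosis) so
#' that the tangent-angle difference across each arc equals the model's
#' kyphosis/lordosis angle exactly. Axial vertebral rotation is coupled
#' linearly to lateral deviation, `phi(y) = axial_rotation_gain * x_ISL(y)`,
#' and displaces the spinous-process line (SPL) laterally.
#'
#' @param patient_id identifier string.
#' @param coronal_amplitude sinusoid amplitude A (mm).
#' @param coronal_wavelength sinusoid wavelength lambda (mm), > 0.
#' @param apex_height craniocaudal position of the curve apex (mm above the
#'   L5 lower endplate).
#' @param kyphosis_angle thoracic kyphosis (degrees, T1--T12 tangent-angle
#'   difference).
#' @param lordosis_angle lumbar lordosis (degrees, L1--L5 tangent-angle
#'   difference; L5 lower endplate, not S1).
#' @param axial_rotation_gain axial rotation per mm of lateral deviation
#'   (degrees/mm).
#' @param spinous_offset posterior distance from vertebral-body centroid to
#'   spinous-process tip (mm), > 0.
#' @param soft_tissue_thickness distance from the ISL to the back surface
#'   (mm), >= 0.
#' @param spine_length C7 to L5 lower endplate (mm), > 0.
#' @return a `spine_model` list; see [implied_cobb()] and [sample_curves()].
#' @export
spine_model <- function(patient_id = "P1",
                        coronal_amplitude = 10,
                        coronal_wavelength = 300,
                        apex_height = 250,
                        kyphosis_angle = 35,
                        lordosis_angle = 45,
                        axial_rotation_gain = 0.5,
                        spinous_offset = 40,
                        soft_tissue_thickness = 60,
                        spine_length = 450) {
  stopifnot(spine_length > 0, coronal_wavelength > 0, spinous_offset > 0,
            soft_tissue_thickness >= 0, coronal_amplitude >= 0,
            kyphosis_angle >= 0, lordosis_angle >= 0)
  m <- list(patient_id = patient_id,
            coronal_amplitude = coronal_amplitude,
            coronal_wavelength = coronal_wavelength,
            apex_height = apex_height,
            kyphosis_angle = kyphosis_angle,
            lordosis_angle = lordosis_angle,
            axial_rotation_gain = axial_rotation_gain,
            spinous_offset = spinous_offset,
            soft_tissue_thickness = soft_tissue_thickness,
            spine_length = spine_length)
  class(m) <- "spine_model"
  cobb <- implied_cobb(m)
  if (cobb < 0 || cobb > 90)
    stop("implied coronal Cobb angle out of [0, 90] degrees", call. = FALSE)
  m
}

#' @exportS3Method base::print
print.spine_model <- function(x, ...) {
  cat(sprintf(
    "<spine_model %s> Cobb %.1f deg (A=%.1f mm, lambda=%.0f mm), kyphosis %.1f, lordosis %.1f deg\n",
    x$patient_id, implied_cobb(x), x$coronal_amplitude, x$coronal_wavelength,
    x$kyphosis_angle, x$lordosis_angle))
  invisible(x)
}

#' Closed-form coronal Cobb angle of a spine model
#'
#' For the single-period sinusoid `x(y) = A sin(2 pi (y - y0) / lambda)` the
#' tangent inclination extrema are `+/- atan(2 pi A / lambda)` at consecutive
#' inflections, so the Cobb angle (maximum tangent-angle difference between
#' consecutive most-tilted levels) is `2 atan(2 pi A / lambda)`.
#'
#' @param model a [spine_model()].
#' @return Cobb angle in degrees.
#' @export
implied_cobb <- function(model) {
  rad2deg(2 * atan(2 * pi * model$coronal_amplitude / model$coronal_wavelength))
}

#' Sinusoid amplitude realizing a target Cobb angle
#'
#' Inverts the closed form: `A = lambda / (2 pi) * tan(cobb / 2)`.
#'
#' @param cobb_deg target coronal Cobb angle (degrees, in `[0, 90)`).
#' @param wavelength sinusoid wavelength (mm).
#' @return amplitude in mm.
#' @export
amplitude_for_cobb <- function(cobb_deg, wavelength) {
  stopifnot(cobb_deg >= 0, cobb_deg < 180)
  wavelength / (2 * pi) * tan(deg2rad(cobb_deg) / 2)
}

# Severity bands in degrees: half-open intervals matching clinical
# "less than" phrasing; "severe" is 45 deg or greater.
severity_bands <- function() {
  list(normal   = c(0, 10),
       mild     = c(10, 25),
       moderate = c(25, 45),
       severe   = c(45, 60))
}

#' Draw a random spine model of a given scoliosis severity
#'
#' The target coronal Cobb angle is drawn uniformly inside the severity band
#' (normal `[0, 10)`, mild `[10, 25)`, moderate `[25, 45)`, severe
#' `[45, 60]` degrees; band edges avoided by a 5\% margin so sampled curves
#' stay inside their band after smoothing) and converted to the sinusoid
#' amplitude via [amplitude_for_cobb()]. Sagittal angles and anthropometry
#' are drawn from ranges typical of adolescent patients.
#'
#' @param severity `"normal"`, `"mild"`, `"moderate"` or `"severe"`.
#' @param seed integer seed.
#' @param patient_id identifier.
#' @param axial_rotation_gain degrees of axial rotation per mm of lateral
#'   deviation (default 0.5).
#' @return a [spine_model()].
#' @export
generate_spine <- function(severity, seed = 1, patient_id = severity,
                           axial_rotation_gain = 0.5) {
  bands <- severity_bands()
  if (!severity %in% names(bands))
    stop("unknown severity label: ", severity, call. = FALSE)
  band <- bands[[severity]]
  with_seed(seed, {
    margin <- 0.05 * diff(band)
    cobb <- stats::runif(1, band[1] + margin, band[2] - margin)
    wavelength <- stats::runif(1, 260, 340)
    spine_length <- stats::runif(1, 420, 480)
    spine_model(
      patient_id = patient_id,
      coronal_amplitude = amplitude_for_cobb(cobb, wavelength),
      coronal_wavelength = wavelength,
      apex_height = stats::runif(1, 0.50, 0.60) * spine_length,
      kyphosis_angle = stats::runif(1, 25, 45),
      lordosis_angle = stats::runif(1, 35, 55),
      axial_rotation_gain = axial_rotation_gain,
      spinous_offset = stats::runif(1, 35, 45),
      soft_tissue_thickness = stats::runif(1, 50, 70),
      spine_length = spine_length)
  })
}

#' Vertebral level heights of a spine model
#'
#' Fixed anatomical fractions of the C7--L5 length: the lumbar spine
#' (L1 upper to L5 lower endplate) occupies the caudal third, the thoracic
#' spine (T1--T12) most of the remainder. These ground-truth levels feed
#' [sagittal_angles()] in synthetic mode; with real data they come from a
#' labeled landmark file.
#'
#' @param model a [spine_model()].
#' @return named numeric vector of y positions (mm): `L5_lower`, `L1`,
#'   `T12`, `T7`, `T3`, `T1`, `C7`.
#' @export
spine_levels <- function(model) {
  L <- model$spine_length
  c(L5_lower = 0, L1 = 0.33 * L, T12 = 0.33 * L, T7 = 0.60 * L,
    T3 = 0.80 * L, T1 = 0.88 * L, C7 = L)
}

# Sagittal antero-posterior profile z(y) built from two tangent circular
# arcs: a lordotic arc over [L5_lower, L1] with central angle
# lordosis_angle and a kyphotic arc over [T12, T1] with central angle
# kyphosis_angle, joined with tangent continuity (vertical tangent at the
# thoracolumbar junction); straight continuation elsewhere. Because the
# tangent-angle change across a circular arc equals its central angle, the
# model's sagittal angles are recovered exactly by tangent-angle
# differencing at the level heights.
sagittal_profile <- function(model, y) {
  lv <- spine_levels(model)
  kappa <- deg2rad(model$kyphosis_angle)
  ell <- deg2rad(model$lordosis_angle)
  y_j <- lv[["T12"]]                       # junction, vertical tangent
  # kyphotic arc above the junction: tangent angle t in [0, kappa],
  # y = y_j + Rk sin t, z = z_j + Rk (1 - cos t)
  Rk <- if (kappa > 0) (lv[["T1"]] - y_j) / sin(kappa) else Inf
  # lordotic arc below the junction curves anteriorly:
  # y = y_j - Rl sin t, z = z_j - Rl (1 - cos t), t in [0, ell]
  Rl <- if (ell > 0) (y_j - lv[["L5_lower"]]) / sin(ell) else Inf
  z <- numeric(length(y))
  for (i in seq_along(y)) {
    yi <- y[i]
    if (yi >= y_j) {
      yy <- min(yi, lv[["T1"]])
      t <- if (is.finite(Rk)) asin(pmin(1, (yy - y_j) / Rk)) else 0
      zi <- if (is.finite(Rk)) Rk * (1 - cos(t)) else 0
      if (yi > lv[["T1"]]) zi <- zi + (yi - lv[["T1"]]) * tan(kappa)
    } else {
      yy <- max(yi, lv[["L5_lower"]])
      t <- if (is.finite(Rl)) asin(pmin(1, (y_j - yy) / Rl)) else 0
      zi <- if (is.finite(Rl)) -Rl * (1 - cos(t)) else 0
      if (yi < lv[["L5_lower"]]) zi <- zi - (lv[["L5_lower"]] - yi) * tan(ell)
    }
    z[i] <- zi
  }
  z
}

#' Sample the ground-truth curves of a spine model
#'
#' Evaluates the ISL, SPL and back-surface lateral outline on a uniform
#' craniocaudal grid. The ISL lateral coordinate is the coronal sinusoid;
#' its antero-posterior coordinate is the two-arc sagittal profile. The SPL
#' is the ISL displaced posteriorly by `spinous_offset` and laterally by
#' `-spinous_offset * sin(phi(y))`, where `phi(y) = axial_rotation_gain *
#' x_ISL(y)` (degrees) is the axial vertebral rotation; with zero gain the
#' SPL is a pure posterior translation of the ISL. The outline is the ISL
#' displaced posteriorly by `soft_tissue_thickness`.
#'
#' @param model a [spine_model()].
#' @param n_samples number of samples (>= 10).
#' @return a list with elements `ISL`, `SPL`, `outline`, each a
#'   [polyline3d()].
#' @export
sample_curves <- function(model, n_samples = 200) {
  if (n_samples < 10) stop("n_samples must be >= 10", call. = FALSE)
  y <- seq(0, model$spine_length, length.out = n_samples)
  y0 <- model$apex_height - model$coronal_wavelength / 4
  x_isl <- model$coronal_amplitude *
    sin(2 * pi * (y - y0) / model$coronal_wavelength)
  z_isl <- sagittal_profile(model, y)
  phi <- deg2rad(model$axial_rotation_gain * x_isl)
  list(
    ISL = polyline3d(x_isl, y, z_isl, "ISL"),
    SPL = polyline3d(x_isl - model$spinous_offset * sin(phi), y,
                     z_isl + model$spinous_offset, "SPL"),
    outline = polyline3d(x_isl, y, z_isl + model$soft_tissue_thickness,
                         "outline"))
}

#' Radiopaque skin-marker positions for a spine model
#'
#' Places markers on the back surface at named vertebral levels
#' (default C7, T3, T7, T12 and the L5 region), emulating the 5 mm
#' radiopaque spherical skin markers used for scan-to-radiograph
#' registration.
#'
#' @param model a [spine_model()].
#' @param levels character vector of level names from [spine_levels()].
#' @return a [polyline3d()] with label `"markers"` and a `level` attribute.
#' @export
make_markers <- function(model, levels = c("L5_lower", "T12", "T7", "T3", "C7")) {
  lv <- spine_levels(model)
  stopifnot(all(levels %in% names(lv)))
  y <- unname(lv[levels])
  crv <- sample_curves(model, 200)$outline
  m <- polyline3d(interp_at(crv$y, crv$x, y), y, interp_at(crv$y, crv$z, y),
                  label = "markers")
  attr(m, "level") <- levels
  m
}
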