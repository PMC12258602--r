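#' Smooth a drawn centerline with a smoothing spline
#'
#' Fits one cubic smoothing spline per transverse coordinate (`x` and `z`)
#' as a function of the craniocaudal coordinate `y` and resamples the fit on
#' a uniform `y` grid spanning the input range. The smoothing parameter is
#' chosen by generalized cross-validation unless given explicitly, which
#' suppresses hand-annotation jitter while reproducing straight segments
#' exactly (a line lies in the null space of the roughness penalty).
#'
#' @param raw a [polyline3d()] with >= 4 points and strictly increasing `y`.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects by GCV.
#' @param n_out number of output samples (default 100).
#' @return a smoothed, uniformly resampled [polyline3d()].
#' @export
smooth_line <- function(raw, spar = NULL, n_out = 100) {
  if (!inherits(raw, "polyline3d")) stop("raw must be a polyline3d", call. = FALSE)
  if (nrow(raw) < 4) stop("smooth_line needs >= 4 points", call. = FALSE)
  if (any(diff(raw$y) <= 0)) stop("non-monotone y in input line", call. = FALSE)
  yg <- seq(min(raw$y), max(raw$y), length.out = n_out)
  fit1 <- function(u) {
    f <- if (is.null(spar)) stats::smooth.spline(raw$y, u, cv = FALSE)
         else stats::smooth.spline(raw$y, u, spar = spar)
    stats::predict(f, yg)$y
  }
  polyline3d(fit1(raw$x), yg, fit1(raw$z), label = attr(raw, "label"))
}

# Tangent inclination theta(y) = atan(du/dy) in degrees, evaluated on a
# dense grid through an interpolating cubic spline of the (already
# smoothed) plane curve; derivative is the spline's analytic derivative.
tangent_angles <- function(curve, n_dense = 512) {
  f <- stats::splinefun(curve$y, curve$u, method = "fmm")
  yg <- seq(min(curve$y), max(curve$y), length.out = n_dense)
  list(y = yg, theta = rad2deg(atan(f(yg, deriv = 1))))
}

# Local extrema of the tangent-angle sequence (endpoints included), pruned
# so that alternating wiggles with tangent-angle prominence below `tol_deg`
# are merged into their surrounding monotone run.
tangent_extrema <- function(theta, tol_deg = 0.5) {
  n <- length(theta)
  d <- diff(theta)
  idx <- c(1L, which(d[-1] * d[-(n - 1)] < 0) + 1L, n)
  idx <- unique(idx)
  repeat {
    if (length(idx) <= 2) break
    gaps <- abs(diff(theta[idx]))
    k <- which.min(gaps)
    if (gaps[k] >= tol_deg) break
    # drop the interior endpoint(s) of the weakest swing
    drop <- intersect(c(k, k + 1), 2:(length(idx) - 1))
    if (!length(drop)) break
    idx <- idx[-drop[1]]
  }
  idx
}

#' Coronal Cobb angle from a smoothed plane curve
#'
#' Follows the Cobb principle on a continuous centerline: the tangent
#' inclination `theta(y) = atan(du/dy)` is evaluated along the curve, its
#' consecutive local extrema play the role of the most tilted vertebral
#' endplates, and the Cobb angle is the largest absolute tangent-angle
#' difference between consecutive extrema. For a circular arc this equals
#' the central angle; for the generator's single-period sinusoid it equals
#' the closed form `2 atan(2 pi A / lambda)`.
#'
#' @param curve a coronal [plane_curve()] with >= 10 samples.
#' @param prominence_deg extrema below this tangent-angle prominence are
#'   treated as noise (degrees, default 0.5).
#' @return list with `angle` (degrees), `endpoint_levels` (the two `y`
#'   positions, mm) and `theta_range` (degrees).
#' @export
cobb_coronal <- function(curve, prominence_deg = 0.5) {
  if (!inherits(curve, "plane_curve")) stop("curve must be a plane_curve", call. = FALSE)
  if (attr(curve, "plane") != "coronal")
    stop("cobb_coronal expects a coronal-plane curve", call. = FALSE)
  if (nrow(curve) < 10)
    stop("curve too short for derivative estimation (need >= 10 samples)", call. = FALSE)
  ta <- tangent_angles(curve)
  idx <- tangent_extrema(ta$theta, prominence_deg)
  diffs <- abs(diff(ta$theta[idx]))
  k <- which.max(diffs)
  list(angle = diffs[k],
       endpoint_levels = c(ta$y[idx[k]], ta$y[idx[k + 1]]),
       theta_range = range(ta$theta))
}

#' Kyphotic and lordotic angles at fixed vertebral levels
#'
#' Tangent-angle differences of a sagittal curve between named level
#' heights: kyphotic `|theta(T1) - theta(T12)|` and lordotic
#' `|theta(L1) - theta(L5_lower)|` (the lumbar angle is taken to the lower
#' endplate of L5, the caudal end of a drawn centerline, not S1).
#'
#' @param curve a sagittal [plane_curve()].
#' @param levels named numeric vector of `y` positions (mm) containing
#'   `T1`, `T12`, `L1`, `L5_lower`; e.g. from [spine_levels()].
#' @return list with `kyphotic` and `lordotic` (degrees).
#' @export
sagittal_angles <- function(curve, levels) {
  if (attr(curve, "plane") != "sagittal")
    stop("sagittal_angles expects a sagittal-plane curve", call. = FALSE)
  need <- c("T1", "T12", "L1", "L5_lower")
  if (!all(need %in% names(levels)))
    stop("levels must name T1, T12, L1, L5_lower", call. = FALSE)
  yr <- range(curve$y)
  if (any(levels[need] < yr[1] - 1e-9 | levels[need] > yr[2] + 1e-9))
    stop("vertebral level outside the curve's y range", call. = FALSE)
  f <- stats::splinefun(curve$y, curve$u, method = "fmm")
  th <- function(y) rad2deg(atan(f(y, deriv = 1)))
  list(kyphotic = abs(th(levels[["T1"]]) - th(levels[["T12"]])),
       lordotic = abs(th(levels[["L1"]]) - th(levels[["L5_lower"]])))
}

#' Lateral (side-view) outline of the back shape
#'
#' For an outline polyline, resamples its antero-posterior coordinate on the
#' requested height grid. For a back-surface point cloud (an n x 3 matrix),
#' bins points by height and takes the most posterior `z` per bin; empty
#' bins are interpolated from neighbors, and more than 20\% empty bins is an
#' error.
#'
#' @param surface_or_curve a [polyline3d()] or an n x 3 point matrix
#'   (columns x, y, z in mm).
#' @param y_grid strictly increasing vector of heights (mm) spanned by the
#'   input.
#' @return a sagittal [plane_curve()] on `y_grid`.
#' @export
lateral_outline <- function(surface_or_curve, y_grid) {
  stopifnot(length(y_grid) >= 2, all(diff(y_grid) > 0))
  if (inherits(surface_or_curve, "polyline3d")) {
    l <- surface_or_curve
    if (min(y_grid) < min(l$y) - 1e-9 || max(y_grid) > max(l$y) + 1e-9)
      stop("y_grid extends beyond the curve", call. = FALSE)
    return(plane_curve(interp_at(l$y, l$z, y_grid), y_grid, "sagittal"))
  }
  p <- as.matrix(surface_or_curve)
  stopifnot(ncol(p) == 3)
  half <- diff(y_grid[1:2]) / 2
  z <- vapply(y_grid, function(yg) {
    sel <- p[, 2] >= yg - half & p[, 2] < yg + half
    if (!any(sel)) NA_real_ else max(p[sel, 3])
  }, 0)
  n_empty <- sum(is.na(z))
  if (n_empty > 0.2 * length(z))
    stop(sprintf("%d of %d height bins empty (> 20%%)", n_empty, length(z)),
         call. = FALSE)
  if (n_empty > 0) {
    ok <- !is.na(z)
    z <- interp_at(y_grid[ok], z[ok], y_grid)
  }
  plane_curve(z, y_grid, "sagittal")
}

#' Posture-alignment error between two lateral outlines
#'
#' Both outlines are resampled on the common overlapping height grid; the
#' pointwise antero-posterior differences `d(y) = z_scan - z_xray` summarize
#' how well the standing posture was replicated between the radiographic
#' and the surface-scan acquisitions. `rmse` uses the `n` denominator,
#' `sd` the sample (`n - 1`) denominator, so
#' `rmse^2 = mean(d)^2 + sd^2 (n - 1) / n`.
#'
#' @param outline_scan,outline_xray sagittal [plane_curve()] objects with
#'   overlapping `y` ranges (overlap must cover at least half of the
#'   shorter outline).
#' @param n_grid number of comparison samples (default: the larger of the
#'   two input counts).
#' @return list with `rmse` (mm), `sd` (mm), `n_samples`.
#' @export
alignment_error <- function(outline_scan, outline_xray,
                            n_grid = max(nrow(outline_scan), nrow(outline_xray))) {
  lo <- max(min(outline_scan$y), min(outline_xray$y))
  hi <- min(max(outline_scan$y), max(outline_xray$y))
  shorter <- min(diff(range(outline_scan$y)), diff(range(outline_xray$y)))
  if (hi - lo < 0.5 * shorter)
    stop("outline y overlap is less than 50% of the shorter outline", call. = FALSE)
  yg <- seq(lo, hi, length.out = n_grid)
  d <- interp_at(outline_scan$y, outline_scan$u, yg) -
       interp_at(outline_xray$y, outline_xray$u, yg)
  list(rmse = sqrt(mean(d^2)), sd = stats::sd(d), n_samples = n_grid)
}

#' Pearson correlation between SPL and ISL in one plane
#'
#' Two conventions mirror the two software options. Option 1
#' (`procrustes = FALSE`): both curves are resampled on the common
#' craniocaudal grid between their shared levels and the Pearson
#' correlation of the transverse coordinates (lateral `x` for coronal,
#' antero-posterior `z` for sagittal) is computed directly. Option 2
#' (`procrustes = TRUE`): both curves are resampled at points equally
#' spaced in arc length (index correspondence that rigid motions preserve
#' exactly), the ISL is superposed onto the SPL by [procrustes_rigid()]
#' (rotation + translation, no scaling), and the correlation is computed on
#' the aligned coordinates, making the result independent of global pose.
#'
#' @param spl,isl [polyline3d()] curves.
#' @param plane `"coronal"` or `"sagittal"`.
#' @param procrustes logical; apply the rigid Procrustes superposition
#'   first (Option 2).
#' @param n_grid number of comparison samples (default 100).
#' @return Pearson correlation coefficient.
#' @export
line_correlation <- function(spl, isl, plane = c("coronal", "sagittal"),
                             procrustes = FALSE, n_grid = 100) {
  plane <- match.arg(plane)
  col <- if (plane == "coronal") 1L else 3L
  if (procrustes) {
    a <- resample_arclength(spl, n_grid)
    b <- resample_arclength(isl, n_grid)
    reg <- rigid_register(b, a)
    b <- b %*% t(reg$transform$rotation) +
      matrix(reg$transform$translation, n_grid, 3, byrow = TRUE)
    u <- a[, col]; v <- b[, col]
  } else {
    lo <- max(min(spl$y), min(isl$y)); hi <- min(max(spl$y), max(isl$y))
    if (hi <= lo) stop("curves share no y range", call. = FALSE)
    yg <- seq(lo, hi, length.out = n_grid)
    pick <- function(l) if (plane == "coronal") interp_at(l$y, l$x, yg)
                        else interp_at(l$y, l$z, yg)
    u <- pick(spl); v <- pick(isl)
  }
  if (stats::sd(u) < 1e-12 || stats::sd(v) < 1e-12)
    stop("undefined correlation: zero variance in a transverse coordinate",
         call. = FALSE)
  stats::cor(u, v)
}
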