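# Shared in-code fixtures; nothing is read from disk.

rotation_about <- spinalign:::rotation_about

# circular arc of given central angle (degrees) in a plane, sampled densely;
# tangent-angle difference across the arc equals the central angle
make_arc <- function(angle_deg, n = 250, radius = 300, plane = "coronal") {
  th <- seq(0, angle_deg * pi / 180, length.out = n)
  plane_curve(radius * (1 - cos(th)), radius * sin(th), plane)
}

# single-period sinusoid curve x(y) = A sin(2 pi y / lambda)
make_sinusoid <- function(amplitude, wavelength, n = 250) {
  y <- seq(0, wavelength, length.out = n)
  plane_curve(amplitude * sin(2 * pi * y / wavelength), y, "coronal")
}

# straight 3D line as a polyline
make_line3d <- function(n = 50, slope_x = 0.1, slope_z = -0.05, label = "ISL") {
  y <- seq(0, 400, length.out = n)
  polyline3d(slope_x * y + 2, y, slope_z * y - 1, label = label)
}

# brute-force rigid registration oracle: direct numerical minimization of
# the least-squares objective over axis-angle + translation parameters
oracle_register_objective <- function(source, target, extra_starts = list()) {
  obj <- function(par) {
    ax <- par[1:3]; t <- par[4:6]
    th <- sqrt(sum(ax^2))
    r <- if (th < 1e-12) diag(3) else {
      k <- ax / th
      kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
    }
    sum((source %*% t(r) + matrix(t, nrow(source), 3, byrow = TRUE) - target)^2)
  }
  best <- Inf
  for (start in c(list(rep(0, 6), c(0.5, -0.3, 0.2, 0, 0, 0),
                       c(-1, 1, 0.5, 10, -5, 3)), extra_starts)) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# angle (degrees) between two rotation matrices
rotation_angle_between <- function(r1, r2) {
  tr <- sum(diag(crossprod(r1, r2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}
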