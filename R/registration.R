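#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric (mm).
#' @return a `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1), no reflection", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @exportS3Method base::print
print.rigid_transform <- function(x, ...) {
  ang <- rad2deg(acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))))
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points or a polyline
#'
#' Computes `R p + t` for every point. When applied to a [polyline3d()] the
#' result is re-sorted by `y` so the craniocaudal-monotone invariant holds.
#'
#' @param points an n x 3 matrix or a [polyline3d()].
#' @param transform a [rigid_transform()].
#' @return object of the same kind as `points`.
#' @export
apply_transform <- function(points, transform) {
  is_line <- inherits(points, "polyline3d")
  lab <- if (is_line) attr(points, "label") else NULL
  p <- as_matrix3(points)
  q <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (!is_line) return(q)
  if (lab != "markers") q <- q[order(q[, 2]), , drop = FALSE]
  polyline3d(q[, 1], q[, 2], q[, 3], label = lab)
}

#' Reconstruct a 3D marker from its biplanar projections
#'
#' Under the parallel-projection biplanar geometry the frontal view records
#' `(x, y)` and the lateral view `(z, y)`. The 3D position is assembled from
#' the frontal `x`, the lateral `z` and the mean of the two `y` readings;
#' the absolute `y` disagreement is reported as a correspondence diagnostic.
#'
#' @param frontal numeric `(x, y)` mm.
#' @param lateral numeric `(z, y)` mm.
#' @param max_y_discrepancy reject threshold on `|y_frontal - y_lateral|`
#'   (mm, default 10).
#' @return list with `point` (x, y, z) and `y_discrepancy` (mm).
#' @export
reconstruct_marker_3d <- function(frontal, lateral, max_y_discrepancy = 10) {
  stopifnot(length(frontal) == 2, length(lateral) == 2)
  stop_if_not_finite(c(frontal, lateral), "marker projections")
  dy <- abs(frontal[2] - lateral[2])
  if (dy > max_y_discrepancy)
    stop(sprintf("marker correspondence error: |dy| = %.1f mm exceeds %.1f mm",
                 dy, max_y_discrepancy), call. = FALSE)
  list(point = c(frontal[1], mean(c(frontal[2], lateral[2])), lateral[1]),
       y_discrepancy = dy)
}

#' Least-squares rigid registration of paired 3D point sets (Kabsch/SVD)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum || R s_i + t - d_i ||^2` over paired points: centroids are removed,
#' the cross-covariance is decomposed by SVD, and the reflection branch is
#' corrected by flipping the sign of the smallest singular vector whenever
#' the determinant of the candidate rotation is negative.
#'
#' @param source,target n x 3 matrices (or [polyline3d()]) of paired points,
#'   n >= 3, not collinear.
#' @return list with `transform` (a [rigid_transform()]) and `rmse` (mm).
#' @export
rigid_register <- function(source, target) {
  s <- as_matrix3(source); d <- as_matrix3(target)
  if (!all(dim(s) == dim(d))) stop("point sets must be paired", call. = FALSE)
  if (nrow(s) < 3) stop("degenerate geometry: need >= 3 paired points", call. = FALSE)
  stop_if_not_finite(c(s, d), "registration points")
  sc <- colMeans(s); dc <- colMeans(d)
  s0 <- sweep(s, 2, sc); d0 <- sweep(d, 2, dc)
  sv_src <- svd(s0)$d
  if (sv_src[2] < 1e-8 * max(sv_src[1], 1))
    stop("degenerate geometry: source points are collinear", call. = FALSE)
  h <- crossprod(s0, d0)
  sv <- svd(h)
  flip <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  r <- sv$v %*% flip %*% t(sv$u)
  t <- dc - as.numeric(r %*% sc)
  res <- d - (s %*% t(r) + matrix(t, nrow(s), 3, byrow = TRUE))
  list(transform = rigid_transform(r, t),
       rmse = sqrt(mean(rowSums(res^2))))
}

#' Procrustes superposition restricted to rotation and translation
#'
#' Rigidly aligns a moving polyline onto a fixed one by least squares
#' (same SVD machinery as [rigid_register()]); no scaling is applied, so
#' curve size is preserved and only global pose is removed. Points must be
#' in index correspondence (equal counts), e.g. after common-grid or
#' arc-length resampling.
#'
#' @param moving,fixed [polyline3d()] (or n x 3 matrices) with equal point
#'   counts.
#' @return the aligned moving line, with attributes `transform` and `rmsd`
#'   (mm, post-alignment root-mean-square point distance).
#' @export
procrustes_rigid <- function(moving, fixed) {
  m <- as_matrix3(moving); f <- as_matrix3(fixed)
  if (nrow(m) != nrow(f))
    stop("procrustes_rigid needs equal sample counts; resample first", call. = FALSE)
  if (max(apply(m, 2, stats::sd)) < 1e-12)
    stop("degenerate input: all moving points coincide", call. = FALSE)
  reg <- rigid_register(m, f)
  out <- apply_transform(moving, reg$transform)
  attr(out, "transform") <- reg$transform
  attr(out, "rmsd") <- reg$rmse
  out
}

# rotation about one coordinate axis; axis 1 = lateral x, 2 = craniocaudal y,
# 3 = antero-posterior z; angle in degrees
rotation_about <- function(axis, angle_deg) {
  a <- deg2rad(angle_deg); c_ <- cos(a); s_ <- sin(a)
  r <- diag(3)
  ix <- setdiff(1:3, axis)
  r[ix, ix] <- matrix(c(c_, s_, -s_, c_), 2, 2)
  r
}
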