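#' Ordered 3D polyline with a craniocaudal parameter
#'
#' The shared container for sampled spinal curves: the internal spinal line
#' (ISL, through vertebral-body centroids), the spinous-process line (SPL),
#' back-surface outlines and marker sets. Coordinates are millimetres in a
#' fixed convention: `x` lateral (coronal transverse), `y` craniocaudal
#' (increasing towards the head), `z` antero-posterior (increasing towards
#' the back surface).
#'
#' @param x,y,z numeric coordinate vectors of equal length (mm).
#' @param label curve label, one of `"ISL"`, `"SPL"`, `"outline"`, `"markers"`.
#' @return a `polyline3d`: a data frame with columns `x`, `y`, `z` and a
#'   `label` attribute. `y` must be strictly increasing except for
#'   `"markers"`, which are an unordered landmark set.
#' @export
polyline3d <- function(x, y, z, label = "ISL") {
  label <- match.arg(label, c("ISL", "SPL", "outline", "markers"))
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (length(y) < 2) stop("polyline3d needs at least 2 points", call. = FALSE)
  stop_if_not_finite(c(x, y, z), "polyline3d")
  if (label != "markers" && any(diff(y) <= 0))
    stop("polyline3d y coordinates must be strictly increasing (craniocaudal)",
         call. = FALSE)
  out <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  attr(out, "label") <- label
  class(out) <- c("polyline3d", "data.frame")
  out
}

#' @exportS3Method base::print
print.polyline3d <- function(x, ...) {
  cat(sprintf("<polyline3d '%s'> %d points, y in [%.1f, %.1f] mm\n",
              attr(x, "label"), nrow(x), min(x$y), max(x$y)))
  invisible(x)
}

as_matrix3 <- function(line) {
  if (inherits(line, "polyline3d")) as.matrix(line[, c("x", "y", "z")])
  else as.matrix(line)
}

#' In-plane view of a curve
#'
#' @param u transverse coordinate (mm): lateral `x` for the coronal plane,
#'   antero-posterior `z` for the sagittal plane.
#' @param y craniocaudal coordinate (mm), strictly increasing.
#' @param plane `"coronal"` or `"sagittal"`.
#' @return a `plane_curve` data frame with columns `u`, `y`.
#' @export
plane_curve <- function(u, y, plane = c("coronal", "sagittal")) {
  plane <- match.arg(plane)
  stopifnot(length(u) == length(y))
  stop_if_not_finite(c(u, y), "plane_curve")
  if (any(diff(y) <= 0)) stop("plane_curve y must be strictly increasing",
                              call. = FALSE)
  out <- data.frame(u = as.numeric(u), y = as.numeric(y))
  attr(out, "plane") <- plane
  class(out) <- c("plane_curve", "data.frame")
  out
}

#' Project a 3D polyline into an anatomical plane
#'
#' @param line a [polyline3d()].
#' @param plane `"coronal"` (keeps `x`) or `"sagittal"` (keeps `z`).
#' @return a [plane_curve()].
#' @export
project_plane <- function(line, plane = c("coronal", "sagittal")) {
  plane <- match.arg(plane)
  u <- if (plane == "coronal") line$x else line$z
  plane_curve(u, line$y, plane)
}

#' Resample a polyline on a uniform craniocaudal grid
#'
#' @param line a [polyline3d()].
#' @param n number of output samples.
#' @param y_range optional `c(min, max)` restriction; defaults to the line's
#'   own range.
#' @return a [polyline3d()] with `n` points.
#' @export
resample_polyline <- function(line, n, y_range = range(line$y)) {
  yg <- seq(y_range[1], y_range[2], length.out = n)
  polyline3d(interp_at(line$y, line$x, yg), yg, interp_at(line$y, line$z, yg),
             label = attr(line, "label"))
}

# Resample a polyline at n points equally spaced in cumulative 3D arc length.
# Arc-length parameterization is preserved exactly by rigid transforms, which
# makes index correspondence between two rigidly related curves exact.
resample_arclength <- function(line, n) {
  p <- as_matrix3(line)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  if (s[length(s)] <= 0) stop("degenerate polyline: zero arc length", call. = FALSE)
  sg <- seq(0, s[length(s)], length.out = n)
  cbind(interp_at(s, p[, 1], sg), interp_at(s, p[, 2], sg), interp_at(s, p[, 3], sg))
}

#' Write / read polylines as CSV
#'
#' The on-disk format has columns `label,point_index,x_mm,y_mm,z_mm`; several
#' curves may share one file.
#'
#' @param lines a named list of [polyline3d()] objects (`write_polyline_csv`).
#' @param path file path.
#' @return `read_polyline_csv` returns a named list of [polyline3d()].
#' @export
write_polyline_csv <- function(lines, path) {
  if (inherits(lines, "polyline3d")) lines <- stats::setNames(list(lines), attr(lines, "label"))
  rows <- do.call(rbind, lapply(names(lines), function(nm) {
    l <- lines[[nm]]
    data.frame(label = nm, point_index = seq_len(nrow(l)) - 1L,
               x_mm = l$x, y_mm = l$y, z_mm = l$z)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_polyline_csv
#' @export
read_polyline_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "point_index", "x_mm", "y_mm", "z_mm") %in% names(d)))
  out <- lapply(split(d, d$label), function(g) {
    g <- g[order(g$point_index), ]
    lab <- g$label[1]
    if (!lab %in% c("ISL", "SPL", "outline", "markers")) lab <- "ISL"
    polyline3d(g$x_mm, g$y_mm, g$z_mm, label = lab)
  })
  out
}
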