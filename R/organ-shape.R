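#' Discretized median line of a plant organ
#'
#' An `organ_shape` represents the planar median line of an organ of length
#' `L` on an arc-length grid running from the base (`s = 0`) to the apex
#' (`s = L`). The local orientation `angle` is measured in radians from the
#' upward vertical (the direction opposing gravity), positive toward the
#' half-plane containing the light source; the local `curvature` is its
#' spatial derivative along the arc length.
#'
#' Exactly one of `angle` or `curvature` may be omitted: the missing field is
#' reconstructed from the other ([curvature_to_angles()] with `base_angle`,
#' or [angles_to_curvature()]), so the two fields are always mutually
#' consistent to discretization accuracy.
#'
#' @param s Numeric vector of arc-length positions, strictly increasing from
#'   0 to the organ length `L`.
#' @param angle Local orientation at each grid node (radians from vertical),
#'   or `NULL` to integrate it from `curvature`.
#' @param curvature Local curvature at each grid node (1/length), or `NULL`
#'   to differentiate it from `angle`.
#' @param base_angle Orientation at the base, used when integrating
#'   `curvature`; defaults to `angle[1]` when `angle` is supplied.
#' @return An object of class `organ_shape`: a list with elements `s`,
#'   `angle`, `curvature` and `L`.
#' @examples
#' sh <- organ_shape(seq(0, 1, length.out = 201),
#'                   curvature = rep(-0.5, 201), base_angle = 0.5)
#' sh$angle[201]  # 0.5 - 0.5 * 1
#' @export
organ_shape <- function(s, angle = NULL, curvature = NULL, base_angle = NULL) {
  check_grid(s)
  if (is.null(angle) && is.null(curvature)) {
    stop("supply at least one of `angle` or `curvature`")
  }
  if (is.null(angle)) {
    if (is.null(base_angle)) base_angle <- 0
    angle <- curvature_to_angles(curvature, base_angle, s)
  } else {
    stopifnot(length(angle) == length(s))
    if (is.null(curvature)) curvature <- angles_to_curvature(angle, s)
  }
  stopifnot(length(curvature) == length(s))
  out <- structure(
    list(s = as.numeric(s), angle = as.numeric(angle),
         curvature = as.numeric(curvature), L = s[length(s)]),
    class = "organ_shape")
  validate_organ_shape(out)
  out
}

check_grid <- function(s) {
  if (length(s) < 2 || anyNA(s) || any(diff(s) <= 0)) {
    stop("arc-length grid must be strictly increasing with at least 2 nodes")
  }
  if (abs(s[1]) > 1e-12 * s[length(s)]) {
    stop("arc-length grid must start at the organ base, s = 0")
  }
  invisible(s)
}

#' @param shape An `organ_shape`.
#' @param tol Relative tolerance for the angle/curvature consistency check.
#' @rdname organ_shape
#' @export
validate_organ_shape <- function(shape, tol = NULL) {
  stopifnot(inherits(shape, "organ_shape"))
  check_grid(shape$s)
  n <- length(shape$s)
  if (length(shape$angle) != n || length(shape$curvature) != n) {
    stop("angle and curvature must have one value per grid node")
  }
  # curvature must be the arc-length derivative of the angle (Eq. 3 at the
  # discretization level); checked in derivative form so it is exact for any
  # shape whose curvature was computed from its angle field, noisy or not
  if (is.null(tol)) {
    scale <- max(abs(shape$curvature), abs(shape$angle) / shape$L)
    # first-order one-sided differences at the ends contribute ~ h/2 |C'|
    h <- max(diff(shape$s))
    slope_c <- if (n >= 3) max(abs(diff(shape$curvature) / diff(shape$s)))
               else 0
    tol <- 1e-6 + 0.02 * scale + 0.75 * h * slope_c
  }
  err <- max(abs(angles_to_curvature(shape$angle, shape$s) - shape$curvature))
  if (err > tol) {
    stop("angle and curvature fields are inconsistent: ",
         "d(angle)/ds does not match the curvature profile")
  }
  invisible(shape)
}

#' @export
print.organ_shape <- function(x, ...) {
  cat(sprintf(
    "<organ_shape> %d nodes, L = %g; base angle %.4f rad, tip angle %.4f rad\n",
    length(x$s), x$L, x$angle[1], x$angle[length(x$angle)]))
  invisible(x)
}

#' Integrate a curvature profile into an angle profile
#'
#' Cumulative trapezoid integration of the curvature along the arc length,
#' offset by the basal orientation: `A(s) = A(0) + integral_0^s C(l) dl`.
#'
#' @param curvature Curvature at each grid node (1/length).
#' @param base_angle Orientation at the base (radians).
#' @param s Strictly increasing arc-length grid starting at 0.
#' @return Angle profile (radians), same length as `s`.
#' @export
curvature_to_angles <- function(curvature, base_angle, s) {
  check_grid(s)
  stopifnot(length(curvature) == length(s), is.finite(base_angle))
  base_angle + as.vector(pracma::cumtrapz(s, curvature))
}

#' Differentiate an angle profile into a curvature profile
#'
#' Second-order finite differences (central in the interior, one-sided at the
#' ends) of the local orientation with respect to arc length.
#'
#' @inheritParams curvature_to_angles
#' @param angle Angle profile (radians).
#' @return Curvature profile (1/length).
#' @export
angles_to_curvature <- function(angle, s) {
  check_grid(s)
  if (length(s) < 3) {
    stop("at least 3 grid nodes are needed to differentiate the angle profile")
  }
  stopifnot(length(angle) == length(s))
  pracma::gradient(angle, s)
}

#' Planar coordinates of the median line
#'
#' Maps an [organ_shape()] to `(x, y)` coordinates with the base at the
#' origin, `y` pointing up (against gravity) and `x` toward the light
#' half-plane: `x(s) = integral sin A dl`, `y(s) = integral cos A dl`.
#' Each grid interval is laid down as a straight segment of its exact arc
#' length in the direction of the interval's midpoint angle, so the polyline
#' path length equals `L` to round-off while the node positions remain
#' second-order accurate.
#'
#' @param shape An `organ_shape`.
#' @return A data frame with columns `s`, `x`, `y`.
#' @export
midline_xy <- function(shape) {
  validate_organ_shape(shape)
  h <- diff(shape$s)
  n <- length(shape$s)
  mid <- (shape$angle[-n] + shape$angle[-1]) / 2
  x <- c(0, cumsum(h * sin(mid)))
  y <- c(0, cumsum(h * cos(mid)))
  data.frame(s = shape$s, x = x, y = y)
}

#' Reconstruct an organ shape from digitized midline points
#'
#' Takes an ordered base-to-apex sequence of planar points, resamples it to a
#' uniform arc-length grid, and recovers the angle field from the segment
#' directions (measured from the upward vertical) and the curvature field by
#' finite differences.
#'
#' @param points A two-column matrix or data frame of `(x, y)` coordinates,
#'   ordered from base to apex, with at least 3 points.
#' @param n_nodes Number of nodes of the output grid; defaults to the number
#'   of input points.
#' @return An [organ_shape()].
#' @export
xy_to_shape <- function(points, n_nodes = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2) {
    pts <- as.matrix(points[, c("x", "y")])
  }
  if (nrow(pts) < 3) stop("at least 3 ordered points are required")
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) {
    stop("degenerate segment: duplicate consecutive points in the midline")
  }
  # segment angles from vertical, unwrapped to a continuous profile
  a_seg <- atan2(d[, 1], d[, 2])
  if (length(a_seg) > 1) {
    jump <- c(0, round(diff(a_seg) / (2 * pi)))
    a_seg <- a_seg - 2 * pi * cumsum(jump)
  }
  s_cum <- c(0, cumsum(len))
  L <- s_cum[length(s_cum)]
  s_mid <- (s_cum[-length(s_cum)] + s_cum[-1]) / 2
  if (is.null(n_nodes)) n_nodes <- nrow(pts)
  s_out <- seq(0, L, length.out = n_nodes)
  # linear interpolation of the segment-midpoint angles, linear extrapolation
  # over the half-segments at either end
  a_out <- approx_extrap(s_mid, a_seg, s_out)
  organ_shape(s_out, angle = a_out)
}

# linear interpolation with two-point linear extrapolation at both ends
approx_extrap <- function(x, y, xout) {
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  if (n >= 2) {
    lo <- xout < x[1]
    hi <- xout > x[n]
    if (any(lo)) {
      sl <- (y[2] - y[1]) / (x[2] - x[1])
      out[lo] <- y[1] + sl * (xout[lo] - x[1])
    }
    if (any(hi)) {
      sl <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
      out[hi] <- y[n] + sl * (xout[hi] - x[n])
    }
  }
  out
}
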