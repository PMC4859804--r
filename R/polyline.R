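#' Border polylines
#'
#' A border polyline is an ordered run of 3D points (mm) tracing one border of
#' the source area's pial surface, rostral to caudal. Polylines carry a `role`
#' naming which border they are: the dorsal border of A30, the A29/A30
#' cytoarchitectonic boundary, the ventral border of A29, or the generic
#' dorsal/ventral border of a single area.
#'
#' @param points numeric matrix (n x 3) or data.frame with columns x, y, z,
#'   ordered rostral to caudal.
#' @param role one of `"dorsal_A30"`, `"A29_A30_boundary"`, `"ventral_A29"`,
#'   `"dorsal_of_area"`, `"ventral_of_area"`.
#' @return An object of class `border_polyline`: the point matrix with
#'   attributes `role` and `arclen` (cumulative arc length per vertex, mm).
#' @export
border_polyline <- function(points,
                            role = c("dorsal_of_area", "ventral_of_area",
                                     "dorsal_A30", "A29_A30_boundary",
                                     "ventral_A29")) {
  role <- match.arg(role)
  if (is.data.frame(points) && all(c("x", "y", "z") %in% names(points)))
    points <- points[, c("x", "y", "z")]
  pts <- unname(as.matrix(points))
  if (ncol(pts) != 3L)
    stop("polyline points must have 3 columns (x, y, z)", call. = FALSE)
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2L)
    stop("a border polyline needs at least 2 points", call. = FALSE)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg == 0))
    stop("consecutive polyline points must be distinct", call. = FALSE)
  structure(pts, role = role, arclen = c(0, cumsum(seg)),
            class = "border_polyline")
}

polyline_length <- function(b) {
  al <- attr(b, "arclen")
  al[length(al)]
}

#' @export
print.border_polyline <- function(x, ...) {
  cat(sprintf("<border_polyline> role=%s, %d points, length %.3f mm\n",
              attr(x, "role"), nrow(x), polyline_length(x)))
  invisible(x)
}

#' Resample a polyline at equal arc-length fractions
#'
#' @param b a [border_polyline()].
#' @param n number of output vertices (>= 2).
#' @return a `border_polyline` with `n` vertices at arc-length fractions
#'   `seq(0, 1, length.out = n)` of the input.
#' @export
resample_polyline <- function(b, n) {
  stopifnot(n >= 2L)
  al <- attr(b, "arclen")
  s <- seq(0, al[length(al)], length.out = n)
  out <- vapply(1:3, function(j) stats::approx(al, b[, j], xout = s)$y,
                numeric(n))
  border_polyline(out, role = attr(b, "role"))
}

#' Smooth a border polyline by local regression against arc length
#'
#' Each coordinate is fitted by tricube-weighted local linear regression
#' (`stats::loess`, degree 1) against cumulative arc length, the smoothing
#' used to clean manually delineated borders before triangulating the surface.
#' Noiseless collinear input is reproduced exactly (a local linear fit of a
#' line is the line).
#'
#' @param raw_border a [border_polyline()] with at least 4 points.
#' @param span loess span: the fraction of points entering each local fit.
#' @return a smoothed `border_polyline` with the same number of points.
#' @export
smooth_borders <- function(raw_border, span = 0.5) {
  if (nrow(raw_border) < 4L)
    stop("border smoothing needs at least 4 points", call. = FALSE)
  s <- attr(raw_border, "arclen")
  fit1 <- function(y) {
    m <- stats::loess(y ~ s, span = span, degree = 1, family = "gaussian",
                      surface = "direct",
                      control = stats::loess.control(statistics = "none"))
    stats::predict(m, data.frame(s = s))
  }
  out <- vapply(1:3, function(j) fit1(raw_border[, j]),
                numeric(nrow(raw_border)))
  border_polyline(out, role = attr(raw_border, "role"))
}

## distance from one point to every segment of a polyline; returns the
## minimizing foot point and its arc-length position along the polyline
.point_to_polyline <- function(p, pts) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  ap <- sweep(a, 2L, p, "-")
  t <- pmin(pmax(-rowSums(ap * ab) / len2, 0), 1)
  foot <- a + ab * t
  d2 <- rowSums(sweep(foot, 2L, p, "-")^2)
  i <- which.min(d2)
  seglen <- sqrt(len2)
  arc0 <- c(0, cumsum(seglen))
  list(dist = sqrt(d2[i]), foot = foot[i, ],
       arc = arc0[i] + t[i] * seglen[i], total = arc0[length(arc0)])
}

#' Minimum Euclidean distance from a point to a border polyline
#'
#' @param p numeric length-3 point.
#' @param b a [border_polyline()].
#' @return scalar distance (mm).
#' @export
dist_to_border <- function(p, b) {
  .point_to_polyline(as.numeric(p), unclass(b))$dist
}
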