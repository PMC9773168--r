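#' Contour primitives for short-axis endocardial borders
#'
#' A contour is a closed, simple 2-D polygon stored as an open point list:
#' the first vertex is not repeated and the closing segment back to it is
#' implicit. Coordinates are millimetres in the slice plane.
#'
#' @param points a two-column numeric matrix (or coercible data frame) of
#'   (x, y) vertex coordinates in mm, ordered around the boundary.
#' @return an object of class `lv_contour`: a numeric matrix with columns
#'   `x` and `y`.
#' @examples
#' sq <- contour_points(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' contour_perimeter(sq)  # 4
#' contour_area(sq)       # 1
#' @export
contour_points <- function(points) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    stop("contour points must be a two-column numeric matrix", call. = FALSE)
  if (nrow(pts) < 3L)
    stop("invalid contour: fewer than 3 points", call. = FALSE)
  if (!all(is.finite(pts)))
    stop("invalid contour: non-finite coordinates", call. = FALSE)
  nxt <- c(2:nrow(pts), 1L)
  if (any(rowSums((pts[nxt, , drop = FALSE] - pts)^2) == 0))
    stop("invalid contour: consecutive duplicate points", call. = FALSE)
  dimnames(pts) <- list(NULL, c("x", "y"))
  class(pts) <- c("lv_contour", "matrix", "array")
  pts
}

as_contour <- function(x) {
  if (inherits(x, "lv_contour")) x else contour_points(x)
}

#' Perimeter of a closed contour
#'
#' Sum of Euclidean segment lengths around the polygon, including the
#' implicit closing segment. Invariant to rotation, translation and cyclic
#' reordering of the vertices; scales linearly under uniform scaling.
#'
#' @param contour an `lv_contour` or two-column coordinate matrix.
#' @return perimeter length in mm (scalar, > 0).
#' @export
contour_perimeter <- function(contour) {
  pts <- as_contour(contour)
  nxt <- c(2:nrow(pts), 1L)
  sum(sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2)))
}

#' Enclosed area of a closed contour
#'
#' Absolute shoelace area of the polygon; independent of vertex orientation.
#' The polygon is assumed simple (non-self-intersecting).
#'
#' @inheritParams contour_perimeter
#' @return enclosed area in mm^2 (scalar, >= 0).
#' @export
contour_area <- function(contour) {
  pts <- as_contour(contour)
  nxt <- c(2:nrow(pts), 1L)
  abs(sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2])) / 2
}

#' Regular polygonal approximation of a circle
#'
#' Builds an `lv_contour` with `n_points` vertices equally spaced on a
#' circle, first vertex at angle 0. Perimeter and area converge to 2*pi*r
#' and pi*r^2 from below as `n_points` grows.
#'
#' @param radius circle radius in mm (> 0).
#' @param n_points number of vertices (>= 3).
#' @param centre length-2 numeric centre (x, y) in mm.
#' @return an `lv_contour`.
#' @export
circle_contour <- function(radius, n_points = 50L, centre = c(0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive scalar", call. = FALSE)
  if (n_points < 3L)
    stop("n_points must be at least 3", call. = FALSE)
  th <- 2 * pi * seq(0L, n_points - 1L) / n_points
  contour_points(cbind(centre[1] + radius * cos(th),
                       centre[2] + radius * sin(th)))
}

#' @export
print.lv_contour <- function(x, ...) {
  cat(sprintf("<lv_contour> %d points, perimeter %.2f mm, area %.2f mm^2\n",
              nrow(x), contour_perimeter(x), contour_area(x)))
  invisible(x)
}
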