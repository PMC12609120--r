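# Signed shoelace area of a polygon (2-column matrix; open or closed ring).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (n >= 2L && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  if (n < 3L) return(0)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

polygon_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (n >= 2L && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# TRUE if any two non-adjacent edges of the ring properly cross.
# Touching at shared vertices (pinches) is allowed.
polygon_self_intersects <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  if (n < 4L) return(FALSE)
  ax <- x; ay <- y; bx <- c(x[-1], x[1]); by <- c(y[-1], y[1])
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]       # edge n is adjacent to edge 1
    if (!length(js)) next
    d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[js], ay[js])
    d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[js], by[js])
    d3 <- cross(ax[js], ay[js], bx[js], by[js], ax[i], ay[i])
    d4 <- cross(ax[js], ay[js], bx[js], by[js], bx[i], by[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Feret (caliper) diameters of a point set
#'
#' Maximum and minimum caliper widths over all directions, computed on the
#' convex hull: the maximum Feret diameter is the largest pairwise distance
#' between hull vertices; the minimum is the smallest hull width, which is
#' always attained perpendicular to a hull edge (rotating-calipers result).
#'
#' @param points 2-column matrix of (x, y) coordinates.
#' @return Named numeric vector `c(feret_max =, feret_min =)`.
#' @export
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' feret_diameters(sq)  # max sqrt(2), min 1
feret_diameters <- function(points) {
  points <- unique(as.matrix(points))
  if (nrow(points) < 2L) return(c(feret_max = 0, feret_min = 0))
  h <- chull(points[, 1], points[, 2])
  hp <- points[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh == 2L) {
    d <- sqrt(sum((hp[1, ] - hp[2, ])^2))
    return(c(feret_max = d, feret_min = 0))
  }
  dmat <- as.matrix(stats::dist(hp))
  fmax <- max(dmat)
  fmin <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    proj <- (hp[, 1] - hp[i, 1]) * nrm[1] + (hp[, 2] - hp[i, 2]) * nrm[2]
    fmin <- min(fmin, diff(range(proj)))
  }
  c(feret_max = fmax, feret_min = fmin)
}

#' Shape morphometrics of a closed polygon
#'
#' Computes the descriptors used for endocrine-object shape profiling:
#' circularity `4*pi*A/P^2`, solidity `A / convex hull area`, maximum and
#' minimum Feret diameters, and the circle-equivalent diameter
#' `2*sqrt(A/pi)`.
#'
#' @param polygon 2-column matrix of (x, y) vertices in microns, open or
#'   closed ring.
#' @param validate If `TRUE` (default) reject self-intersecting polygons.
#' @return One-row data frame: `area`, `perimeter`, `circularity`,
#'   `solidity`, `feret_max`, `feret_min`, `equivalent_diameter`.
#' @export
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' morphology(sq)  # solidity 1, circularity pi/4
morphology <- function(polygon, validate = TRUE) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L) stop("`polygon` must be a 2-column matrix")
  if (nrow(polygon) < 3L) stop("`polygon` must have at least 3 vertices")
  if (validate && polygon_self_intersects(polygon))
    stop("self-intersecting polygon")
  A <- abs(polygon_area(polygon))
  if (A == 0) stop("degenerate polygon with zero area")
  P <- polygon_perimeter(polygon)
  h <- chull(polygon[, 1], polygon[, 2])
  hull_area <- abs(polygon_area(polygon[h, , drop = FALSE]))
  fer <- feret_diameters(polygon)
  data.frame(area = A,
             perimeter = P,
             circularity = 4 * pi * A / P^2,
             solidity = A / hull_area,
             feret_max = unname(fer["feret_max"]),
             feret_min = unname(fer["feret_min"]),
             equivalent_diameter = 2 * sqrt(A / pi))
}
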