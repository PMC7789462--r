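## Planar polygon and polyline primitives shared by all measurement code.
## Vertices are n x 2 matrices of (x, y) in mm; polygons are stored open
## (first vertex not repeated) and are treated as closed.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in the package coordinate
#' frame (x anterior to posterior, y caudal to cranial).
#'
#' @param xy numeric matrix with two columns of vertex coordinates in mm;
#'   the polygon is closed implicitly.
#' @return signed area in mm^2.
#' @export
polygonArea <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("polygon needs at least 3 vertices")
  j <- c(2:n, 1L)
  0.5 * sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])
}

#' Area centroid of a simple polygon
#'
#' Centre of gravity of the enclosed region (not the vertex mean), from the
#' standard shoelace moments.
#'
#' @inheritParams polygonArea
#' @return numeric length-2 vector (x, y) in mm.
#' @export
polygonCentroid <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("polygon needs at least 3 vertices")
  j <- c(2:n, 1L)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- 0.5 * sum(cr)
  if (abs(a) < .Machine$double.eps * max(abs(xy)) ^ 2 * n)
    stop("zero-area polygon has no centroid")
  cx <- sum((xy[, 1] + xy[j, 1]) * cr) / (6 * a)
  cy <- sum((xy[, 2] + xy[j, 2]) * cr) / (6 * a)
  c(cx, cy)
}

## Cumulative arc length along an open polyline, starting at 0.
cumulativeArcLength <- function(xy) {
  xy <- as.matrix(xy)
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(0, cumsum(seg))
}

## Point at a given arc-length fraction (0..1) along an open polyline,
## linearly interpolated between vertices.
pointAtArcFraction <- function(xy, fraction, arclen = cumulativeArcLength(xy)) {
  stopifnot(fraction >= 0, fraction <= 1)
  total <- arclen[length(arclen)]
  if (total == 0) return(xy[1, ])
  s <- fraction * total
  i <- findInterval(s, arclen, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(xy) - 1L)
  ds <- arclen[i + 1L] - arclen[i]
  w <- if (ds > 0) (s - arclen[i]) / ds else 0
  (1 - w) * xy[i, ] + w * xy[i + 1L, ]
}

## Signed perpendicular distance of points p (n x 2) from the line a -> b;
## positive on the left of the direction a -> b.
signedChordDistance <- function(p, a, b) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) stop("chord endpoints coincide")
  p <- matrix(p, ncol = 2)
  (d[1] * (p[, 2] - a[2]) - d[2] * (p[, 1] - a[1])) / len
}

## Ensure counter-clockwise vertex order (positive shoelace area).
ensureCounterClockwise <- function(xy) {
  if (polygonArea(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

## Indices from `from` to `to` walking forward around a ring of size n,
## inclusive of both endpoints.
ringPath <- function(n, from, to) {
  if (from <= to) from:to else c(from:n, 1:to)
}
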