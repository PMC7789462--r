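# Brute-force oracles and fixture builders. The oracles re-implement the
# landmark definitions as plain exhaustive loops, independent of the
# vectorized package code paths.

# exhaustive scan: vertex maximizing projection on the cranially-directed
# major axis; ties by smaller x
bruteLungApex <- function(contour, ellipse) {
  v <- vertices(contour)
  ang <- ellipse@angleRad
  u <- c(sin(ang), cos(ang))
  best <- NULL
  for (i in seq_len(nrow(v))) {
    pr <- v[i, 1] * u[1] + v[i, 2] * u[2]
    if (is.null(best) || pr > best$pr + 0 ||
        (pr == best$pr && v[i, 1] < best$x)) {
      best <- list(pr = pr, x = v[i, 1], p = v[i, ])
    }
  }
  as.numeric(best$p)
}

# exhaustive max-distance scan over the lower-part vertices of each side;
# ties broken caudal-most (smaller axis projection) then smaller x
bruteCorners <- function(contour, ellipse, centroid) {
  v <- vertices(contour)
  ang <- ellipse@angleRad
  u <- c(sin(ang), cos(ang))
  w <- c(cos(ang), -sin(ang))
  lexBetter <- function(a, b) {        # is key a better than key b?
    for (j in seq_along(a)) {
      if (a[j] < b[j]) return(TRUE)
      if (a[j] > b[j]) return(FALSE)
    }
    FALSE
  }
  pickBest <- function(rows) {
    best <- NULL
    for (i in rows) {
      rel <- v[i, ] - centroid
      key <- c(-sqrt(sum(rel^2)), sum(rel * u), v[i, 1])
      if (is.null(best) || lexBetter(key, best$key))
        best <- list(key = key, p = v[i, ])
    }
    as.numeric(best$p)
  }
  lower <- which(apply(v, 1, function(p) sum((p - centroid) * u)) < 0)
  side <- vapply(lower, function(i) sum((v[i, ] - centroid) * w), 0)
  list(anterior = pickBest(lower[side <= 0]),
       posterior = pickBest(lower[side > 0]))
}

# exhaustive scan of perpendicular distance to the corner chord
bruteRawApex <- function(dia) {
  pts <- dia@points
  a <- pts[1, ]; b <- pts[nrow(pts), ]
  len <- sqrt(sum((b - a)^2))
  best <- NULL
  for (i in seq_len(nrow(pts))) {
    d <- abs((b[1] - a[1]) * (pts[i, 2] - a[2]) -
               (b[2] - a[2]) * (pts[i, 1] - a[1])) / len
    if (is.null(best) || d > best$d) best <- list(d = d, i = i)
  }
  total <- dia@arcLengthMM[nrow(pts)]
  list(point = as.numeric(pts[best$i, ]), d = best$d,
       fraction = dia@arcLengthMM[best$i] / total)
}

rotatePoints <- function(xy, angle, center = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(sweep(xy, 2, center) %*% t(R), 2, center, `+`)
}

# randomized but feasible single lung contour (optionally rotated/jittered)
randomLungContour <- function(seed) {
  set.seed(seed)
  ap <- runif(1, 70, 140)
  cc <- runif(1, 1.2, 2.2) * ap
  h <- runif(1, 15, 0.35 * cc)
  full <- runif(1, 0.35, 0.75)
  f <- runif(1, 0.15, 0.85)
  xy <- diaphragmotion:::buildLungPolygon(ap, cc + h, h, full, f, 160L)
  xy <- xy + matrix(rnorm(length(xy), 0, 0.4), ncol = 2)
  xy <- rotatePoints(xy, runif(1, -0.25, 0.25), center = colMeans(xy))
  xy <- sweep(xy, 2, runif(2, -40, 40), `+`)
  lungContour(xy)
}

# semicircular diaphragm polyline (dome on one side of the chord)
semicircleDiaphragm <- function(r = 30, n = 721, below = FALSE,
                                x0 = 0, y0 = 0) {
  th <- seq(pi, 0, length.out = n)
  y <- r * sin(th)
  if (below) y <- -y
  pts <- cbind(x0 + r + r * cos(th), y0 + y)
  new("DiaphragmContour", points = pts,
      arcLengthMM = diaphragmotion:::cumulativeArcLength(pts))
}

# D-shaped lung used by the corner-detection examples: flat bottom with
# sharp basal corners at (x1, 0) and (x2, 0), elliptical roof above
dShapeContour <- function(x1 = 10, x2 = 90, roofH = 120, n = 120) {
  xs <- seq(x1, x2, length.out = n)
  bottom <- cbind(xs, 0)
  xr <- rev(xs)[-c(1, n)]
  cx <- (x1 + x2) / 2; a <- (x2 - x1) / 2
  roof <- cbind(xr, roofH * sqrt(pmax(0, 1 - ((xr - cx) / a)^2)))
  lungContour(rbind(bottom, roof))
}

writePhantomPNGs <- function(dir, params, subjectId = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generatePhantomSeries(params, output = "mask", subjectId = subjectId)
  for (i in seq_along(ph$masks))
    png::writePNG(ph$masks[[i]]@pixels,
                  file.path(dir, sprintf("frame_%02d.png", i)))
  ph
}
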