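#' @include AllClasses.R geometry.R
NULL

## Direct algebraic least-squares conic fit (numerically stabilised
## formulation solving the reduced 3x3 eigenproblem), on centred and scaled
## coordinates. Returns the conic coefficients c(A, B, C, D, E, F) in the
## original frame, or NULL when no elliptic solution exists.
directConicFit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(sc) || sc == 0) return(NULL)
  u <- (x - mx) / sc; v <- (y - my) / sc
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  i <- which(cond > 1e-12)
  if (!length(i)) return(NULL)
  a1 <- vec[, i[1]]
  k <- c(a1, as.numeric(Tm %*% a1))    # conic in (u, v)
  ## map back: u = (x - mx)/sc, v = (y - my)/sc
  A <- k[1] / sc^2; B <- k[2] / sc^2; C <- k[3] / sc^2
  D <- k[4] / sc - 2 * A * mx - B * my
  E <- k[5] / sc - 2 * C * my - B * mx
  Fc <- k[6] + A * mx^2 + B * mx * my + C * my^2 - k[4] * mx / sc - k[5] * my / sc
  c(A, B, C, D, E, Fc)
}

## Conic coefficients -> center, semi-axes, major-axis direction.
conicToEllipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; Fc <- k[6]
  M <- matrix(c(2 * A, B, B, 2 * C), 2)
  cen <- tryCatch(solve(M, -c(D, E)), error = function(e) NULL)
  if (is.null(cen)) return(NULL)
  K <- A * cen[1]^2 + B * cen[1] * cen[2] + C * cen[2]^2 + D * cen[1] +
    E * cen[2] + Fc
  eq <- eigen(matrix(c(A, B / 2, B / 2, C), 2), symmetric = TRUE)
  ax2 <- -K / eq$values
  if (any(ax2 <= 0) || any(!is.finite(ax2))) return(NULL)
  ax <- sqrt(ax2)
  j <- which.max(ax)
  list(center = cen, a = max(ax), b = min(ax), v = eq$vectors[, j])
}

## Fold a major-axis direction into an angle from the +y axis in
## (-pi/2, pi/2], choosing the representative with nonnegative y component.
axisAngleFromY <- function(v) {
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  ang <- atan2(v[1], v[2])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  ang
}

## Cranially-directed unit vector of the major axis.
majorAxisUnit <- function(ellipse) c(sin(ellipse@angleRad), cos(ellipse@angleRad))

#' Fit the orientation ellipse of a lung contour
#'
#' Determines the general orientation of the lung by fitting an ellipse to
#' the points on the lung outline, correcting for small positional
#' differences between subjects. The fit is the direct algebraic least
#' squares solution; when that is degenerate (near-collinear vertices), the
#' principal axes of the vertex scatter are used instead and flagged via
#' `method = "principal"`.
#'
#' @param contour a [LungContour-class] with at least 8 vertices.
#' @return an [EllipseFit-class]; the major-axis angle is measured from the
#'   +y (cranio-caudal) axis toward +x, in (-pi/2, pi/2].
#' @export
fitOrientation <- function(contour) {
  v <- vertices(contour)
  if (nrow(v) < 8) stop("orientation fit needs at least 8 vertices")
  k <- directConicFit(v[, 1], v[, 2])
  ell <- if (!is.null(k)) conicToEllipse(k) else NULL
  if (!is.null(ell)) {
    return(new("EllipseFit", center = as.numeric(ell$center),
               semiMajorMM = ell$a, semiMinorMM = ell$b,
               angleRad = axisAngleFromY(ell$v), method = "direct"))
  }
  ## fallback: principal axes of the vertex scatter; for points uniformly
  ## distributed on an ellipse the axis variance is (semi-axis)^2 / 2
  cv <- stats::cov(v)
  eg <- eigen(cv, symmetric = TRUE)
  a <- sqrt(2 * max(eg$values))
  b <- sqrt(2 * max(min(eg$values), .Machine$double.eps))
  new("EllipseFit", center = colMeans(v), semiMajorMM = a, semiMinorMM = b,
      angleRad = axisAngleFromY(eg$vectors[, which.max(eg$values)]),
      method = "principal")
}

#' Locate the lung apex
#'
#' The highest point on the lung outline, measured in the direction of the
#' major axis of the orientation ellipse: the vertex maximizing the scalar
#' projection onto the cranially-directed major-axis unit vector. Ties are
#' broken by the smaller x coordinate.
#'
#' @param contour a [LungContour-class].
#' @param ellipse the frame's [EllipseFit-class].
#' @return numeric length-2 point (x, y) mm.
#' @export
findLungApex <- function(contour, ellipse) {
  v <- vertices(contour)
  u <- majorAxisUnit(ellipse)
  proj <- v %*% u
  cand <- which(proj == max(proj))
  if (length(cand) > 1) cand <- cand[order(v[cand, 1])]
  as.numeric(v[cand[1], ])
}

#' Area centroid of a lung contour
#'
#' Centre of gravity of the segmented region (polygon area centroid, not
#' the vertex mean).
#'
#' @param contour a [LungContour-class] bounding a nonzero area.
#' @return numeric length-2 point (x, y) mm.
#' @export
contourCentroid <- function(contour) polygonCentroid(vertices(contour))

#' Detect the costophrenic angles
#'
#' The anterior and posterior costophrenic angles are the points with the
#' largest Euclidean distance to the centroid in the lower part of the
#' lung. "Lower" is orientation-corrected: vertices whose projection on the
#' cranially-directed major axis falls below the centroid's projection.
#' That set is split by the major-axis line through the centroid into an
#' anterior (smaller x) and a posterior side, and the most distant vertex
#' of each side is returned. Ties are broken caudal-most, then smallest x.
#'
#' @param contour a [LungContour-class].
#' @param ellipse the frame's [EllipseFit-class].
#' @param centroid the frame's area centroid.
#' @return list with numeric points `anterior` and `posterior`.
#' @export
findCostophrenicAngles <- function(contour, ellipse, centroid) {
  v <- vertices(contour)
  u <- majorAxisUnit(ellipse)
  w <- c(cos(ellipse@angleRad), -sin(ellipse@angleRad))  # +x-ward normal
  rel <- sweep(v, 2, centroid)
  proj <- rel %*% u
  side <- rel %*% w
  lower <- proj < 0
  pick <- function(idx) {
    if (!length(idx)) return(NULL)
    d <- sqrt(rowSums(rel[idx, , drop = FALSE]^2))
    ord <- order(-d, proj[idx], v[idx, 1])
    as.numeric(v[idx[ord[1]], ])
  }
  ant <- pick(which(lower & side <= 0))
  post <- pick(which(lower & side > 0))
  if (is.null(ant) || is.null(post))
    stop("degenerate contour: no vertices on one side of the lower lung")
  list(anterior = ant, posterior = post)
}

#' Isolate the diaphragm contour
#'
#' Of the two paths along the closed lung contour between the costophrenic
#' angles, returns the one not containing the lung apex, oriented anterior
#' to posterior, with cumulative arc length.
#'
#' @param contour a [LungContour-class].
#' @param anterior,posterior the costophrenic angle points (must be contour
#'   vertices).
#' @param lungApex the lung apex point.
#' @return a [DiaphragmContour-class].
#' @export
diaphragmContour <- function(contour, anterior, posterior, lungApex) {
  v <- vertices(contour)
  nearest <- function(p) which.min((v[, 1] - p[1])^2 + (v[, 2] - p[2])^2)
  ia <- nearest(anterior); ip <- nearest(posterior); ix <- nearest(lungApex)
  if (ix == ia || ix == ip)
    stop("lung apex coincides with a costophrenic angle")
  n <- nrow(v)
  fwd <- ringPath(n, ia, ip)
  bwd <- rev(ringPath(n, ip, ia))
  path <- if (ix %in% fwd[-c(1, length(fwd))]) bwd else fwd
  pts <- v[path, , drop = FALSE]
  new("DiaphragmContour", points = pts, arcLengthMM = cumulativeArcLength(pts))
}

#' Raw diaphragm apex
#'
#' The point on the diaphragm contour furthest from the straight line
#' between the two costophrenic angles, with its arc-length fraction along
#' the diaphragm (0 at the anterior angle, 1 at the posterior). Ties are
#' broken toward the smaller fraction. When all points are collinear with
#' the chord the apex is undefined: the chord midpoint is reported at
#' fraction 0.5 with `flat = TRUE`.
#'
#' @param dia a [DiaphragmContour-class] with at least 3 points.
#' @return list with `point`, `fraction`, `distance` (mm, unsigned) and
#'   `flat`.
#' @export
findDiaphragmApexRaw <- function(dia) {
  pts <- dia@points
  if (nrow(pts) < 3) stop("diaphragm contour needs at least 3 points")
  a <- pts[1, ]; b <- pts[nrow(pts), ]
  d <- abs(signedChordDistance(pts, a, b))
  if (max(d) < 1e-9 * (1 + sqrt(sum((b - a)^2)))) {
    return(list(point = as.numeric((a + b) / 2), fraction = 0.5,
                distance = 0, flat = TRUE))
  }
  i <- which.max(d)                    # first max = smallest arc fraction
  total <- dia@arcLengthMM[length(dia@arcLengthMM)]
  list(point = as.numeric(pts[i, ]), fraction = dia@arcLengthMM[i] / total,
       distance = d[i], flat = FALSE)
}

#' Derived diaphragm apex across a series
#'
#' The raw apex can be variable between consecutive frames, so the series
#' median of the per-frame arc-length fractions is computed once and the
#' derived apex of every frame is placed at that fraction along the frame's
#' diaphragm contour (linear interpolation between vertices). With an even
#' number of frames the median is the mean of the two middle fractions.
#'
#' @param fractions numeric vector of per-frame raw-apex fractions.
#' @param diaphragms list of [DiaphragmContour-class], one per frame.
#' @return list with `medianFraction` and `points` (list of length-2
#'   numeric points).
#' @export
deriveApex <- function(fractions, diaphragms) {
  if (!length(fractions)) stop("empty series")
  if (length(fractions) != length(diaphragms))
    stop("one fraction per diaphragm contour is required")
  med <- stats::median(fractions)
  pts <- lapply(diaphragms, function(d)
    as.numeric(pointAtArcFraction(d@points, med, d@arcLengthMM)))
  list(medianFraction = med, points = pts)
}

#' Detect all landmarks of a single frame
#'
#' Runs the per-frame chain: orientation ellipse, lung apex, area centroid,
#' costophrenic angles, diaphragm contour and raw diaphragm apex. The
#' derived apex needs the whole series and is filled by
#' [seriesLandmarks()].
#'
#' @param contour a [LungContour-class].
#' @return list with `landmarks` (a [LandmarkSet-class], `apexDerived`
#'   unset), `diaphragm` (a [DiaphragmContour-class]) and `ellipse`.
#' @export
frameLandmarks <- function(contour) {
  ell <- fitOrientation(contour)
  apex <- findLungApex(contour, ell)
  cen <- contourCentroid(contour)
  ang <- findCostophrenicAngles(contour, ell, cen)
  dia <- diaphragmContour(contour, ang$anterior, ang$posterior, apex)
  raw <- findDiaphragmApexRaw(dia)
  lm <- new("LandmarkSet", lungApex = apex, centroid = cen,
            anteriorAngle = ang$anterior, posteriorAngle = ang$posterior,
            apexRaw = raw$point, apexRawFraction = raw$fraction,
            flatDiaphragm = raw$flat, frameIndex = contour@frameIndex)
  list(landmarks = lm, diaphragm = dia, ellipse = ell)
}

#' Detect landmarks for every frame of a series
#'
#' Applies [frameLandmarks()] per frame, then computes the derived
#' diaphragm apex at the series-median raw-apex fraction.
#'
#' @param series a [FrameSeries-class].
#' @return list with `landmarks` (list of completed [LandmarkSet-class]),
#'   `diaphragms`, `ellipses` and `medianFraction`.
#' @export
seriesLandmarks <- function(series) {
  per <- lapply(seq_along(series@contours), function(i) {
    ct <- series@contours[[i]]
    ct@frameIndex <- i
    frameLandmarks(ct)
  })
  dias <- lapply(per, `[[`, "diaphragm")
  fracs <- vapply(per, function(p) p$landmarks@apexRawFraction, 0)
  der <- deriveApex(fracs, dias)
  lms <- lapply(seq_along(per), function(i) {
    lm <- per[[i]]$landmarks
    lm@apexDerived <- der$points[[i]]
    lm
  })
  list(landmarks = lms, diaphragms = dias,
       ellipses = lapply(per, `[[`, "ellipse"),
       medianFraction = der$medianFraction)
}

#' Export landmarks to a long-format data frame
#'
#' @param landmarks list of [LandmarkSet-class] as returned by
#'   [seriesLandmarks()].
#' @return data.frame with columns `frame_index`, `landmark`, `x_mm`,
#'   `y_mm`, `fraction`.
#' @export
landmarksToFrame <- function(landmarks) {
  do.call(rbind, lapply(landmarks, function(lm) {
    data.frame(
      frame_index = lm@frameIndex,
      landmark = c("lung_apex", "centroid", "anterior_angle",
                   "posterior_angle", "apex_raw", "apex_derived"),
      x_mm = c(lm@lungApex[1], lm@centroid[1], lm@anteriorAngle[1],
               lm@posteriorAngle[1], lm@apexRaw[1], lm@apexDerived[1]),
      y_mm = c(lm@lungApex[2], lm@centroid[2], lm@anteriorAngle[2],
               lm@posteriorAngle[2], lm@apexRaw[2], lm@apexDerived[2]),
      fraction = c(NA, NA, NA, NA, lm@apexRawFraction, NA))
  }))
}
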