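# major axis along y, rotated by `angle` from +y toward +x (the package's
# angle convention)
densEllipse <- function(a, b, angle = 0, center = c(0, 0), n = 400) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  xy <- cbind(b * cos(th), a * sin(th))
  lungContour(rotatePoints(xy, -angle) + rep(center, each = n))
}

test_that("direct ellipse fit recovers canonical and rotated ellipses", {
  e <- fitOrientation(densEllipse(60, 30, center = c(5, -7)))
  expect_equal(e@method, "direct")
  expect_equal(e@semiMajorMM, 60, tolerance = 0.01)
  expect_equal(e@semiMinorMM, 30, tolerance = 0.01)
  expect_equal(e@angleRad, 0, tolerance = 1e-6)
  expect_equal(e@center, c(5, -7), tolerance = 1e-6)

  # rotation by 0.3 rad toward +x; oracle = principal axes of dense samples
  ct <- densEllipse(60, 30, angle = 0.3, n = 10000)
  e2 <- fitOrientation(ct)
  expect_equal(e2@angleRad, 0.3, tolerance = 0.01)
  pr <- eigen(stats::cov(vertices(ct)), symmetric = TRUE)
  vmain <- pr$vectors[, which.max(pr$values)]
  expect_equal(e2@angleRad, diaphragmotion:::axisAngleFromY(vmain),
               tolerance = 0.01)

  # circle: axes equal within 1%, any angle accepted
  e3 <- fitOrientation(densEllipse(40, 40))
  expect_equal(e3@semiMajorMM / e3@semiMinorMM, 1, tolerance = 0.01)
  expect_error(fitOrientation(lungContour(rbind(c(0, 0), c(1, 0), c(1, 1),
                                                c(0, 1)))), "8 vertices")
})

test_that("collinear input falls back to principal axes", {
  x <- seq(0, 100, length.out = 30)
  pts <- cbind(x, 2 * x)
  ct <- new("LungContour", vertices = pts, frameIndex = NA_integer_)
  e <- fitOrientation(ct)
  expect_equal(e@method, "principal")
  expect_equal(tan(e@angleRad), 0.5, tolerance = 0.01)
})

test_that("lung apex maximizes the cranially-directed axis projection", {
  ct <- densEllipse(60, 30)
  e <- fitOrientation(ct)
  expect_equal(findLungApex(ct, e), c(0, 60), tolerance = 1e-9)

  ct2 <- densEllipse(60, 30, angle = 0.3)
  e2 <- fitOrientation(ct2)
  expect_equal(findLungApex(ct2, e2), bruteLungApex(ct2, e2))

  # tie on the projection resolves to the smaller x
  flat <- lungContour(rbind(c(0, 0), c(10, 0), c(10, 5), c(6, 5), c(2, 5),
                            c(0, 5), c(0, 2), c(0, 1)))
  eFlat <- new("EllipseFit", center = c(5, 2.5), semiMajorMM = 5,
               semiMinorMM = 2.5, angleRad = 0, method = "principal")
  expect_equal(findLungApex(flat, eFlat), c(0, 5))
})

test_that("costophrenic angles are the most distant lower-part vertices", {
  d <- dShapeContour(10, 90, 120)
  e <- fitOrientation(d)
  cen <- contourCentroid(d)
  ang <- findCostophrenicAngles(d, e, cen)
  expect_equal(ang$anterior, c(10, 0))
  expect_equal(ang$posterior, c(90, 0))
  br <- bruteCorners(d, e, cen)
  expect_equal(ang$anterior, br$anterior)
  expect_equal(ang$posterior, br$posterior)

  # rotating the whole scene moves the detected corners with it
  rot <- lungContour(rotatePoints(vertices(d), 0.2, center = cen))
  eR <- fitOrientation(rot)
  cenR <- contourCentroid(rot)
  angR <- findCostophrenicAngles(rot, eR, cenR)
  expect_equal(angR$anterior, as.numeric(rotatePoints(rbind(ang$anterior),
                                                      0.2, center = cen)),
               tolerance = 1e-6)
  expect_equal(angR$posterior, as.numeric(rotatePoints(rbind(ang$posterior),
                                                       0.2, center = cen)),
               tolerance = 1e-6)
})

test_that("diaphragm contour is the corner-to-corner path avoiding the apex", {
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  circ <- lungContour(cbind(50 + 40 * cos(th), 40 * sin(th)))
  dia <- diaphragmContour(circ, anterior = c(10, 0), posterior = c(90, 0),
                          lungApex = c(50, 40))
  expect_lt(max(dia@points[, 2]), 1e-6)            # bottom semicircle
  expect_equal(dia@points[1, ], c(10, 0), tolerance = 1e-6)
  expect_equal(dia@points[nrow(dia@points), ], c(90, 0), tolerance = 1e-6)
  total <- dia@arcLengthMM[length(dia@arcLengthMM)]
  expect_equal(total, pi * 40, tolerance = 0.01)
  expect_gte(total, sqrt(sum(c(80, 0)^2)))         # arc >= chord

  # reversed stored orientation yields the identical polyline
  circRev <- new("LungContour",
                 vertices = vertices(circ)[rev(seq_len(720)), ],
                 frameIndex = NA_integer_)
  diaRev <- diaphragmContour(circRev, c(10, 0), c(90, 0), c(50, 40))
  expect_equal(diaRev@points, dia@points)
  expect_error(diaphragmContour(circ, c(10, 0), c(90, 0), c(10, 0)),
               "coincides")
})

test_that("raw diaphragm apex is the furthest point from the corner chord", {
  dia <- semicircleDiaphragm(30)
  raw <- findDiaphragmApexRaw(dia)
  expect_equal(raw$distance, 30, tolerance = 1e-4)
  expect_equal(raw$fraction, 0.5, tolerance = 1e-3)
  expect_false(raw$flat)

  # asymmetric dome: spliced quarter-ellipses; equals the brute-force scan
  th1 <- seq(pi, pi / 2, length.out = 200)
  th2 <- seq(pi / 2, 0, length.out = 400)
  pts <- rbind(cbind(20 + 20 * cos(th1), 25 * sin(th1)),
               cbind(20 + 55 * cos(th2), 25 * sin(th2))[-1, ])
  diaA <- new("DiaphragmContour", points = pts,
              arcLengthMM = diaphragmotion:::cumulativeArcLength(pts))
  rawA <- findDiaphragmApexRaw(diaA)
  br <- bruteRawApex(diaA)
  expect_equal(rawA$point, br$point)
  expect_equal(rawA$fraction, br$fraction)

  # flat diaphragm: flagged, fraction 0.5, zero distance
  flatPts <- cbind(seq(0, 60, length.out = 31), 0)
  flat <- new("DiaphragmContour", points = flatPts,
              arcLengthMM = diaphragmotion:::cumulativeArcLength(flatPts))
  rawF <- findDiaphragmApexRaw(flat)
  expect_true(rawF$flat)
  expect_equal(rawF$fraction, 0.5)
  expect_equal(rawF$distance, 0)
})

test_that("derived apex uses the series-median fraction with interpolation", {
  dias <- list(semicircleDiaphragm(30), semicircleDiaphragm(32),
               semicircleDiaphragm(28))
  d1 <- deriveApex(c(0.40, 0.50, 0.60), dias)
  expect_equal(d1$medianFraction, 0.5)
  expect_equal(d1$points[[1]], c(30, 30), tolerance = 1e-3)

  # median is robust to one outlying frame
  d2 <- deriveApex(c(0.2, 0.2, 0.9), dias)
  expect_equal(d2$medianFraction, 0.2)

  # even frame count: mean of the two middle fractions
  d3 <- deriveApex(c(0.1, 0.4, 0.6, 0.9), c(dias, dias[1]))
  expect_equal(d3$medianFraction, 0.5)

  # interpolated point matches an independent arc-length parameterization
  dia <- semicircleDiaphragm(30)
  frac <- 0.37
  p <- deriveApex(rep(frac, 2), list(dia, dia))$points[[1]]
  thAt <- pi - frac * pi                           # constant-speed semicircle
  expect_equal(p, c(30 + 30 * cos(thAt), 30 * sin(thAt)), tolerance = 1e-3)
  expect_error(deriveApex(numeric(0), list()), "empty")
})

test_that("landmarks are equivariant under rigid motion of the contour", {
  base <- randomLungContour(11)
  res <- frameLandmarks(base)
  shift <- c(31.5, -12.25)
  angle <- 0.18
  move <- function(p) as.numeric(
    rotatePoints(rbind(p), angle, center = c(20, 10)) + rep(shift, each = 1))
  moved <- lungContour(rotatePoints(vertices(base), angle,
                                    center = c(20, 10)) +
                         rep(shift, each = nrow(vertices(base))))
  resM <- frameLandmarks(moved)
  tol <- 0.5                                       # 0.01 rad over ~100 mm arm
  expect_equal(resM$landmarks@lungApex, move(res$landmarks@lungApex),
               tolerance = tol)
  expect_equal(resM$landmarks@centroid, move(res$landmarks@centroid),
               tolerance = 1e-6)
  expect_equal(resM$landmarks@anteriorAngle,
               move(res$landmarks@anteriorAngle), tolerance = tol)
  expect_equal(resM$landmarks@posteriorAngle,
               move(res$landmarks@posteriorAngle), tolerance = tol)
  expect_equal(resM$landmarks@apexRawFraction,
               res$landmarks@apexRawFraction, tolerance = 0.01)
})

test_that("every landmark equals its brute-force oracle on random phantoms", {
  for (seed in 1:25) {
    ct <- randomLungContour(seed)
    e <- fitOrientation(ct)
    cen <- contourCentroid(ct)
    expect_equal(findLungApex(ct, e), bruteLungApex(ct, e), info = seed)
    ang <- findCostophrenicAngles(ct, e, cen)
    br <- bruteCorners(ct, e, cen)
    expect_equal(ang$anterior, br$anterior, info = seed)
    expect_equal(ang$posterior, br$posterior, info = seed)
    dia <- diaphragmContour(ct, ang$anterior, ang$posterior,
                            findLungApex(ct, e))
    raw <- findDiaphragmApexRaw(dia)
    brr <- bruteRawApex(dia)
    expect_equal(raw$point, brr$point, info = seed)
    expect_true(raw$fraction >= 0 && raw$fraction <= 1)
  }
})
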