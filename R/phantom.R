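#' @include AllClasses.R geometry.R segmentation-io.R
NULL

## Power-arch dome on u in [-1, 1]: y = h (1 - u^2)^m, apex h at u = 0.
## Fullness (area / (chord * height)) is F(m) = sqrt(pi) Gamma(m+1) /
## (2 Gamma(m+3/2)), strictly decreasing from 1 (m -> 0) to 0 (m -> Inf),
## so height and area - hence the DH and DA targets - are two independent
## shape degrees of freedom. For m > 1 the arch meets the chord with a
## horizontal tangent, giving near-right-angle costophrenic corners that
## survive binary rasterization; the fullness defaults keep every frame in
## that regime.
powerDomeFullness <- function(m)
  sqrt(pi) / 2 * exp(lgamma(m + 1) - lgamma(m + 3 / 2))

powerDomeExponent <- function(F) {
  if (F <= 0.05 || F >= 0.95)
    stop(sprintf(
      "inconsistent phantom parameters: dome fullness %.3f outside (0.05, 0.95)",
      F))
  stats::uniroot(function(m) powerDomeFullness(m) - F,
                 interval = c(1e-3, 200), tol = 1e-12)$root
}

## One lung outline in its local frame: diaphragm chord from (0,0) to
## (ap,0), dome arch above the chord, vertical walls, half-ellipse cap.
## T = supra-chord height (= cc + h), f = cap fraction of T.
buildLungPolygon <- function(ap, T, h, fullness, f, nVertices) {
  m <- powerDomeExponent(fullness)
  capH <- f * T
  wallH <- (1 - f) * T
  nDome <- max(33L, 2L * (nVertices %/% 5L) + 1L)     # odd: exact apex vertex
  nCap <- max(33L, 2L * (nVertices %/% 5L) + 1L)
  nWall <- max(2L, nVertices %/% 10L)
  u <- seq(-1, 1, length.out = nDome)
  dome <- cbind((u + 1) * ap / 2, h * (1 - u^2)^m)
  tw <- seq_len(nWall) / (nWall + 1)
  wallPost <- cbind(ap, tw * wallH)
  tc <- seq(0, pi, length.out = nCap)
  cap <- cbind(ap / 2 + (ap / 2) * cos(tc), wallH + capH * sin(tc))
  wallAnt <- cbind(0, rev(tw) * wallH)
  rbind(dome, wallPost, cap, wallAnt)   # counter-clockwise
}

## Closed-form lung area of the local shape.
lungPolygonArea <- function(ap, T, h, fullness, f)
  ap * T * (1 - f * (1 - pi / 4)) - fullness * ap * h

## Resolve the per-frame geometry and analytic outcomes implied by a
## parameter set; errors when targets are geometrically inconsistent.
phantomGeometry <- function(params) {
  apRatio <- params@ccRatio / params@ccApRatio
  ccE <- params@ccExpMM; apE <- params@apExpMM; hE <- params@domeHeightExpMM
  fE <- params@capFracExp
  fullE <- params@domeFullnessExp
  ccI <- ccE * params@ccRatio
  apI <- apE * apRatio
  hI <- hE * params@dhRatio
  if (hI >= ccI)
    stop("inconsistent phantom parameters: inspiratory dome deeper than lung")
  ## DA = fullness * chord * height, so the inspiratory fullness follows
  ## from the DA target given the AP and DH targets
  fullI <- fullE * params@daRatio / (apRatio * params@dhRatio)
  powerDomeExponent(fullI)             # range check
  areaE <- lungPolygonArea(apE, ccE + hE, hE, fullE, fE)
  areaI <- areaE * params@areaRatio
  ## cap fraction at inspiration solved from the lung-area target
  TI <- ccI + hI
  fI <- (apI * TI - fullI * apI * hI - areaI) / (apI * TI * (1 - pi / 4))
  if (fI < 0.01 || fI > 0.99)
    stop(sprintf(
      "inconsistent phantom parameters: lung-area ratio %.3f needs cap fraction %.3f outside (0.01, 0.99)",
      params@areaRatio, fI))
  dAP <- apI - apE
  if (params@postDisplacementMM < abs(dAP))
    stop(sprintf(
      "inconsistent phantom parameters: posterior displacement %.1f mm smaller than the AP-extent change %.1f mm",
      params@postDisplacementMM, abs(dAP)))
  drop <- sqrt(params@postDisplacementMM^2 - dAP^2)
  list(apRatio = apRatio, fullE = fullE, fullI = fullI, fE = fE, fI = fI,
       ccE = ccE, apE = apE, hE = hE, ccI = ccI, apI = apI, hI = hI,
       areaE = areaE, areaI = areaI, chordDrop = drop)
}

#' Phantom phenotype presets
#'
#' Parameter sets whose true outcome ratios equal the reported group means
#' of the three study cohorts, plus a `severe` phenotype in which the
#' diaphragm shows hardly any motion and the CC ratio is 1. Healthy
#' controls: CC 1.72, area 2.54, CC-AP 1.38, DA 0.91, DH 0.82, posterior
#' displacement 70.7 mm. Patients with normal spirometry: 1.60, 2.57,
#' 1.22, 1.34, 1.08, 70.6 mm. Patients with decreased spirometry: 1.32,
#' 1.95, 1.04, 1.79, 1.41, 35.6 mm. The AP ratio is always
#' `cc_ratio / cc_ap_ratio`. The severe preset's non-CC values are package
#' choices consistent with the qualitative phenotype (thoracic-wall
#' dominated inspiration, strongly increased dome curvature).
#'
#' @param name one of `"healthy"`, `"normal_spiro_pompe"`,
#'   `"decreased_spiro_pompe"`, `"severe"`.
#' @param ... overrides forwarded to [phantomParams()].
#' @return a [PhantomParams-class].
#' @export
phantomPreset <- function(name = c("healthy", "normal_spiro_pompe",
                                   "decreased_spiro_pompe", "severe"), ...) {
  name <- match.arg(name)
  p <- switch(name,
    healthy = list(ccRatio = 1.72, areaRatio = 2.54, ccApRatio = 1.38,
                   daRatio = 0.91, dhRatio = 0.82, postDisplacementMM = 70.7),
    normal_spiro_pompe = list(ccRatio = 1.60, areaRatio = 2.57,
                              ccApRatio = 1.22, daRatio = 1.34,
                              dhRatio = 1.08, postDisplacementMM = 70.6),
    decreased_spiro_pompe = list(ccRatio = 1.32, areaRatio = 1.95,
                                 ccApRatio = 1.04, daRatio = 1.79,
                                 dhRatio = 1.41, postDisplacementMM = 35.6),
    severe = list(ccRatio = 1.00, areaRatio = 1.30, ccApRatio = 0.80,
                  daRatio = 1.90, dhRatio = 1.55, postDisplacementMM = 32))
  do.call(phantomParams, utils::modifyList(p, list(...)))
}

#' Construct phantom parameters
#'
#' Baseline expiratory geometry defaults to a realistic sagittal right
#' lung: CC 120 mm, AP 100 mm, dome height 30 mm, with the half-ellipse
#' cap occupying 90% of the supra-chord height (an expiratory lung is
#' dome-like, an inspiratory one elongated). 15 frames span end-expiration
#' to end-inspiration.
#'
#' @param ccExpMM,apExpMM,domeHeightExpMM expiratory extents in mm.
#' @param capFracExp expiratory cap fraction in (0, 1).
#' @param domeFullnessExp expiratory dome fullness (area / (chord x
#'   height)); the default 0.5 keeps the dome in the flat-tangent regime
#'   where costophrenic corners are near right angles.
#' @param ccRatio,ccApRatio,areaRatio,daRatio,dhRatio true ratios.
#' @param postDisplacementMM true posterior-corner displacement (mm).
#' @param nFrames,verticesPerContour,rasterSpacingMM,jitterSdMM,seed see
#'   [PhantomParams-class].
#' @return a validated [PhantomParams-class]; geometric consistency of the
#'   targets is checked immediately.
#' @export
phantomParams <- function(ccExpMM = 120, apExpMM = 100, domeHeightExpMM = 30,
                          capFracExp = 0.9, domeFullnessExp = 0.5,
                          ccRatio = 1.72, ccApRatio = 1.38,
                          areaRatio = 2.54, daRatio = 0.91, dhRatio = 0.82,
                          postDisplacementMM = 70.7, nFrames = 15L,
                          verticesPerContour = 200L, rasterSpacingMM = 1,
                          jitterSdMM = 0, seed = 1L) {
  params <- new("PhantomParams", ccExpMM = ccExpMM, apExpMM = apExpMM,
                domeHeightExpMM = domeHeightExpMM, capFracExp = capFracExp,
                domeFullnessExp = domeFullnessExp,
                ccRatio = ccRatio, ccApRatio = ccApRatio,
                areaRatio = areaRatio, daRatio = daRatio, dhRatio = dhRatio,
                postDisplacementMM = postDisplacementMM,
                nFrames = as.integer(nFrames),
                verticesPerContour = as.integer(verticesPerContour),
                rasterSpacingMM = rasterSpacingMM, jitterSdMM = jitterSdMM,
                seed = as.integer(seed))
  phantomGeometry(params)              # fail fast on inconsistent targets
  params
}

#' Rasterize a contour to a binary mask
#'
#' Even-odd scanline fill on the pixel-center grid. The grid is defined by
#' a bounding box (shared across the frames of a series) and the pixel
#' spacing; row 1 of the mask is the cranial edge.
#'
#' @param contour a [LungContour-class].
#' @param spacingMM (row, col) spacing in mm.
#' @param bbox numeric `c(xmin, xmax, ymin, ymax)`; defaults to the contour
#'   bounds plus a margin.
#' @return a [MaskFrame-class].
#' @export
rasterizeContour <- function(contour, spacingMM = c(1, 1), bbox = NULL) {
  v <- vertices(contour)
  if (is.null(bbox))
    bbox <- c(min(v[, 1]) - 3, max(v[, 1]) + 3, min(v[, 2]) - 3, max(v[, 2]) + 3)
  spr <- spacingMM[1]; spc <- spacingMM[2]
  nc <- max(1L, ceiling((bbox[2] - bbox[1]) / spc))
  nr <- max(1L, ceiling((bbox[4] - bbox[3]) / spr))
  xs <- bbox[1] + (seq_len(nc) - 0.5) * spc
  ys <- bbox[4] - (seq_len(nr) - 0.5) * spr      # row 1 cranial
  mask <- matrix(0, nr, nc)
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[c(2:n, 1), 1]; y2 <- v[c(2:n, 1), 2]
  for (i in seq_len(nr)) {
    y <- ys[i]
    hit <- (y1 <= y) != (y2 <= y)
    if (!any(hit)) next
    cx <- x1[hit] + (y - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    cx <- sort(cx)
    for (k in seq(1, length(cx) - 1, by = 2))
      mask[i, xs >= cx[k] & xs <= cx[k + 1]] <- 1
  }
  maskFrame(mask, spacingMM = spacingMM, frameIndex = contour@frameIndex,
            orientation = "anterior_left")
}

#' Generate one phantom frame series with known ground truth
#'
#' Builds the respiratory sequence of one synthetic subject. Extents, dome
#' height and shape parameters interpolate geometrically (constant
#' per-frame factor) from the expiratory to the inspiratory state, so every
#' intermediate frame is a valid lung shape; the diaphragm chord descends
#' linearly by the drop implied by the posterior-displacement target. With
#' `output = "polygon"` the series holds the exact polygons; with
#' `output = "mask"` each frame is rasterized at `rasterSpacingMM` and the
#' series is re-extracted through the mask pipeline, exercising the full
#' measurement chain.
#'
#' @param params a [PhantomParams-class].
#' @param output `"polygon"` or `"mask"`.
#' @param subjectId subject label.
#' @return list with `series` (a [FrameSeries-class]), `truth` (one-row
#'   data.frame of analytic outcomes: six ratios plus anterior/posterior
#'   displacements in mm) and, for mask output, `masks` (list of
#'   [MaskFrame-class]).
#' @export
generatePhantomSeries <- function(params, output = c("polygon", "mask"),
                                  subjectId = "phantom") {
  output <- match.arg(output)
  g <- phantomGeometry(params)
  n <- params@nFrames
  s <- (seq_len(n) - 1) / (n - 1)
  if (params@jitterSdMM > 0) set.seed(params@seed)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    ap <- g$apE * (g$apI / g$apE)^s[i]
    cc <- g$ccE * (g$ccI / g$ccE)^s[i]
    h <- g$hE * (g$hI / g$hE)^s[i]
    fu <- g$fullE * (g$fullI / g$fullE)^s[i]
    f <- g$fE * (g$fI / g$fE)^s[i]
    xy <- buildLungPolygon(ap, cc + h, h, fu, f, params@verticesPerContour)
    xy[, 2] <- xy[, 2] - g$chordDrop * s[i]
    if (params@jitterSdMM > 0)
      xy <- xy + matrix(stats::rnorm(length(xy), 0, params@jitterSdMM),
                        ncol = 2)
    polys[[i]] <- lungContour(xy, frameIndex = i)
  }
  truth <- data.frame(
    subject_id = subjectId,
    cc_ratio = params@ccRatio,
    ap_ratio = g$apRatio,
    cc_ap_ratio = params@ccApRatio,
    area_ratio = g$areaI / g$areaE,
    da_ratio = params@daRatio,
    dh_ratio = params@dhRatio,
    ant_displacement_mm = g$chordDrop,
    post_displacement_mm = params@postDisplacementMM)
  if (output == "polygon") {
    series <- frameSeries(polys, subjectId = subjectId)
    return(list(series = series, truth = truth))
  }
  allv <- do.call(rbind, lapply(polys, vertices))
  bbox <- c(min(allv[, 1]) - 3, max(allv[, 1]) + 3,
            min(allv[, 2]) - 3, max(allv[, 2]) + 3)
  masks <- lapply(polys, rasterizeContour,
                  spacingMM = rep(params@rasterSpacingMM, 2), bbox = bbox)
  extracted <- lapply(masks, extractContour)
  series <- frameSeries(extracted,
                        spacingMM = rep(params@rasterSpacingMM, 2),
                        subjectId = subjectId)
  list(series = series, truth = truth, masks = masks)
}

#' Simulate paired rater measurements
#'
#' Emulates a two-rater validation design (each rater measures every
#' subject once) by adding rater bias and Gaussian noise to true values.
#'
#' @param truth numeric vector of true per-subject values.
#' @param raterBias additive bias of the second rater.
#' @param noiseSd measurement noise sd (applied to both raters).
#' @param seed integer seed.
#' @return numeric matrix, subjects x 2 raters.
#' @export
simulateRaters <- function(truth, raterBias = 0, noiseSd = 0, seed = 1L) {
  stopifnot(noiseSd >= 0)
  set.seed(seed)
  n <- length(truth)
  cbind(rater1 = truth + stats::rnorm(n, 0, noiseSd),
        rater2 = truth + raterBias + stats::rnorm(n, 0, noiseSd))
}
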