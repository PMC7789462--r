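#' @include AllClasses.R geometry.R landmarks.R
NULL

#' Cranio-caudal distance
#'
#' Euclidean distance between the lung apex and the (derived) diaphragm
#' apex of the same frame; indexes diaphragm motion.
#'
#' @param lungApex,diaphragmApex numeric length-2 points (mm).
#' @return distance in mm.
#' @export
ccDistance <- function(lungApex, diaphragmApex)
  sqrt(sum((lungApex - diaphragmApex)^2))

#' Anterior-posterior distance
#'
#' Longest front-to-back extent of the lung: the x range of the contour in
#' the orientation-normalized frame. Measured along the fixed x axis rather
#' than the ellipse minor axis, so it is stable when the per-frame ellipse
#' fit rotates slightly.
#'
#' @param contour a [LungContour-class].
#' @return extent in mm.
#' @export
apDistance <- function(contour) {
  v <- vertices(contour)
  max(v[, 1]) - min(v[, 1])
}

#' Lung area
#'
#' Area of the segmentation (absolute shoelace area of the contour).
#'
#' @param contour a [LungContour-class].
#' @return area in mm^2.
#' @export
lungArea <- function(contour) abs(polygonArea(vertices(contour)))

#' Diaphragm area (signed)
#'
#' Area between the diaphragm contour and the straight line connecting the
#' costophrenic angles. Positive when the dome bulges toward the lung
#' interior (the left of the anterior-to-posterior chord direction), so a
#' dome that inverts caudally yields a negative area and an S-shaped
#' diaphragm a net signed area.
#'
#' @param dia a [DiaphragmContour-class].
#' @return signed area in mm^2.
#' @export
diaphragmArea <- function(dia) {
  pts <- dia@points
  ## closing edge of the shoelace loop is exactly the chord; the traversal
  ## anterior -> posterior puts a lung-ward bulge on a clockwise loop,
  ## hence the sign flip
  -polygonArea(pts)
}

#' Diaphragm height (signed)
#'
#' Perpendicular distance from the diaphragm apex to the line joining the
#' costophrenic angles; positive toward the lung interior.
#'
#' @param apex the (derived) diaphragm apex point.
#' @param anterior,posterior the costophrenic angle points.
#' @return signed distance in mm.
#' @export
diaphragmHeight <- function(apex, anterior, posterior) {
  if (all(anterior == posterior)) stop("costophrenic angles coincide")
  as.numeric(signedChordDistance(matrix(apex, 1), anterior, posterior))
}

#' Costophrenic corner displacement
#'
#' Net Euclidean displacement of the selected costophrenic angle between
#' the end-expiration and end-inspiration frames. The summed frame-to-frame
#' path length is also returned as a jitter-sensitive diagnostic.
#'
#' @param landmarks list of [LandmarkSet-class] (one per frame).
#' @param which `"anterior"` or `"posterior"`.
#' @param endExpiration,endInspiration frame indices of the breath-hold
#'   states.
#' @return list with `net` (mm) and `path` (mm).
#' @export
cornerDisplacement <- function(landmarks, which = c("anterior", "posterior"),
                               endExpiration = 1L,
                               endInspiration = length(landmarks)) {
  which <- match.arg(which)
  slot <- if (which == "anterior") "anteriorAngle" else "posteriorAngle"
  pts <- t(vapply(landmarks, methods::slot, numeric(2), slot))
  rng <- endExpiration:endInspiration
  seg <- sqrt(diff(pts[rng, 1])^2 + diff(pts[rng, 2])^2)
  net <- sqrt(sum((pts[endInspiration, ] - pts[endExpiration, ])^2))
  list(net = net, path = sum(seg))
}

#' Per-frame outcome measures
#'
#' The five frame-level quantities feeding the subject ratios: CC distance,
#' AP distance, lung area, diaphragm area and diaphragm height. CC and DH
#' use the derived diaphragm apex, which is stable across frames; the raw
#' apex is retained in the landmark export for diagnostics.
#'
#' @param contour a [LungContour-class].
#' @param landmarks the frame's completed [LandmarkSet-class].
#' @param dia the frame's [DiaphragmContour-class].
#' @return one-row data.frame: `frame_index`, `cc_mm`, `ap_mm`,
#'   `lung_area_mm2`, `da_mm2`, `dh_mm`.
#' @export
measureFrame <- function(contour, landmarks, dia) {
  data.frame(
    frame_index = landmarks@frameIndex,
    cc_mm = ccDistance(landmarks@lungApex, landmarks@apexDerived),
    ap_mm = apDistance(contour),
    lung_area_mm2 = lungArea(contour),
    da_mm2 = diaphragmArea(dia),
    dh_mm = diaphragmHeight(landmarks@apexDerived, landmarks@anteriorAngle,
                            landmarks@posteriorAngle))
}

#' Inspiration/expiration outcome ratios
#'
#' Ratios are end-inspiration value divided by end-expiration value, the
#' per-subject normalization for anatomical size; the CC-AP ratio is the CC
#' ratio divided by the AP ratio. A flat expiratory diaphragm makes the DA
#' and DH ratios ill-conditioned, so when the expiratory |DH| falls below
#' `dhThresholdMM` both are reported `NA` and flagged undefined rather than
#' returned as near-infinite values. A sign change of DA or DH between the
#' two frames (paradoxical dome inversion) is flagged, not suppressed.
#'
#' @param expiration,inspiration one-row frame-outcome data.frames from
#'   [measureFrame()].
#' @param dhThresholdMM minimum expiratory |DH| in mm for defined DA/DH
#'   ratios (default 0.5).
#' @return one-row data.frame of ratios and flags.
#' @export
computeRatios <- function(expiration, inspiration, dhThresholdMM = 0.5) {
  stopifnot(expiration$cc_mm > 0, expiration$ap_mm > 0,
            expiration$lung_area_mm2 > 0)
  ccR <- inspiration$cc_mm / expiration$cc_mm
  apR <- inspiration$ap_mm / expiration$ap_mm
  areaR <- inspiration$lung_area_mm2 / expiration$lung_area_mm2
  defined <- abs(expiration$dh_mm) >= dhThresholdMM
  data.frame(
    cc_ratio = ccR,
    ap_ratio = apR,
    cc_ap_ratio = ccR / apR,
    area_ratio = areaR,
    da_ratio = if (defined && expiration$da_mm2 != 0)
      inspiration$da_mm2 / expiration$da_mm2 else NA_real_,
    dh_ratio = if (defined) inspiration$dh_mm / expiration$dh_mm else NA_real_,
    dh_defined = defined,
    sign_flip = defined &&
      (sign(inspiration$dh_mm) != sign(expiration$dh_mm) ||
         sign(inspiration$da_mm2) != sign(expiration$da_mm2)))
}

#' Measure a full frame series
#'
#' End-to-end measurement of one subject: landmark detection on every
#' frame, per-frame outcomes, inspiration/expiration ratios and the
#' costophrenic-angle displacements.
#'
#' @param series a [FrameSeries-class].
#' @param dhThresholdMM passed to [computeRatios()].
#' @return list with `record` (one-row subject data.frame: subject_id, six
#'   ratios, displacements, flags), `frames` (per-frame outcome
#'   data.frame), `landmarks` and `medianFraction`.
#' @export
measureSeries <- function(series, dhThresholdMM = 0.5) {
  sl <- seriesLandmarks(series)
  frames <- do.call(rbind, lapply(seq_along(series@contours), function(i)
    measureFrame(series@contours[[i]], sl$landmarks[[i]], sl$diaphragms[[i]])))
  iExp <- series@endExpiration
  iInsp <- series@endInspiration
  ratios <- computeRatios(frames[iExp, ], frames[iInsp, ],
                          dhThresholdMM = dhThresholdMM)
  ant <- cornerDisplacement(sl$landmarks, "anterior", iExp, iInsp)
  post <- cornerDisplacement(sl$landmarks, "posterior", iExp, iInsp)
  record <- cbind(
    data.frame(subject_id = series@subjectId),
    ratios,
    data.frame(ant_displacement_mm = ant$net, post_displacement_mm = post$net,
               ant_path_mm = ant$path, post_path_mm = post$path))
  list(record = record, frames = frames, landmarks = sl$landmarks,
       medianFraction = sl$medianFraction)
}
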