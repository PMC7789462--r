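#' @import methods
NULL

#' Lung contour
#'
#' An ordered, implicitly closed polygon of lung-outline points in physical
#' coordinates (mm). The package frame has x increasing anterior to
#' posterior and y increasing caudal to cranial; contours extracted from
#' masks are normalized to this frame and stored counter-clockwise.
#'
#' @slot vertices numeric matrix, n x 2, columns x and y in mm; the first
#'   vertex is not repeated.
#' @slot frameIndex integer position of the frame in its series (1-based).
#' @export
setClass("LungContour",
  representation(vertices = "matrix", frameIndex = "integer"),
  prototype(frameIndex = NA_integer_))

setValidity("LungContour", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2) return("vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 3) return("a contour needs at least 3 vertices")
  if (any(!is.finite(v))) return("vertices must be finite")
  TRUE
})

#' Mask frame
#'
#' One binary lung segmentation raster with its physical pixel spacing.
#' Row 1 of the pixel matrix is the cranial image edge. The orientation flag
#' records on which image side the anterior chest wall lies; contour
#' extraction flips x as needed so anterior is always at smaller x.
#'
#' @slot pixels numeric/logical matrix; any nonzero value is foreground.
#' @slot spacingMM numeric length 2, (row, col) pixel spacing in mm.
#' @slot frameIndex integer, 1-based index in the acquisition order.
#' @slot orientation character, `"anterior_left"` or `"anterior_right"`.
#' @export
setClass("MaskFrame",
  representation(pixels = "matrix", spacingMM = "numeric",
                 frameIndex = "integer", orientation = "character"))

setValidity("MaskFrame", function(object) {
  if (length(object@spacingMM) != 2 || any(object@spacingMM <= 0))
    return("spacingMM must be two strictly positive values (row, col)")
  if (!object@orientation %in% c("anterior_left", "anterior_right"))
    return("orientation must be 'anterior_left' or 'anterior_right'")
  TRUE
})

#' Frame series
#'
#' The ordered respiratory sequence of one subject: lung contours from
#' end-expiration to end-inspiration, with the two breath-hold frames
#' identified. By default the first frame is end-expiration and the last
#' end-inspiration, matching a dynamic forced-inspiration acquisition.
#'
#' @slot contours list of [LungContour-class], acquisition order.
#' @slot endExpiration integer index (1-based) of the end-expiration frame.
#' @slot endInspiration integer index of the end-inspiration frame.
#' @slot spacingMM numeric length 2; `NA` for exact-polygon series.
#' @slot orientation character; orientation flag shared by all frames.
#' @slot subjectId character scalar.
#' @export
setClass("FrameSeries",
  representation(contours = "list", endExpiration = "integer",
                 endInspiration = "integer", spacingMM = "numeric",
                 orientation = "character", subjectId = "character"),
  prototype(spacingMM = c(NA_real_, NA_real_), orientation = "anterior_left",
            subjectId = "subject"))

setValidity("FrameSeries", function(object) {
  n <- length(object@contours)
  if (n < 2) return("a series needs at least 2 frames")
  if (!all(vapply(object@contours, is, logical(1), "LungContour")))
    return("contours must all be LungContour objects")
  if (object@endExpiration < 1 || object@endExpiration > n ||
      object@endInspiration < 1 || object@endInspiration > n)
    return("end-expiration/inspiration indices out of range")
  if (object@endExpiration == object@endInspiration)
    return("end-expiration and end-inspiration frames must differ")
  TRUE
})

#' Ellipse fit of a lung outline
#'
#' Orientation model of one contour: best-fit ellipse by direct algebraic
#' least squares, or the principal axes of the vertex scatter when the
#' algebraic fit is degenerate (`method == "principal"`). The axis angle is
#' measured from the +y (cranio-caudal) axis toward +x, in (-pi/2, pi/2].
#'
#' @slot center numeric length 2 (x, y) mm.
#' @slot semiMajorMM,semiMinorMM positive reals, semi-axis lengths in mm.
#' @slot angleRad major-axis angle from the +y axis, radians.
#' @slot method `"direct"` or `"principal"`.
#' @export
setClass("EllipseFit",
  representation(center = "numeric", semiMajorMM = "numeric",
                 semiMinorMM = "numeric", angleRad = "numeric",
                 method = "character"))

setValidity("EllipseFit", function(object) {
  if (object@semiMajorMM < object@semiMinorMM || object@semiMinorMM <= 0)
    return("semi-axes must satisfy semiMajorMM >= semiMinorMM > 0")
  if (object@angleRad <= -pi / 2 || object@angleRad > pi / 2)
    return("angleRad must lie in (-pi/2, pi/2]")
  TRUE
})

#' Diaphragm contour
#'
#' The caudal portion of a lung contour between the two costophrenic
#' angles, oriented anterior to posterior, with cumulative arc length.
#'
#' @slot points numeric matrix, polyline from the anterior to the posterior
#'   costophrenic angle.
#' @slot arcLengthMM nondecreasing cumulative arc length, starting at 0.
#' @export
setClass("DiaphragmContour",
  representation(points = "matrix", arcLengthMM = "numeric"))

setValidity("DiaphragmContour", function(object) {
  if (nrow(object@points) < 2) return("diaphragm contour needs >= 2 points")
  if (length(object@arcLengthMM) != nrow(object@points))
    return("arcLengthMM must have one entry per point")
  if (any(diff(object@arcLengthMM) < 0)) return("arc length must be nondecreasing")
  TRUE
})

#' Landmark set
#'
#' The per-frame anatomical reference points: lung apex, area centroid,
#' anterior and posterior costophrenic angles, the raw diaphragm apex
#' (furthest point from the inter-corner chord) with its arc-length
#' fraction, and the derived diaphragm apex placed at the series-median
#' fraction. `flatDiaphragm` flags frames whose diaphragm is collinear with
#' the chord, where the raw apex is undefined and reported at fraction 0.5.
#'
#' @slot lungApex,centroid,anteriorAngle,posteriorAngle,apexRaw,apexDerived
#'   numeric length-2 points (x, y) mm; `apexDerived` is `NA` until the
#'   series-level median fraction has been applied.
#' @slot apexRawFraction arc-length fraction of the raw apex in [0, 1].
#' @slot flatDiaphragm logical degenerate-diaphragm flag.
#' @slot frameIndex integer.
#' @export
setClass("LandmarkSet",
  representation(lungApex = "numeric", centroid = "numeric",
                 anteriorAngle = "numeric", posteriorAngle = "numeric",
                 apexRaw = "numeric", apexRawFraction = "numeric",
                 apexDerived = "numeric", flatDiaphragm = "logical",
                 frameIndex = "integer"),
  prototype(apexDerived = c(NA_real_, NA_real_), flatDiaphragm = FALSE,
            frameIndex = NA_integer_))

setValidity("LandmarkSet", function(object) {
  if (object@anteriorAngle[1] >= object@posteriorAngle[1])
    return("anterior costophrenic angle must lie at smaller x than the posterior one")
  if (object@apexRawFraction < 0 || object@apexRawFraction > 1)
    return("apexRawFraction must lie in [0, 1]")
  TRUE
})

#' Phantom parameters
#'
#' Ground-truth geometry and motion of one synthetic subject. The
#' end-expiration lung is a half-ellipse cap over a rectangle with a caudal
#' diaphragm dome spanning the basal corners; end-inspiration extents follow
#' from the true outcome ratios, and intermediate frames interpolate
#' geometrically. See the package vignette for the shape family and its
#' closed-form outcomes.
#'
#' @slot ccExpMM,apExpMM,domeHeightExpMM baseline end-expiration
#'   cranio-caudal distance, anterior-posterior extent and dome height (mm).
#' @slot capFracExp fraction of the supra-chord height occupied by the
#'   half-ellipse cap at end-expiration.
#' @slot domeFullnessExp expiratory dome fullness, area / (chord x height),
#'   in (0.05, 0.95); the inspiratory fullness follows from the DA target.
#' @slot ccRatio,ccApRatio,areaRatio,daRatio,dhRatio true
#'   inspiration/expiration outcome ratios (the AP ratio is
#'   `ccRatio / ccApRatio`).
#' @slot postDisplacementMM true net displacement of the posterior
#'   costophrenic angle (mm).
#' @slot nFrames frames from end-expiration to end-inspiration.
#' @slot verticesPerContour polygon sampling density.
#' @slot rasterSpacingMM pixel spacing used when masks are rendered.
#' @slot jitterSdMM sd of Gaussian vertex jitter (0 = exact geometry).
#' @slot seed integer seed for jitter.
#' @export
setClass("PhantomParams",
  representation(ccExpMM = "numeric", apExpMM = "numeric",
                 domeHeightExpMM = "numeric", capFracExp = "numeric",
                 domeFullnessExp = "numeric",
                 ccRatio = "numeric", ccApRatio = "numeric",
                 areaRatio = "numeric", daRatio = "numeric",
                 dhRatio = "numeric", postDisplacementMM = "numeric",
                 nFrames = "integer", verticesPerContour = "integer",
                 rasterSpacingMM = "numeric", jitterSdMM = "numeric",
                 seed = "integer"))

setValidity("PhantomParams", function(object) {
  if (any(c(object@ccExpMM, object@apExpMM, object@domeHeightExpMM) <= 0))
    return("extents must be positive")
  if (object@domeHeightExpMM >= object@ccExpMM)
    return("dome height must be smaller than the cranio-caudal extent")
  if (any(c(object@ccRatio, object@ccApRatio, object@areaRatio,
            object@daRatio, object@dhRatio) <= 0))
    return("true ratios must be positive")
  if (object@capFracExp <= 0 || object@capFracExp >= 1)
    return("capFracExp must lie in (0, 1)")
  if (object@domeFullnessExp <= 0.05 || object@domeFullnessExp >= 0.95)
    return("domeFullnessExp must lie in (0.05, 0.95)")
  if (object@nFrames < 2) return("nFrames must be >= 2")
  if (object@verticesPerContour < 64) return("verticesPerContour must be >= 64")
  if (object@rasterSpacingMM <= 0) return("rasterSpacingMM must be positive")
  TRUE
})

#' Cohort specification
#'
#' Group structure and between-subject variability for synthetic cohorts.
#' Defaults mirror a three-group study design: patients with decreased
#' supine spirometry (n = 22), patients with normal spirometry (n = 13) and
#' healthy controls (n = 18), with simulated age, sex and pulmonary
#' function covariates linked to the subject's true cranio-caudal ratio.
#'
#' @slot groups data.frame with columns `label`, `n`, `preset`.
#' @slot betweenSubjectSd named numeric: `cc`, `ap`, `dh`, `area`,
#'   `postDisp` latent/independent sds on the true ratios.
#' @slot pftNoiseSd named numeric: residual sds of the simulated
#'   pulmonary-function values (% predicted).
#' @export
setClass("CohortSpec",
  representation(groups = "data.frame", betweenSubjectSd = "numeric",
                 pftNoiseSd = "numeric"))

setValidity("CohortSpec", function(object) {
  need <- c("label", "n", "preset")
  if (!all(need %in% names(object@groups)))
    return("groups needs columns label, n, preset")
  if (any(object@groups$n < 1)) return("each group needs n >= 1")
  if (any(object@betweenSubjectSd < 0) || any(object@pftNoiseSd < 0))
    return("sds must be nonnegative")
  TRUE
})

#' Intraclass correlation result
#'
#' Single-measurement absolute-agreement ICC from the two-way mean squares,
#' the form used to validate automatic against manual measurements when
#' each rater contributes one measurement per subject.
#'
#' @slot icc estimate in [-1, 1]; `NaN` (with `defined = FALSE`) for a
#'   constant matrix.
#' @slot modelTag fixed descriptor of the estimator.
#' @slot nSubjects,nRaters design size.
#' @slot msSubject,msRater,msError two-way mean squares.
#' @slot defined logical.
#' @export
setClass("ICCResult",
  representation(icc = "numeric", modelTag = "character",
                 nSubjects = "integer", nRaters = "integer",
                 msSubject = "numeric", msRater = "numeric",
                 msError = "numeric", defined = "logical"))

#' Group comparison result
#'
#' Covariate-adjusted comparison of one outcome across subject groups by
#' ordinary least squares: overall group effect (joint F test on the group
#' indicators) and all pairwise contrasts, judged against a Bonferroni
#' pairwise threshold.
#'
#' @slot outcomeName character.
#' @slot overallP joint F-test p-value for the group factor.
#' @slot pairwise data.frame: `group_a`, `group_b`, `estimate`, `se`, `p`,
#'   `significant`.
#' @slot alphaPairwise pairwise significance level (0.017 for three groups).
#' @slot covariates character vector of adjusted covariates.
#' @slot diagnostics list of residual summaries.
#' @export
setClass("GroupComparisonResult",
  representation(outcomeName = "character", overallP = "numeric",
                 pairwise = "data.frame", alphaPairwise = "numeric",
                 covariates = "character", diagnostics = "list"))
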