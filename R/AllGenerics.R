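#' @include AllClasses.R
NULL

#' Accessors for contour and series objects
#'
#' @param object a [LungContour-class], [FrameSeries-class] or
#'   [DiaphragmContour-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "LungContour", function(object) object@vertices)
#' @rdname accessors
#' @export
setMethod("vertices", "DiaphragmContour", function(object) object@points)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSeries", function(object) length(object@contours))

#' @rdname accessors
#' @export
setGeneric("contours", function(object) standardGeneric("contours"))
#' @rdname accessors
#' @export
setMethod("contours", "FrameSeries", function(object) object@contours)

#' @rdname accessors
#' @export
setGeneric("endExpiration", function(object) standardGeneric("endExpiration"))
#' @rdname accessors
#' @export
setMethod("endExpiration", "FrameSeries", function(object) object@endExpiration)

#' @rdname accessors
#' @export
setGeneric("endInspiration", function(object) standardGeneric("endInspiration"))
#' @rdname accessors
#' @export
setMethod("endInspiration", "FrameSeries", function(object) object@endInspiration)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "FrameSeries", function(object) object@subjectId)

setMethod("show", "LungContour", function(object) {
  cat("LungContour with", nrow(object@vertices), "vertices;",
      sprintf("area %.1f mm^2", abs(polygonArea(object@vertices))), "\n")
})

setMethod("show", "FrameSeries", function(object) {
  cat("FrameSeries '", object@subjectId, "': ", length(object@contours),
      " frames (end-expiration ", object@endExpiration,
      ", end-inspiration ", object@endInspiration, ")\n", sep = "")
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(
    "EllipseFit (%s): center (%.1f, %.1f) mm, semi-axes %.1f/%.1f mm, angle %.3f rad\n",
    object@method, object@center[1], object@center[2],
    object@semiMajorMM, object@semiMinorMM, object@angleRad))
})

setMethod("show", "LandmarkSet", function(object) {
  fmt <- function(p) sprintf("(%.1f, %.1f)", p[1], p[2])
  cat("LandmarkSet frame", object@frameIndex, "\n",
      " lung apex", fmt(object@lungApex),
      " centroid", fmt(object@centroid), "\n",
      " anterior angle", fmt(object@anteriorAngle),
      " posterior angle", fmt(object@posteriorAngle), "\n",
      " raw apex", fmt(object@apexRaw),
      sprintf(" (fraction %.3f)", object@apexRawFraction),
      if (all(is.finite(object@apexDerived)))
        paste(" derived apex", fmt(object@apexDerived)) else "", "\n")
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC (%s): %.4f  [n = %d subjects, k = %d raters]%s\n",
              object@modelTag, object@icc, object@nSubjects, object@nRaters,
              if (!object@defined) "  (undefined: constant measurements)" else ""))
})

setMethod("show", "GroupComparisonResult", function(object) {
  cat("Group comparison for", object@outcomeName, "\n")
  cat(sprintf(" overall p = %.4g (joint F test on group indicators)\n",
              object@overallP))
  if (length(object@covariates))
    cat(" adjusted for:", paste(object@covariates, collapse = ", "), "\n")
  cat(sprintf(" pairwise contrasts (significance at p <= %.3f):\n",
              object@alphaPairwise))
  print(object@pairwise, row.names = FALSE)
})

setMethod("show", "PhantomParams", function(object) {
  cat(sprintf(
    "PhantomParams: exp CC %.0f mm, AP %.0f mm, dome %.0f mm; true ratios cc %.2f, cc-ap %.2f, area %.2f, da %.2f, dh %.2f; posterior displacement %.1f mm; %d frames\n",
    object@ccExpMM, object@apExpMM, object@domeHeightExpMM, object@ccRatio,
    object@ccApRatio, object@areaRatio, object@daRatio, object@dhRatio,
    object@postDisplacementMM, object@nFrames))
})
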