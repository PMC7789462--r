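#' @include AllClasses.R geometry.R
NULL

#' Construct a mask frame
#'
#' @param pixels matrix; any nonzero entry is foreground. Row 1 is the
#'   cranial image edge.
#' @param spacingMM numeric length 2, (row, col) pixel spacing in mm.
#' @param frameIndex 1-based frame position.
#' @param orientation `"anterior_left"` if the anterior chest wall is on the
#'   low-column side of the image, `"anterior_right"` otherwise.
#' @return a [MaskFrame-class].
#' @export
maskFrame <- function(pixels, spacingMM = c(1, 1), frameIndex = 1L,
                      orientation = c("anterior_left", "anterior_right")) {
  orientation <- match.arg(orientation)
  new("MaskFrame", pixels = (pixels != 0) * 1, spacingMM = as.numeric(spacingMM),
      frameIndex = as.integer(frameIndex), orientation = orientation)
}

#' Construct a lung contour
#'
#' @param vertices n x 2 matrix of (x, y) mm, implicitly closed. Stored
#'   counter-clockwise.
#' @param frameIndex optional 1-based frame index.
#' @return a [LungContour-class].
#' @export
lungContour <- function(vertices, frameIndex = NA_integer_) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  new("LungContour", vertices = ensureCounterClockwise(vertices),
      frameIndex = as.integer(frameIndex))
}

#' Assemble a frame series from contours
#'
#' The first frame defaults to end-expiration and the last to
#' end-inspiration, the breath-hold states bounding a dynamic forced
#' inspiration; both can be overridden per subject.
#'
#' @param contours list of [LungContour-class] in acquisition order.
#' @param endExpiration,endInspiration 1-based frame indices of the two
#'   breath-hold states.
#' @param spacingMM pixel spacing, or `NA` for exact polygons.
#' @param orientation orientation flag shared by all frames.
#' @param subjectId subject label.
#' @return a [FrameSeries-class].
#' @export
frameSeries <- function(contours, endExpiration = 1L,
                        endInspiration = length(contours),
                        spacingMM = c(NA_real_, NA_real_),
                        orientation = "anterior_left",
                        subjectId = "subject") {
  new("FrameSeries", contours = contours,
      endExpiration = as.integer(endExpiration),
      endInspiration = as.integer(endInspiration),
      spacingMM = as.numeric(spacingMM), orientation = orientation,
      subjectId = as.character(subjectId))
}

#' Extract the lung contour from a binary mask
#'
#' Traces the boundary of the largest connected foreground component at the
#' 0.5 iso-level (marching squares with linear interpolation), which avoids
#' the staircase bias of pixel-edge tracing in area and distance measures.
#' Smaller components (segmentation specks) and interior holes are
#' discarded; component ties are broken by first raster-scan occurrence.
#' Pixel coordinates are converted to mm in the package frame: x anterior
#' to posterior, y caudal to cranial, with image row 1 on the cranial side.
#'
#' @param frame a [MaskFrame-class] with at least one foreground pixel.
#' @return a [LungContour-class], counter-clockwise.
#' @export
extractContour <- function(frame) {
  stopifnot(is(frame, "MaskFrame"))
  mask <- frame@pixels
  if (!any(mask != 0))
    stop("frame ", frame@frameIndex, " has no foreground pixels")
  lab <- EBImage::bwlabel(mask != 0)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)            # first max = earliest raster-scan label
  m <- (lab == keep) * 1

  ## orientation normalization: anterior at smaller x
  if (frame@orientation == "anterior_right")
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]

  nr <- nrow(m); nc <- ncol(m)
  spr <- frame@spacingMM[1]; spc <- frame@spacingMM[2]
  ## pad with background so boundary components produce closed loops
  z <- matrix(0, nc + 2L, nr + 2L)
  ## z[xi, yi] with x along columns of the image and y ascending caudal->cranial
  z[2:(nc + 1L), 2:(nr + 1L)] <- t(m[nr:1, , drop = FALSE])
  xs <- ((0:(nc + 1L)) - 0.5) * spc
  ys <- ((0:(nr + 1L)) - 0.5) * spr
  loops <- grDevices::contourLines(xs, ys, z, levels = 0.5)
  if (!length(loops)) stop("contour extraction failed")
  areas <- vapply(loops, function(l) abs(polygonArea(cbind(l$x, l$y))), 0)
  l <- loops[[which.max(areas)]]       # outer boundary; holes are smaller
  xy <- cbind(l$x, l$y)
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
    xy <- xy[-nrow(xy), , drop = FALSE]
  lungContour(xy, frameIndex = frame@frameIndex)
}

#' Read a mask stack into a frame series
#'
#' Accepts either a directory of PNG frames (sorted lexicographically; any
#' nonzero pixel is foreground) or a NIfTI volume whose third axis is time.
#' For NIfTI input the in-plane spacing defaults to the header pixdim and
#' can be overridden.
#'
#' @param path directory of PNG files, or a `.nii`/`.nii.gz` file.
#' @param spacingMM (row, col) spacing in mm; required for PNG, optional
#'   for NIfTI.
#' @param orientation orientation flag for all frames.
#' @param endExpiration,endInspiration breath-hold frame overrides
#'   (defaults: first and last frame).
#' @param subjectId subject label (defaults to the path's base name).
#' @return a [FrameSeries-class].
#' @export
readMaskStack <- function(path, spacingMM = NULL,
                          orientation = c("anterior_left", "anterior_right"),
                          endExpiration = 1L, endInspiration = NULL,
                          subjectId = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(subjectId)) subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 2)
      stop("'", path, "' contains fewer than 2 PNG frames")
    if (is.null(spacingMM))
      stop("spacingMM must be supplied for PNG stacks")
    masks <- lapply(files, function(f) {
      px <- png::readPNG(f)
      if (length(dim(px)) == 3) px <- px[, , 1]
      px
    })
  } else if (file.exists(path)) {
    if (!grepl("\\.nii(\\.gz)?$", path))
      stop("unsupported input '", path, "': expected a PNG directory or NIfTI volume")
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) != 3 || d[3] < 2)
      stop("NIfTI volume must be 3D with time on the third axis (>= 2 frames)")
    if (is.null(spacingMM)) {
      pd <- RNifti::pixdim(vol)
      spacingMM <- c(pd[1], pd[2])
    }
    masks <- lapply(seq_len(d[3]), function(t) vol[, , t])
  } else {
    stop("input '", path, "' does not exist")
  }
  contoursList <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    fr <- maskFrame(masks[[i]], spacingMM = spacingMM, frameIndex = i,
                    orientation = orientation)
    contoursList[[i]] <- extractContour(fr)
  }
  if (is.null(endInspiration)) endInspiration <- length(contoursList)
  frameSeries(contoursList, endExpiration = endExpiration,
              endInspiration = endInspiration, spacingMM = spacingMM,
              orientation = orientation, subjectId = subjectId)
}

#' Write the vertices of a series to CSV
#'
#' Long-format dump with columns `frame_index`, `vertex`, `x_mm`, `y_mm`.
#'
#' @param series a [FrameSeries-class].
#' @param file output CSV path.
#' @export
writeContours <- function(series, file) {
  rows <- do.call(rbind, lapply(seq_along(series@contours), function(i) {
    v <- series@contours[[i]]@vertices
    data.frame(frame_index = i, vertex = seq_len(nrow(v)),
               x_mm = v[, 1], y_mm = v[, 2])
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
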