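#' @describeIn markerIds ids of 3D markers
#' @export
setMethod("markerIds", "MarkerSet3D", function(x) x@ids)

#' @describeIn markerIds ids of 2D markers
#' @export
setMethod("markerIds", "MarkerSet2D", function(x) x@ids)

#' @describeIn markerPositions nm positions of 3D markers (columns x, y, z)
#' @export
setMethod("markerPositions", "MarkerSet3D", function(x) {
  m <- x@positions
  rownames(m) <- x@ids
  m
})

#' @describeIn markerPositions nm positions of 2D markers (columns x, y)
#' @export
setMethod("markerPositions", "MarkerSet2D", function(x) {
  m <- x@positions
  rownames(m) <- x@ids
  m
})

#' Channels of the markers in a 3D set
#' @param x a [MarkerSet3D-class].
#' @return character vector of channel labels.
#' @export
markerChannels <- function(x) {
  stopifnot(is(x, "MarkerSet3D"))
  x@channels
}

#' @describeIn centroid mean 3D position (Eq.-style arithmetic mean per
#'   coordinate)
#' @export
setMethod("centroid", "MarkerSet3D", function(x) {
  if (nrow(x@positions) == 0L)
    stop("centroid of an empty marker set is undefined")
  colMeans(x@positions)
})

#' @describeIn centroid mean 2D position
#' @export
setMethod("centroid", "MarkerSet2D", function(x) {
  if (nrow(x@positions) == 0L)
    stop("centroid of an empty marker set is undefined")
  colMeans(x@positions)
})

#' @describeIn nMarkers markers in a 3D set
#' @export
setMethod("nMarkers", "MarkerSet3D", function(x) length(x@ids))

#' @describeIn nMarkers markers in a 2D set
#' @export
setMethod("nMarkers", "MarkerSet2D", function(x) length(x@ids))

#' @describeIn nMarkers pairs in a correspondence
#' @export
setMethod("nMarkers", "Correspondence", function(x) length(x@ids3d))

#' @describeIn anglesDeg degrees from an EulerAngles object
#' @export
setMethod("anglesDeg", "EulerAngles", function(x)
  c(thetaX = x@thetaX, thetaY = x@thetaY, thetaZ = x@thetaZ) * 180 / pi)

#' @describeIn anglesDeg degrees of a registration's solved angles
#' @export
setMethod("anglesDeg", "RegistrationResult",
          function(x) anglesDeg(x@angles))

#' @describeIn anglesRad radians from an EulerAngles object
#' @export
setMethod("anglesRad", "EulerAngles", function(x)
  c(thetaX = x@thetaX, thetaY = x@thetaY, thetaZ = x@thetaZ))

#' @describeIn anglesRad radians of a registration's solved angles
#' @export
setMethod("anglesRad", "RegistrationResult",
          function(x) anglesRad(x@angles))

#' @describeIn registrationSD RMS residual of the fit, nm
#' @export
setMethod("registrationSD", "RegistrationResult", function(x) x@sd)

#' @describeIn markerDeviations per-marker residuals of the fit, nm
#' @export
setMethod("markerDeviations", "RegistrationResult",
          function(x) x@perMarkerDeviation)

#' Ids of markers kept in the fit
#' @param x a [RegistrationResult-class].
#' @return character vector.
#' @export
usedIds <- function(x) x@usedIds

#' Ids of markers rejected during refinement
#' @param x a [RegistrationResult-class].
#' @return character vector.
#' @export
rejectedIds <- function(x) x@rejectedIds

#' 3D marker set as used at the optimum
#'
#' After iterated refinement the z coordinates of the kept markers may
#' have been re-optimized; this returns the marker set the final solve
#' actually used (NULL for a plain single solve that did not store it).
#'
#' @param x a [RegistrationResult-class].
#' @return a [MarkerSet3D-class] or NULL.
#' @export
refinedMarkers <- function(x) x@markers3d

#' Pixel size of a FIB image or 2D marker set
#' @param x a [FibImage-class] or [MarkerSet2D-class].
#' @return nm per pixel.
#' @export
pixelSize <- function(x) {
  if (is(x, "FibImage")) x@pixelSize else x@pixelSize
}

#' Voxel pitch of a stack
#' @param x a [VolumeStack-class].
#' @return named numeric c(x=, y=, z=), nm.
#' @export
voxelPitch <- function(x) x@pitch

setMethod("show", "EulerAngles", function(object) {
  d <- anglesDeg(object)
  cat(sprintf("EulerAngles (Z-Y-X): thetaX=%.3f deg, thetaY=%.3f deg, thetaZ=%.3f deg\n",
              d[1], d[2], d[3]))
})

setMethod("show", "MarkerSet3D", function(object) {
  cat(sprintf("MarkerSet3D with %d marker(s)", nMarkers(object)))
  if (nMarkers(object) > 0L) {
    cat(sprintf(" [channels: %s]\n",
                paste(unique(object@channels), collapse = ", ")))
    print(utils::head(markerPositions(object), 5))
    if (nMarkers(object) > 5L) cat("...\n")
  } else cat("\n")
})

setMethod("show", "MarkerSet2D", function(object) {
  cat(sprintf("MarkerSet2D with %d marker(s)", nMarkers(object)))
  if (!is.na(object@pixelSize))
    cat(sprintf(" (pixel size %.1f nm)", object@pixelSize))
  cat("\n")
  if (nMarkers(object) > 0L) {
    print(utils::head(markerPositions(object), 5))
    if (nMarkers(object) > 5L) cat("...\n")
  }
})

setMethod("show", "Correspondence", function(object) {
  cat(sprintf("Correspondence with %d pair(s)\n", nMarkers(object)))
})

setMethod("show", "RegistrationResult", function(object) {
  d <- anglesDeg(object)
  cat("RegistrationResult\n")
  cat(sprintf("  angles (deg): thetaX=%.4f thetaY=%.4f thetaZ=%.4f\n",
              d[1], d[2], d[3]))
  cat(sprintf("  SD: %.3f nm over %d marker(s); %d rejected\n",
              object@sd, length(object@usedIds),
              length(object@rejectedIds)))
  if (object@scale != 1)
    cat(sprintf("  fitted scale: %.6f\n", object@scale))
  if (object@mirrorAmbiguity)
    cat("  note: near-tied mirror solution exists (planar configuration)\n")
  cat(sprintf("  converged: %s (%d iterations)\n",
              object@converged, object@nIterations))
})

setMethod("show", "VolumeStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeStack %d x %d x %d (y,x,z), pitch %g/%g/%g nm (x/y/z), channel '%s'\n",
              d[1], d[2], d[3], object@pitch["x"], object@pitch["y"],
              object@pitch["z"], object@channel))
})

setMethod("show", "FibImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("FibImage %d x %d px, pixel %g nm, milling direction +y\n",
              d[1], d[2], object@pixelSize))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d bead(s), slab %g x %g x %g um, bead %g nm\n",
              nrow(object@positions), object@extents[1] / 1000,
              object@extents[2] / 1000, object@extents[3] / 1000,
              object@beadDiameter))
  d <- anglesDeg(object@trueAngles)
  cat(sprintf("  true angles (deg): %.2f %.2f %.2f; noise xy/z/fib: %g/%g/%g nm; seed %d\n",
              d[1], d[2], d[3], object@noise["sigmaXY"],
              object@noise["sigmaZ"], object@noise["sigmaFIB"],
              object@seed))
})
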