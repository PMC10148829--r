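#' Marker ids
#' @param x a marker set, correspondence or registration result.
#' @return character vector of identifiers.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' Marker positions in nanometres
#' @param x a marker set.
#' @return numeric matrix, one row per marker (columns x, y[, z]), nm.
#' @export
setGeneric("markerPositions",
           function(x) standardGeneric("markerPositions"))

#' Centroid of a marker set
#'
#' Arithmetic mean position of the markers, the translation anchor of the
#' registration model: both datasets are expressed relative to their own
#' centroid before the rotation is solved, which handles the translation
#' between the frames exactly under orthographic projection.
#'
#' @param x a [MarkerSet3D-class] or [MarkerSet2D-class].
#' @return named numeric (x, y[, z]) in nm.
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))

#' Number of markers
#' @param x a marker set or correspondence.
#' @return integer count.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' Angles of a registration, in degrees
#' @param x an [EulerAngles-class] or [RegistrationResult-class].
#' @return named numeric c(thetaX, thetaY, thetaZ) in degrees.
#' @export
setGeneric("anglesDeg", function(x) standardGeneric("anglesDeg"))

#' Angles of a registration, in radians
#' @param x an [EulerAngles-class] or [RegistrationResult-class].
#' @return named numeric c(thetaX, thetaY, thetaZ) in radians.
#' @export
setGeneric("anglesRad", function(x) standardGeneric("anglesRad"))

#' Overall registration residual (nm)
#'
#' Root-mean-square 2D distance between the projected volume markers and
#' their FIB counterparts, over the markers used in the fit.
#'
#' @param x a [RegistrationResult-class].
#' @return single numeric, nm.
#' @export
setGeneric("registrationSD", function(x) standardGeneric("registrationSD"))

#' Per-marker residual distances (nm)
#' @param x a [RegistrationResult-class].
#' @return named numeric vector, nm, one entry per used marker.
#' @export
setGeneric("markerDeviations",
           function(x) standardGeneric("markerDeviations"))
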