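#' Wrap an angle to (-pi, pi]
#' @param theta numeric vector, radians.
#' @return wrapped angles.
#' @keywords internal
wrapAngle <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))  # [-pi, pi)
  w[w == -pi] <- pi                                     # -> (-pi, pi]
  w
}

#' Create Euler angles (Z-Y-X convention)
#'
#' @param thetaX,thetaY,thetaZ rotation angles about x, y, z.  The
#'   composite rotation applies the z rotation first, then y, then x.
#' @param degrees logical; interpret the inputs as degrees (default FALSE:
#'   radians).
#' @return an [EulerAngles-class] object, each angle wrapped to (-pi, pi].
#' @examples
#' eulerAngles(10, 5, 30, degrees = TRUE)
#' @export
eulerAngles <- function(thetaX = 0, thetaY = 0, thetaZ = 0,
                        degrees = FALSE) {
  v <- unname(c(thetaX, thetaY, thetaZ))
  if (length(v) != 3L || !all(is.finite(v)))
    stop("thetaX, thetaY, thetaZ must each be a single finite number")
  if (degrees) v <- v * pi / 180
  v <- wrapAngle(v)
  new("EulerAngles", thetaX = v[1], thetaY = v[2], thetaZ = v[3])
}

#' Create a 3D marker set
#'
#' @param ids character marker identifiers (unique); defaults to
#'   \code{"m1"..."mN"}.
#' @param positions numeric matrix (or data.frame) with one row per marker
#'   and columns x, y, z in nanometres.
#' @param channels fluorescence channel per marker (recycled).
#' @return a [MarkerSet3D-class].
#' @examples
#' markerSet3D(positions = rbind(c(0, 0, 0), c(1000, 0, 500)))
#' @export
markerSet3D <- function(ids = NULL, positions, channels = "green") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  n <- nrow(positions)
  if (is.null(ids)) ids <- paste0("m", seq_len(n))
  ids <- as.character(ids)
  channels <- rep_len(as.character(channels), n)
  new("MarkerSet3D", ids = ids, positions = positions,
      channels = channels)
}

#' Create a 2D marker set
#'
#' @param ids character marker identifiers (unique); defaults to
#'   \code{"f1"..."fN"}.
#' @param positions numeric matrix (or data.frame) with columns x, y in
#'   nanometres.
#' @param pixelSize nm per FIB pixel used in the conversion (NA when the
#'   coordinates were supplied in nm directly).
#' @return a [MarkerSet2D-class].
#' @export
markerSet2D <- function(ids = NULL, positions, pixelSize = NA_real_) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y")
  n <- nrow(positions)
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  new("MarkerSet2D", ids = as.character(ids), positions = positions,
      pixelSize = as.numeric(pixelSize))
}

#' Create a 3D/2D marker correspondence
#'
#' @param ids3d,ids2d equal-length id vectors; pair i is
#'   \code{(ids3d[i], ids2d[i])}.
#' @return a [Correspondence-class].
#' @export
correspondence <- function(ids3d, ids2d = ids3d) {
  new("Correspondence", ids3d = as.character(ids3d),
      ids2d = as.character(ids2d))
}

#' Create solver options
#'
#' @param gridStepDeg coarse multi-start grid step, degrees.
#' @param boundsDeg per-angle search bounds, degrees.
#' @param tol convergence tolerance on the squared objective, nm^2.
#' @param prior [EulerAngles-class] tie-break prior for near-equivalent
#'   minima (mirror ambiguity of planar marker configurations).
#' @param fitScale fit an isotropic scale factor alongside the angles
#'   (default FALSE; the faithful model has no scale term).
#' @param nStarts number of coarse-grid nodes refined locally.
#' @return a [SolverOptions-class].
#' @export
solverOptions <- function(gridStepDeg = 15, boundsDeg = c(-90, 90),
                          tol = 1e-9, prior = eulerAngles(),
                          fitScale = FALSE, nStarts = 8L) {
  new("SolverOptions", gridStepDeg = gridStepDeg,
      boundsDeg = as.numeric(boundsDeg), tol = tol, prior = prior,
      fitScale = fitScale, nStarts = as.integer(nStarts))
}

#' Create a refinement policy
#'
#' @param outlierFactor reject markers with residual beyond this multiple
#'   of the RMS residual.
#' @param minMarkers never reject below this many markers.
#' @param zBound maximum per-marker z adjustment, nm.
#' @param maxRounds maximum refinement rounds.
#' @param sdTol stop when the residual improves by less than this (nm).
#' @return a [RefinementPolicy-class].
#' @export
refinementPolicy <- function(outlierFactor = 2, minMarkers = 4L,
                             zBound = 500, maxRounds = 10L, sdTol = 0.1) {
  new("RefinementPolicy", outlierFactor = outlierFactor,
      minMarkers = as.integer(minMarkers), zBound = zBound,
      maxRounds = as.integer(maxRounds), sdTol = sdTol)
}

#' Create a volume stack
#'
#' @param data numeric array indexed \code{[y, x, z]}.
#' @param pitch voxel pitch in nm, named c(x=, y=, z=) (an unnamed
#'   length-3 vector is taken in x, y, z order).
#' @param channel channel label.
#' @return a [VolumeStack-class].
#' @export
volumeStack <- function(data, pitch = c(x = 120, y = 120, z = 250),
                        channel = "green") {
  pitch <- as.numeric(pitch)
  names(pitch) <- c("x", "y", "z")
  new("VolumeStack", data = data, pitch = pitch, channel = channel)
}

#' Create a FIB image
#'
#' @param data numeric matrix \code{[y, x]}.
#' @param pixelSize nm per pixel.
#' @return a [FibImage-class].
#' @export
fibImage <- function(data, pixelSize) {
  new("FibImage", data = as.matrix(data),
      pixelSize = as.numeric(pixelSize))
}
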