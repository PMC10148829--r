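#' @import methods
NULL

## All physical coordinates in this package are nanometres, in a right-handed
## frame.  In the FIB image frame +y is the ion-beam milling direction.
## Conversion from voxel/pixel indices happens only at I/O boundaries:
## a voxel/pixel index is 0-based and addresses the voxel centre, so the
## physical coordinate of index i along an axis with pitch p is i * p.

#' Euler angles for the Z-Y-X rotation convention
#'
#' Holds the three rotation parameters (theta_x, theta_y, theta_z), in
#' radians, of the rigid rotation between the fluorescence-volume frame and
#' the FIB view.  The composite rotation is
#' \eqn{R = R_x(\theta_x) R_y(\theta_y) R_z(\theta_z)} applied to column
#' vectors (an active Z-Y-X rotation: z first, then y, then x).  Each angle
#' is wrapped to \eqn{(-\pi, \pi]}.
#'
#' @slot thetaX,thetaY,thetaZ single numeric angles in radians.
#' @seealso [eulerAngles()], [rotationMatrix()]
#' @exportClass EulerAngles
setClass("EulerAngles",
  representation(thetaX = "numeric", thetaY = "numeric", thetaZ = "numeric"),
  prototype(thetaX = 0, thetaY = 0, thetaZ = 0),
  validity = function(object) {
    v <- c(object@thetaX, object@thetaY, object@thetaZ)
    if (length(v) != 3L || !all(is.finite(v)))
      return("thetaX, thetaY, thetaZ must each be a single finite number")
    if (any(v <= -pi - 1e-12) || any(v > pi + 1e-12))
      return("angles must be wrapped to (-pi, pi]")
    TRUE
  })

#' Fiducial markers localized in the 3D fluorescence volume
#'
#' A set of fiducial-microsphere positions identified in the 3D cryo-SIM
#' stack, in physical nanometres.  The centroid (arithmetic mean position)
#' is derived, never stored, so it can never fall out of step with the
#' positions.
#'
#' @slot ids character vector of unique marker identifiers.
#' @slot positions numeric matrix with one row per marker and columns
#'   \code{x}, \code{y}, \code{z} (nm).
#' @slot channels character vector naming the fluorescence channel of each
#'   marker (recycled from length 1).
#' @seealso [markerSet3D()], [centroid()]
#' @exportClass MarkerSet3D
setClass("MarkerSet3D",
  representation(ids = "character", positions = "matrix",
                 channels = "character"),
  validity = function(object) {
    n <- length(object@ids)
    if (anyDuplicated(object@ids)) return("marker ids must be unique")
    if (!is.numeric(object@positions) || ncol(object@positions) != 3L)
      return("positions must be a numeric matrix with columns x, y, z")
    if (nrow(object@positions) != n)
      return("one position row per id required")
    if (n > 0L && !all(is.finite(object@positions)))
      return("positions must be finite")
    if (length(object@channels) != n)
      return("one channel per marker required")
    TRUE
  })

#' Fiducial markers localized in the 2D FIB image
#'
#' Fiducial-microsphere positions identified in the cryo-FIB image plane,
#' in physical nanometres.  \code{pixelSize} records the nm/pixel used to
#' convert from image pixel indices.
#'
#' @slot ids character vector of unique marker identifiers.
#' @slot positions numeric matrix with columns \code{x}, \code{y} (nm).
#' @slot pixelSize single numeric, nm per FIB pixel (NA when markers were
#'   supplied directly in nm).
#' @seealso [markerSet2D()], [centroid()]
#' @exportClass MarkerSet2D
setClass("MarkerSet2D",
  representation(ids = "character", positions = "matrix",
                 pixelSize = "numeric"),
  validity = function(object) {
    n <- length(object@ids)
    if (anyDuplicated(object@ids)) return("marker ids must be unique")
    if (!is.numeric(object@positions) || ncol(object@positions) != 2L)
      return("positions must be a numeric matrix with columns x, y")
    if (nrow(object@positions) != n)
      return("one position row per id required")
    if (n > 0L && !all(is.finite(object@positions)))
      return("positions must be finite")
    if (length(object@pixelSize) != 1L)
      return("pixelSize must be a single value (possibly NA)")
    if (!is.na(object@pixelSize) && object@pixelSize <= 0)
      return("pixelSize must be positive")
    TRUE
  })

#' One-to-one pairing between 3D and 2D markers
#'
#' Records which marker in the volume corresponds to which marker in the
#' FIB image.  The pairing is one-to-one; ids are validated against the
#' marker sets when a registration is solved.
#'
#' @slot ids3d,ids2d character vectors of equal length, pair i being
#'   \code{(ids3d[i], ids2d[i])}.
#' @seealso [correspondence()]
#' @exportClass Correspondence
setClass("Correspondence",
  representation(ids3d = "character", ids2d = "character"),
  validity = function(object) {
    if (length(object@ids3d) != length(object@ids2d))
      return("ids3d and ids2d must have equal length")
    if (anyDuplicated(object@ids3d) || anyDuplicated(object@ids2d))
      return("correspondence must be one-to-one")
    TRUE
  })

#' Options controlling the Euler-angle least-squares solver
#'
#' The solver is a deterministic multi-start: the squared-residual
#' objective is evaluated on a coarse grid of angle triples, and the best
#' distinct nodes seed derivative-free local refinement (Nelder-Mead).
#'
#' @slot gridStepDeg coarse grid step in degrees (default 15).
#' @slot boundsDeg search bounds per angle, degrees (default c(-90, 90)).
#' @slot tol convergence tolerance on the squared objective, nm^2
#'   (default 1e-9).
#' @slot prior EulerAngles used to break ties between near-equivalent
#'   minima (default all zero).
#' @slot fitScale logical; when TRUE an isotropic scale factor is fitted
#'   alongside the angles to absorb pixel-size calibration error.  Default
#'   FALSE: the faithful rotate-then-project model has no scale term.
#' @slot nStarts number of distinct coarse-grid nodes refined locally
#'   (default 8).
#' @seealso [solverOptions()], [solveRotation()]
#' @exportClass SolverOptions
setClass("SolverOptions",
  representation(gridStepDeg = "numeric", boundsDeg = "numeric",
                 tol = "numeric", prior = "EulerAngles",
                 fitScale = "logical", nStarts = "integer"),
  prototype(gridStepDeg = 15, boundsDeg = c(-90, 90), tol = 1e-9,
            prior = new("EulerAngles"), fitScale = FALSE, nStarts = 8L),
  validity = function(object) {
    if (object@gridStepDeg <= 0) return("gridStepDeg must be positive")
    if (length(object@boundsDeg) != 2L ||
        object@boundsDeg[1] >= object@boundsDeg[2])
      return("boundsDeg must be c(lower, upper) with lower < upper")
    if (object@tol <= 0) return("tol must be positive")
    if (object@nStarts < 1L) return("nStarts must be >= 1")
    TRUE
  })

#' Result of a 3D-to-2D fiducial registration
#'
#' Stores the solved Euler angles, the per-marker deviations and overall
#' root-mean-square residual (nm) over the markers used, the accepted and
#' rejected marker ids, and convergence metadata.  For planar marker
#' configurations the orthographic model admits an exact mirror solution
#' (theta_x, theta_y negated); when a near-tie was detected the result is
#' flagged and the alternative recorded.
#'
#' @slot angles solved [EulerAngles-class].
#' @slot sd root-mean-square 2D residual over used markers, nm.
#' @slot perMarkerDeviation named numeric, residual distance (nm) of each
#'   used marker.
#' @slot usedIds,rejectedIds 3D marker ids kept in / dropped from the fit.
#' @slot nIterations objective evaluations spent by the solver (or rounds,
#'   for an iterated refinement).
#' @slot converged logical.
#' @slot scale fitted isotropic scale (1 unless scale fitting was enabled).
#' @slot mirrorAmbiguity TRUE when a mirror solution with near-identical
#'   residual exists (planar or near-planar marker configuration).
#' @slot mirrorAngles the alternative solution when flagged, else NULL.
#' @slot centroid3d,centroid2d centroids (nm) of the used markers, the
#'   translation part of the model.
#' @slot markers3d the 3D marker set as used at the optimum (z coordinates
#'   may have been refined), or NULL.
#' @slot rounds list of per-round audit records for iterated refinement.
#' @seealso [solveRotation()], [iterateRegistration()], [applyModel()]
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  representation(angles = "EulerAngles", sd = "numeric",
                 perMarkerDeviation = "numeric",
                 usedIds = "character", rejectedIds = "character",
                 nIterations = "integer", converged = "logical",
                 scale = "numeric", mirrorAmbiguity = "logical",
                 mirrorAngles = "ANY",
                 centroid3d = "numeric", centroid2d = "numeric",
                 markers3d = "ANY", rounds = "list"),
  prototype(scale = 1, mirrorAmbiguity = FALSE, mirrorAngles = NULL,
            markers3d = NULL, rounds = list()),
  validity = function(object) {
    if (length(object@sd) != 1L || object@sd < 0)
      return("sd must be a single non-negative number")
    if (length(intersect(object@usedIds, object@rejectedIds)) > 0L)
      return("usedIds and rejectedIds must be disjoint")
    if (!setequal(names(object@perMarkerDeviation), object@usedIds))
      return("perMarkerDeviation must be named by usedIds")
    TRUE
  })

#' Policy for iterative registration refinement
#'
#' Controls the refinement loop: markers whose residual exceeds
#' \code{outlierFactor} times the RMS residual are dropped (never below
#' \code{minMarkers}), each remaining marker's z coordinate is re-optimized
#' at fixed angles within \code{zBound} nm of its measured value, and the
#' loop stops when the residual improves by less than \code{sdTol} nm or
#' after \code{maxRounds} rounds.
#'
#' @slot outlierFactor multiple of the RMS residual beyond which a marker
#'   is rejected (default 2).
#' @slot minMarkers never reject below this many markers (default 4).
#' @slot zBound maximum z adjustment, nm (default 500, the axial optical
#'   resolution).
#' @slot maxRounds maximum refinement rounds (default 10).
#' @slot sdTol stop when the residual improves by less than this, nm
#'   (default 0.1).
#' @seealso [refinementPolicy()], [iterateRegistration()]
#' @exportClass RefinementPolicy
setClass("RefinementPolicy",
  representation(outlierFactor = "numeric", minMarkers = "integer",
                 zBound = "numeric", maxRounds = "integer",
                 sdTol = "numeric"),
  prototype(outlierFactor = 2, minMarkers = 4L, zBound = 500,
            maxRounds = 10L, sdTol = 0.1),
  validity = function(object) {
    if (object@outlierFactor <= 1) return("outlierFactor must be > 1")
    if (object@minMarkers < 3L) return("minMarkers must be >= 3")
    if (object@zBound < 0) return("zBound must be >= 0")
    if (object@maxRounds < 1L) return("maxRounds must be >= 1")
    if (object@sdTol < 0) return("sdTol must be >= 0")
    TRUE
  })

#' A 3D fluorescence image stack
#'
#' Intensity volume with physical voxel pitch.  Data are stored as an
#' array indexed \code{[y, x, z]}; the physical coordinate of voxel
#' (0-based) index i along an axis of pitch p is \code{i * p} nm (voxel
#' centres, origin at the centre of voxel (0,0,0)).  z increases with
#' slice index.
#'
#' @slot data numeric array \code{[y, x, z]}.
#' @slot pitch named numeric c(x=, y=, z=), nm per voxel.  Default
#'   c(120, 120, 250), a typical 3D-SIM acquisition grid.
#' @slot channel channel label.
#' @seealso [volumeStack()], [detectBeads3D()]
#' @exportClass VolumeStack
setClass("VolumeStack",
  representation(data = "array", pitch = "numeric", channel = "character"),
  prototype(pitch = c(x = 120, y = 120, z = 250), channel = "green"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3D array [y, x, z]")
    if (length(object@pitch) != 3L || any(object@pitch <= 0) ||
        !identical(names(object@pitch), c("x", "y", "z")))
      return("pitch must be a positive numeric named c(x=, y=, z=)")
    TRUE
  })

#' A 2D FIB/SEM image
#'
#' Grayscale ion- or electron-beam image with physical pixel size.  By
#' convention +y (increasing row index) is the milling direction along
#' which the beam advances; the bump-apex bead-centre rule is defined
#' along it.
#'
#' @slot data numeric matrix \code{[y, x]}.
#' @slot pixelSize nm per pixel.
#' @seealso [fibImage()], [fibCenterFromApex()]
#' @exportClass FibImage
setClass("FibImage",
  representation(data = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@data)) return("data must be a numeric matrix")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single positive number (nm)")
    TRUE
  })

#' A fully specified virtual correlative experiment
#'
#' Ground-truth bead positions in a rectangular slab, the true Z-Y-X
#' rotation between the fluorescence and FIB frames, modality-specific
#' localization noise levels, and the seed fixing all downstream
#' randomness.  Used for parameter-recovery testing of every other
#' component.
#'
#' @slot positions numeric matrix, one row per bead, columns x, y, z (nm).
#' @slot trueAngles [EulerAngles-class] of the ground-truth rotation.
#' @slot extents slab extents c(x, y, z) in nm.
#' @slot beadDiameter fiducial bead diameter, nm (default 1000, i.e. the
#'   1 um microspheres commonly used as cryo-CLEM fiducials).
#' @slot noise named numeric c(sigmaXY=, sigmaZ=, sigmaFIB=), the 1-sigma
#'   localization errors (nm) of the fluorescence x/y, fluorescence z and
#'   FIB-side marker coordinates.
#' @slot fibOffset arbitrary translation (nm) anchoring the FIB frame.
#' @slot seed integer seed.
#' @seealso [makeScene()], [simulateLocalizations()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(positions = "matrix", trueAngles = "EulerAngles",
                 extents = "numeric", beadDiameter = "numeric",
                 noise = "numeric", fibOffset = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (ncol(object@positions) != 3L)
      return("positions must have columns x, y, z")
    if (length(object@extents) != 3L || any(object@extents <= 0))
      return("extents must be three positive lengths (nm)")
    if (object@beadDiameter <= 0) return("beadDiameter must be positive")
    if (!identical(names(object@noise),
                   c("sigmaXY", "sigmaZ", "sigmaFIB")) ||
        any(object@noise < 0))
      return("noise must be non-negative c(sigmaXY=, sigmaZ=, sigmaFIB=)")
    ok <- sweep(abs(sweep(object@positions, 2, object@extents / 2)), 2,
                object@extents / 2 + 1e-6, "<=")
    if (nrow(object@positions) > 0L && !all(ok))
      return("bead positions must lie inside the slab")
    TRUE
  })
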