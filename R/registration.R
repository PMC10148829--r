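## Registration model
## ------------------
## A fiducial marker localized at X = (x, y, z) (nm) in the fluorescence
## volume is predicted to appear in the FIB image at
##
##     X' = P(z) . R_x(thetaX) R_y(thetaY) R_z(thetaZ) . (X - mu3),
##
## where mu3 is the centroid of the 3D markers and P(z) drops the z
## component after rotation (orthographic projection along the FIB view
## axis).  FIB-side markers are likewise centred on their own centroid,
## which accounts for the translation between the frames exactly: an
## orthographic projection of a rotation maps the centroid of a set to
## the centroid of its image.  The three Euler angles are the only free
## parameters; they are estimated by least squares on the RMS 2D residual.

#' Rotation matrix of Z-Y-X Euler angles
#'
#' Builds the composite rotation \eqn{R = R_x(\theta_x) R_y(\theta_y)
#' R_z(\theta_z)} acting on column vectors: the z rotation is applied
#' first, then y, then x.
#'
#' @param angles an [EulerAngles-class].
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @examples
#' rotationMatrix(eulerAngles())            # identity
#' rotationMatrix(eulerAngles(thetaZ = pi / 2)) %*% c(1, 0, 0)  # -> (0,1,0)
#' @export
rotationMatrix <- function(angles) {
  stopifnot(is(angles, "EulerAngles"))
  cx <- cos(angles@thetaX); sx <- sin(angles@thetaX)
  cy <- cos(angles@thetaY); sy <- sin(angles@thetaY)
  cz <- cos(angles@thetaZ); sz <- sin(angles@thetaZ)
  rx <- matrix(c(1, 0, 0,
                 0, cx, -sx,
                 0, sx, cx), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy,
                 0, 1, 0,
                 -sy, 0, cy), 3, 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0,
                 sz, cz, 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  rx %*% ry %*% rz
}

#' Project 3D markers onto the FIB image plane
#'
#' Centres the marker set on its centroid, applies the Z-Y-X rotation and
#' drops the z component.  By linearity the projected set is itself
#' centred: its centroid is (0, 0).
#'
#' @param set3d a [MarkerSet3D-class] (non-empty).
#' @param angles an [EulerAngles-class].
#' @return numeric matrix (columns x, y; nm), rownames the marker ids;
#'   coordinates are relative to the projected centroid.
#' @export
projectToFib <- function(set3d, angles) {
  stopifnot(is(set3d, "MarkerSet3D"))
  if (nMarkers(set3d) == 0L) stop("cannot project an empty marker set")
  xc <- sweep(set3d@positions, 2, centroid(set3d))
  r <- rotationMatrix(angles)
  proj <- xc %*% t(r[1:2, , drop = FALSE])
  dimnames(proj) <- list(set3d@ids, c("x", "y"))
  proj
}

#' Centre FIB markers on their centroid
#'
#' @param set2d a [MarkerSet2D-class] (non-empty).
#' @return numeric matrix (columns x, y; nm) with centroid (0, 0),
#'   rownames the marker ids.
#' @export
centerFib <- function(set2d) {
  stopifnot(is(set2d, "MarkerSet2D"))
  if (nMarkers(set2d) == 0L) stop("cannot centre an empty marker set")
  out <- sweep(set2d@positions, 2, centroid(set2d))
  dimnames(out) <- list(set2d@ids, c("x", "y"))
  out
}

#' Registration residual: RMS 2D distance over paired markers
#'
#' The deviation between the two centred datasets,
#' \deqn{SD = \sqrt{\frac{1}{n}\sum_i \|X'_{3D,i} - X'_{FIB,i}\|^2},}
#' the root-mean-square Euclidean distance over the corresponding pairs.
#'
#' @param proj projected/centred 3D marker coordinates: numeric matrix
#'   (columns x, y) with rownames ids, as from [projectToFib()].
#' @param fib centred FIB marker coordinates, as from [centerFib()].
#' @param corr a [Correspondence-class]; when omitted, rows are matched by
#'   identical rownames.
#' @return single numeric, nm.  Zero iff every pair coincides.
#' @export
residualSD <- function(proj, fib, corr = NULL) {
  d <- pairedResiduals(proj, fib, corr)
  sqrt(mean(rowSums(d^2)))
}

## residual vectors (n x 2) of corresponding pairs, rownames = 3D ids
pairedResiduals <- function(proj, fib, corr = NULL) {
  if (is.null(corr))
    corr <- correspondence(rownames(proj), rownames(proj))
  if (nMarkers(corr) == 0L) stop("at least one correspondence required")
  i3 <- match(corr@ids3d, rownames(proj))
  i2 <- match(corr@ids2d, rownames(fib))
  if (anyNA(i3))
    stop("correspondence refers to unknown 3D marker id(s): ",
         paste(corr@ids3d[is.na(i3)], collapse = ", "))
  if (anyNA(i2))
    stop("correspondence refers to unknown 2D marker id(s): ",
         paste(corr@ids2d[is.na(i2)], collapse = ", "))
  d <- proj[i3, , drop = FALSE] - fib[i2, , drop = FALSE]
  rownames(d) <- corr@ids3d
  d
}

## matched, ordered position matrices for a correspondence
matchedPositions <- function(set3d, set2d, corr) {
  i3 <- match(corr@ids3d, set3d@ids)
  i2 <- match(corr@ids2d, set2d@ids)
  if (anyNA(i3))
    stop("correspondence refers to unknown 3D marker id(s): ",
         paste(corr@ids3d[is.na(i3)], collapse = ", "))
  if (anyNA(i2))
    stop("correspondence refers to unknown 2D marker id(s): ",
         paste(corr@ids2d[is.na(i2)], collapse = ", "))
  list(x3 = set3d@positions[i3, , drop = FALSE],
       x2 = set2d@positions[i2, , drop = FALSE])
}

## Squared-residual objective at angle triple th (radians), evaluated
## through precomputed second moments of the centred coordinates:
##   n * SD^2 = tr(R2 S R2') - 2 tr(C R2') + sum(fc^2),
## with S = xc'xc (3x3), C = fc'xc (2x3) and R2 the first two rows of R.
## O(1) per evaluation and algebraically identical to the explicit
## per-marker sum.  When fitScale, the optimal isotropic scale at this
## rotation is folded in analytically (value = (F2 - num^2/den) / n).
solverMoments <- function(xc, fc) {
  list(S = crossprod(xc), C = crossprod(fc, xc), F2 = sum(fc^2),
       n = nrow(xc))
}

solverObjective <- function(th, mom, fitScale = FALSE) {
  r12 <- rot12(th[1], th[2], th[3])
  den <- sum(r12 * (r12 %*% mom$S))
  num <- sum(r12 * mom$C)
  if (fitScale && den > 0)
    (mom$F2 - num^2 / den) / mom$n
  else
    (den - 2 * num + mom$F2) / mom$n
}

## first two rows of R_x(tx) R_y(ty) R_z(tz), closed form, no S4
## overhead; tx/ty/tz may be equal-length vectors, giving a list of
## entry vectors instead of a matrix
rot12 <- function(tx, ty, tz, asList = FALSE) {
  cx <- cos(tx); sx <- sin(tx)
  cy <- cos(ty); sy <- sin(ty)
  cz <- cos(tz); sz <- sin(tz)
  m11 <- cy * cz;                m12 <- -cy * sz;               m13 <- sy
  m21 <- cx * sz + sx * sy * cz; m22 <- cx * cz - sx * sy * sz
  m23 <- -sx * cy
  if (asList)
    list(m11 = m11, m12 = m12, m13 = m13,
         m21 = m21, m22 = m22, m23 = m23)
  else
    matrix(c(m11, m21, m12, m22, m13, m23), 2, 3)
}

## vectorized moment-form objective over many angle triples
solverObjectiveVec <- function(tx, ty, tz, mom, fitScale = FALSE) {
  m <- rot12(tx, ty, tz, asList = TRUE)
  S <- mom$S; C <- mom$C
  den <- S[1, 1] * (m$m11^2 + m$m21^2) +
    S[2, 2] * (m$m12^2 + m$m22^2) +
    S[3, 3] * (m$m13^2 + m$m23^2) +
    2 * S[1, 2] * (m$m11 * m$m12 + m$m21 * m$m22) +
    2 * S[1, 3] * (m$m11 * m$m13 + m$m21 * m$m23) +
    2 * S[2, 3] * (m$m12 * m$m13 + m$m22 * m$m23)
  num <- C[1, 1] * m$m11 + C[1, 2] * m$m12 + C[1, 3] * m$m13 +
    C[2, 1] * m$m21 + C[2, 2] * m$m22 + C[2, 3] * m$m23
  if (fitScale)
    (mom$F2 - num^2 / pmax(den, .Machine$double.xmin)) / mom$n
  else
    (den - 2 * num + mom$F2) / mom$n
}

#' Solve the Euler-angle registration by least squares
#'
#' Estimates the three Z-Y-X Euler angles minimizing the RMS 2D residual
#' between the projected 3D markers and their FIB counterparts (both
#' centred on their own centroids).  The solver is deterministic: the
#' objective is evaluated on a coarse angle grid, the best distinct nodes
#' seed Nelder-Mead refinement, and the best refined solution is
#' returned.  Planar 3D configurations admit an exact mirror solution
#' (theta_x and theta_y negated); when the mirror residual is within 1\%
#' of the optimum the result is flagged and the candidate closest to the
#' prior (smallest L2 distance in angle space) is returned.
#'
#' @param set3d a [MarkerSet3D-class].
#' @param set2d a [MarkerSet2D-class].
#' @param corr a [Correspondence-class] (>= 3 pairs whose 3D positions
#'   are not collinear).
#' @param opts a [SolverOptions-class].
#' @return a [RegistrationResult-class].
#' @examples
#' s3 <- markerSet3D(positions = cbind(runif(8, 0, 5e4),
#'                                     runif(8, 0, 5e4),
#'                                     runif(8, 0, 8e3)))
#' truth <- eulerAngles(0.3, -0.2, 0.5)
#' proj <- projectToFib(s3, truth)
#' s2 <- markerSet2D(ids = rownames(proj), positions = proj)
#' fit <- solveRotation(s3, s2, correspondence(markerIds(s3)))
#' anglesRad(fit)
#' @export
solveRotation <- function(set3d, set2d, corr = NULL,
                          opts = solverOptions()) {
  stopifnot(is(set3d, "MarkerSet3D"), is(set2d, "MarkerSet2D"))
  if (is.null(corr)) {
    shared <- intersect(set3d@ids, set2d@ids)
    corr <- correspondence(shared, shared)
  }
  n <- nMarkers(corr)
  if (n < 3L)
    stop("degenerate geometry: at least 3 marker correspondences are ",
         "required to solve 3 rotation angles (got ", n, ")")
  m <- matchedPositions(set3d, set2d, corr)
  mu3 <- colMeans(m$x3); mu2 <- colMeans(m$x2)
  xc <- sweep(m$x3, 2, mu3); fc <- sweep(m$x2, 2, mu2)
  sv <- svd(xc, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: the 3D marker positions are collinear; ",
         "the rotation about the line is unconstrained")
  planar <- sv[3] < 1e-9 * max(sv[1], 1)
  if (n < 5L)
    warning("only ", n, " marker correspondences; 5 or more are ",
            "recommended for a stable fit")

  nEval <- 0L
  mom <- solverMoments(xc, fc)
  ## exact per-marker objective for local refinement: the moment form
  ## loses ~|fc|^2 * eps of absolute precision to cancellation, which
  ## matters near a zero-residual optimum; the explicit sum does not
  fnExact <- function(th) {
    nEval <<- nEval + 1L
    p <- xc %*% t(rot12(th[1], th[2], th[3]))
    if (opts@fitScale) {
      den <- sum(p * p)
      if (den > 0) p <- (sum(p * fc) / den) * p
    }
    mean(rowSums((p - fc)^2))
  }

  ## deterministic multi-start: coarse grid, then local refinement from
  ## the best mutually distinct nodes
  step <- opts@gridStepDeg * pi / 180
  ax <- seq(opts@boundsDeg[1], opts@boundsDeg[2],
            by = opts@gridStepDeg) * pi / 180
  grid <- as.matrix(expand.grid(tx = ax, ty = ax, tz = ax,
                                KEEP.OUT.ATTRS = FALSE))
  vals <- solverObjectiveVec(grid[, 1], grid[, 2], grid[, 3], mom,
                             opts@fitScale)
  nEval <- nEval + nrow(grid)
  ord <- order(vals)
  starts <- matrix(NA_real_, 0, 3)
  for (k in ord) {
    if (nrow(starts) >= opts@nStarts) break
    if (nrow(starts) == 0L ||
        all(rowSums(sweep(starts, 2, grid[k, ])^2) > (1.5 * step)^2))
      starts <- rbind(starts, grid[k, ])
  }

  ## Nelder-Mead run to (relative) machine tolerance, restarted from
  ## its own optimum until the squared objective improves by less than
  ## opts@tol (restarting rebuilds the simplex, which otherwise
  ## collapses prematurely near a zero-residual optimum)
  refine <- function(th0) {
    o <- stats::optim(th0, fnExact, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    for (k in 1:4) {
      o2 <- stats::optim(o$par, fnExact, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 5000))
      imp <- o$value - o2$value
      if (o2$value <= o$value) o <- o2
      if (imp <= opts@tol) break
    }
    o
  }
  fits <- apply(starts, 1L, refine)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]

  ## mirror candidate: for planar sets projecting with (tx,ty,tz) equals
  ## projecting with (-tx,-ty,tz), so check the reflected solution
  mirrorStart <- c(-best$par[1], -best$par[2], best$par[3])
  mfit <- refine(mirrorStart)
  prior <- anglesRad(opts@prior)
  angDist <- function(th) sum(wrapAngle(th - prior)^2)
  primary <- best; alternate <- mfit
  mirrorTie <- FALSE
  sdBest <- sqrt(max(best$value, 0)); sdMir <- sqrt(max(mfit$value, 0))
  denom <- max(sdBest, sdMir, 1e-12)
  distinct <- sqrt(sum(wrapAngle(best$par - mfit$par)^2)) > 1e-6
  if (distinct && abs(sdBest - sdMir) <= 0.01 * denom) {
    mirrorTie <- TRUE
    if (angDist(mfit$par) < angDist(best$par)) {
      primary <- mfit; alternate <- best
    }
  } else if (mfit$value < best$value) {
    primary <- mfit; alternate <- best
  }

  th <- wrapAngle(primary$par)
  angles <- eulerAngles(th[1], th[2], th[3])
  r12 <- rotationMatrix(angles)[1:2, , drop = FALSE]
  p <- xc %*% t(r12)
  scale <- 1
  if (opts@fitScale) {
    den <- sum(p * p)
    if (den > 0) scale <- sum(p * fc) / den
    p <- scale * p
  }
  resid <- p - fc
  dev <- sqrt(rowSums(resid^2))
  names(dev) <- corr@ids3d
  mirrorAngles <- NULL
  if (mirrorTie) {
    tm <- wrapAngle(alternate$par)
    mirrorAngles <- eulerAngles(tm[1], tm[2], tm[3])
  }
  new("RegistrationResult", angles = angles,
      sd = sqrt(mean(rowSums(resid^2))), perMarkerDeviation = dev,
      usedIds = corr@ids3d, rejectedIds = character(0),
      nIterations = nEval, converged = primary$convergence == 0L,
      scale = scale, mirrorAmbiguity = mirrorTie || planar,
      mirrorAngles = mirrorAngles,
      centroid3d = mu3, centroid2d = mu2,
      markers3d = NULL, rounds = list())
}

#' Map 3D target positions into the FIB image frame
#'
#' Applies the fitted model to arbitrary 3D points (typically milling
#' targets defined in the fluorescence volume):
#' \code{scale * P(z) R (target - mu3) + mu2}, with the centroids taken
#' over the markers the fit used.
#'
#' @param targets numeric matrix of 3D points (columns x, y, z; nm), or a
#'   [MarkerSet3D-class].
#' @param result a [RegistrationResult-class].
#' @param set3d,set2d the marker sets the registration was solved from
#'   (used to recompute the centroids over \code{usedIds(result)}); when
#'   NULL the centroids stored in the result are used.
#' @param asPixels return 0-based FIB pixel indices instead of nm
#'   (requires a pixel size).
#' @param pixelSizeNm nm per pixel for \code{asPixels} (default: the 2D
#'   set's).
#' @return numeric matrix (columns x, y), nm in the un-centred FIB frame
#'   (or pixels).
#' @export
applyModel <- function(targets, result, set3d = NULL, set2d = NULL,
                       asPixels = FALSE, pixelSizeNm = NULL) {
  stopifnot(is(result, "RegistrationResult"))
  if (is(targets, "MarkerSet3D")) {
    tn <- targets@ids
    targets <- targets@positions
  } else {
    targets <- rbind(targets)
    tn <- rownames(targets)
  }
  mu3 <- result@centroid3d; mu2 <- result@centroid2d
  if (!is.null(set3d)) {
    keep <- set3d@ids %in% result@usedIds
    mu3 <- colMeans(set3d@positions[keep, , drop = FALSE])
  }
  if (!is.null(set2d)) {
    ## the fit used the 2D partners of the used 3D markers; with identity
    ## pairing those share ids, otherwise fall back to all markers
    keep <- set2d@ids %in% result@usedIds
    if (!any(keep)) keep <- rep(TRUE, nMarkers(set2d))
    mu2 <- colMeans(set2d@positions[keep, , drop = FALSE])
  }
  r12 <- rotationMatrix(result@angles)[1:2, , drop = FALSE]
  out <- result@scale * sweep(targets, 2, mu3) %*% t(r12)
  out <- sweep(out, 2, mu2, "+")
  colnames(out) <- c("x", "y")
  rownames(out) <- tn
  if (asPixels) {
    px <- pixelSizeNm
    if (is.null(px) && !is.null(set2d)) px <- set2d@pixelSize
    if (is.null(px) || is.na(px))
      stop("a pixel size is required to convert to FIB pixel indices")
    out <- out / px
  }
  out
}

#' Diagnose the geometric quality of a marker configuration
#'
#' The reliability of the angle fit depends on the spatial spread of the
#' fiducials: markers should bracket the target region, especially along
#' y (the milling direction), and must not be coplanar or collinear.
#' This reports the extents, a planarity measure (the smallest singular
#' value of the centred coordinate matrix, in nm), and whether the
#' markers straddle a supplied target in y.  Weak configurations raise
#' warnings, never errors.
#'
#' @param set3d a [MarkerSet3D-class] with >= 3 markers.
#' @param corr optional [Correspondence-class] restricting which markers
#'   are assessed.
#' @param target optional numeric c(x, y, z) (nm): the intended milling
#'   target.
#' @param minExtentY warn when the y spread is below this (nm; default
#'   10000 = 10 um).
#' @param minPlanarity warn when the smallest singular value is below
#'   this (nm; default 100).
#' @return a list with elements \code{yExtent}, \code{zExtent},
#'   \code{xExtent}, \code{planarity}, \code{straddlesY} (NA without a
#'   target) and \code{warnings} (character).
#' @export
configurationQuality <- function(set3d, corr = NULL, target = NULL,
                                 minExtentY = 1e4, minPlanarity = 100) {
  stopifnot(is(set3d, "MarkerSet3D"))
  pos <- set3d@positions
  if (!is.null(corr)) {
    i3 <- match(corr@ids3d, set3d@ids)
    if (anyNA(i3)) stop("correspondence refers to unknown 3D marker id(s)")
    pos <- pos[i3, , drop = FALSE]
  }
  if (nrow(pos) < 3L) stop("at least 3 markers required for diagnostics")
  rng <- apply(pos, 2, range)
  ext <- rng[2, ] - rng[1, ]
  sv <- svd(sweep(pos, 2, colMeans(pos)), nu = 0, nv = 0)$d
  straddles <- NA
  if (!is.null(target))
    straddles <- rng[1, "y"] < target[2] && target[2] < rng[2, "y"]
  warnings <- character(0)
  if (sv[3] < minPlanarity)
    warnings <- c(warnings, sprintf(
      "near-planar marker configuration (planarity %.1f nm): the fit has a mirror ambiguity in (thetaX, thetaY)",
      sv[3]))
  if (ext["y"] < minExtentY)
    warnings <- c(warnings, sprintf(
      "small y extent (%.0f nm): markers should bracket the target along the milling direction",
      ext["y"]))
  if (identical(straddles, FALSE))
    warnings <- c(warnings,
                  "markers do not straddle the target in y")
  for (w in warnings) warning(w, call. = FALSE)
  list(xExtent = unname(ext["x"]), yExtent = unname(ext["y"]),
       zExtent = unname(ext["z"]), planarity = sv[3],
       straddlesY = straddles, warnings = warnings)
}
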