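## Iterative refinement
## --------------------
## After a first angle solve, markers whose residual is far above the RMS
## are dropped (their centres were likely mislocalized, e.g. a bead bump
## half-buried in ice), and the z coordinate of each remaining marker is
## re-optimized at fixed angles: the axial localization of a fluorescence
## z-stack is several times worse than the lateral one, so z is the
## coordinate worth re-estimating from the registration itself.  The loop
## alternates solve / reject / z-optimize until the residual stops
## improving.

#' Reject markers with large residuals
#'
#' Drops markers whose residual exceeds \code{outlierFactor} times the
#' RMS residual of the fit, but never reduces the set below
#' \code{minMarkers} (when the rule would, the markers with the smallest
#' residuals are kept).  Deterministic.
#'
#' @param result a [RegistrationResult-class] with per-marker deviations.
#' @param policy a [RefinementPolicy-class].
#' @return list with character vectors \code{kept} and \code{rejected}.
#' @export
rejectOutliers <- function(result, policy = refinementPolicy()) {
  stopifnot(is(result, "RegistrationResult"),
            is(policy, "RefinementPolicy"))
  dev <- result@perMarkerDeviation
  if (length(dev) == 0L) stop("result carries no per-marker deviations")
  rms <- sqrt(mean(dev^2))
  ## numerically-zero residuals are never outliers, whatever their ratio
  bad <- dev > policy@outlierFactor * rms & dev > 1e-6
  if (sum(!bad) < policy@minMarkers) {
    ## floor rule: keep the minMarkers smallest-deviation markers
    keepN <- min(policy@minMarkers, length(dev))
    keepIdx <- order(dev)[seq_len(keepN)]
    bad <- rep(TRUE, length(dev))
    bad[keepIdx] <- FALSE
  }
  if (sum(!bad) < 3L)
    stop("outlier rejection would leave fewer than 3 markers")
  list(kept = names(dev)[!bad], rejected = names(dev)[bad])
}

#' Re-optimize each marker's z coordinate at fixed angles
#'
#' With the angles and both centroids held fixed, the projected position
#' of marker i is affine in its z coordinate along the direction
#' \code{(r13, r23)} (the third column, first two rows, of the rotation
#' matrix), so the least-squares z is available in closed form:
#' \deqn{z^* = z_0 - \frac{e_0 \cdot a}{a \cdot a}, \quad a = (r_{13},
#' r_{23}),} with \eqn{e_0} the current 2D residual.  The update is
#' clamped to \code{zBound} nm around the measured z.  At zero tilt
#' \code{(r13, r23) = (0, 0)}: z is unobservable in the projection and
#' all markers are left unchanged and flagged.
#'
#' @param set3d the current [MarkerSet3D-class].
#' @param set2d the [MarkerSet2D-class].
#' @param corr a [Correspondence-class] over the markers to adjust.
#' @param angles fixed [EulerAngles-class].
#' @param policy a [RefinementPolicy-class] (supplies \code{zBound}).
#' @param referenceZ named numeric of measured z values (nm) that anchor
#'   the clamp window; defaults to the current z of \code{set3d}, so pass
#'   the original measurements when calling repeatedly.
#' @return list: \code{set3d} (updated markers; centroid is derived so it
#'   reflects the new z), \code{flagged} (ids with unobservable z),
#'   \code{deltaZ} (named numeric of applied adjustments, nm).
#' @export
optimizeMarkerZ <- function(set3d, set2d, corr, angles,
                            policy = refinementPolicy(),
                            referenceZ = NULL) {
  stopifnot(is(set3d, "MarkerSet3D"), is(set2d, "MarkerSet2D"),
            is(corr, "Correspondence"), is(angles, "EulerAngles"))
  m <- matchedPositions(set3d, set2d, corr)
  mu3 <- colMeans(m$x3); mu2 <- colMeans(m$x2)
  r <- rotationMatrix(angles)
  a <- r[1:2, 3]
  aa <- sum(a^2)
  proj <- sweep(m$x3, 2, mu3) %*% t(r[1:2, , drop = FALSE])
  resid <- proj - sweep(m$x2, 2, mu2)
  if (is.null(referenceZ)) {
    referenceZ <- m$x3[, "z"]
    names(referenceZ) <- corr@ids3d
  }
  newPos <- set3d@positions
  flagged <- character(0)
  deltaZ <- numeric(0)
  if (aa < 1e-12) {
    ## z does not move the projection at these angles
    flagged <- corr@ids3d
  } else {
    for (i in seq_len(nMarkers(corr))) {
      id <- corr@ids3d[i]
      z0 <- m$x3[i, "z"]
      zStar <- z0 - sum(resid[i, ] * a) / aa
      zRef <- referenceZ[[id]]
      zStar <- min(max(zStar, zRef - policy@zBound),
                   zRef + policy@zBound)
      j <- match(id, set3d@ids)
      deltaZ[id] <- zStar - newPos[j, "z"]
      newPos[j, "z"] <- zStar
    }
  }
  out <- set3d
  out@positions <- newPos
  list(set3d = out, flagged = flagged, deltaZ = deltaZ)
}

#' Iterate registration with outlier rejection and z refinement
#'
#' Alternates [solveRotation()], [rejectOutliers()] and
#' [optimizeMarkerZ()] until the residual improves by less than
#' \code{sdTol} nm or \code{maxRounds} is reached.  The residual over the
#' kept markers is non-increasing across rounds.  z optimization is
#' skipped (with a warning) below 5 kept markers, where re-estimating one
#' z per marker on top of three angles risks overfitting the 2n
#' constraints.
#'
#' @param set3d a [MarkerSet3D-class] (z values are taken as the measured
#'   anchors for the clamp window).
#' @param set2d a [MarkerSet2D-class].
#' @param corr a [Correspondence-class]; NULL pairs shared ids.
#' @param opts a [SolverOptions-class].
#' @param policy a [RefinementPolicy-class].
#' @return a [RegistrationResult-class]; \code{rejectedIds} holds the
#'   dropped markers, \code{refinedMarkers()} the z-adjusted set, and the
#'   \code{rounds} slot a per-round audit trail (round, sd, angles in
#'   degrees, rejected ids, z adjustments).
#' @export
iterateRegistration <- function(set3d, set2d, corr = NULL,
                                opts = solverOptions(),
                                policy = refinementPolicy()) {
  if (is.null(corr)) {
    shared <- intersect(set3d@ids, set2d@ids)
    corr <- correspondence(shared, shared)
  }
  referenceZ <- stats::setNames(
    set3d@positions[match(corr@ids3d, set3d@ids), "z"], corr@ids3d)
  cur3d <- set3d
  curCorr <- corr
  rejected <- character(0)
  rounds <- list()
  fit <- solveRotation(cur3d, set2d, curCorr, opts)
  prevSD <- Inf
  round <- 0L
  zWarned <- FALSE
  while (round < policy@maxRounds && prevSD - fit@sd >= policy@sdTol) {
    round <- round + 1L
    prevSD <- fit@sd

    sel <- rejectOutliers(fit, policy)
    newRejected <- sel$rejected
    if (length(newRejected) > 0L) {
      rejected <- c(rejected, newRejected)
      keep <- !(curCorr@ids3d %in% newRejected)
      curCorr <- correspondence(curCorr@ids3d[keep], curCorr@ids2d[keep])
      fit <- solveRotation(cur3d, set2d, curCorr, opts)
    }

    deltaZ <- numeric(0)
    if (policy@zBound > 0) {
      if (nMarkers(curCorr) >= 5L) {
        zopt <- optimizeMarkerZ(cur3d, set2d, curCorr, fit@angles,
                                policy, referenceZ)
        cur3d <- zopt$set3d
        deltaZ <- zopt$deltaZ
      } else if (!zWarned) {
        warning("fewer than 5 markers: skipping z optimization to avoid ",
                "overfitting")
        zWarned <- TRUE
      }
    }
    newFit <- solveRotation(cur3d, set2d, curCorr, opts)
    ## the alternation can only improve the objective over the kept set
    if (newFit@sd <= fit@sd || length(newRejected) > 0L ||
        length(deltaZ) > 0L)
      fit <- newFit
    rounds[[round]] <- list(round = round, sd = fit@sd,
                            anglesDeg = unname(anglesDeg(fit)),
                            rejected = newRejected,
                            deltaZ = deltaZ)
  }
  fit@rejectedIds <- rejected
  fit@markers3d <- cur3d
  fit@rounds <- rounds
  fit@nIterations <- max(round, 1L)
  fit@converged <- round < policy@maxRounds
  validObject(fit)
  fit
}
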