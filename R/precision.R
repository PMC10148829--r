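## Targeting precision
## -------------------
## The operational definition of targeting precision is the residual on
## markers NOT used in the fit: register on one fiducial population (for
## instance the green-channel beads), then measure the RMS 2D deviation
## of a second, held-out population (the red beads) after mapping it
## through the fitted model.  A leave-one-out variant provides the same
## diagnostic from a single population.

#' Held-out registration precision
#'
#' Solves the Euler angles on the fit population only, maps the held-out
#' 3D markers through the fitted model (using the fit population's
#' centroids, since the held-out markers did not contribute to the
#' translation anchor), and reports their per-marker deviations and RMS
#' residual against their measured FIB positions.
#'
#' @param fit3d,fit2d,fitCorr the fit (registration) population.
#' @param eval3d,eval2d,evalCorr the held-out (evaluation) population;
#'   ids must be disjoint from the fit population's.
#' @param opts a [SolverOptions-class].
#' @param refine optional [RefinementPolicy-class]; when supplied the fit
#'   population is refined with [iterateRegistration()] before
#'   evaluation.
#' @return list: \code{fit} (the [RegistrationResult-class]),
#'   \code{deviations} (named numeric, nm, one per held-out marker),
#'   \code{sd} (their RMS, nm), \code{n} (held-out count).
#' @export
heldoutDeviation <- function(fit3d, fit2d, fitCorr, eval3d, eval2d,
                             evalCorr, opts = solverOptions(),
                             refine = NULL) {
  if (nMarkers(evalCorr) == 0L)
    stop("the held-out evaluation set is empty")
  if (length(intersect(fitCorr@ids3d, evalCorr@ids3d)) > 0L)
    stop("fit and evaluation populations must be disjoint")
  fit <- if (is.null(refine))
    solveRotation(fit3d, fit2d, fitCorr, opts)
  else
    iterateRegistration(fit3d, fit2d, fitCorr, opts, refine)
  m <- matchedPositions(eval3d, eval2d, evalCorr)
  pred <- applyModel(m$x3, fit)
  d <- pred - m$x2
  dev <- sqrt(rowSums(d^2))
  names(dev) <- evalCorr@ids3d
  list(fit = fit, deviations = dev, sd = sqrt(mean(dev^2)),
       n = length(dev))
}

#' Leave-one-out cross-validated deviations
#'
#' For each correspondence, refits the registration without it and
#' records the deviation of the left-out marker under the refit model.
#' A degenerate refit (for example, the remaining markers become
#' collinear) yields NA for that marker rather than a fatal error.
#'
#' @param set3d,set2d,corr the marker population (>= 4 correspondences).
#' @param opts a [SolverOptions-class].
#' @return list: \code{deviations} (named numeric, nm, NA where the
#'   refit was degenerate), \code{rms} (RMS over the non-NA entries).
#' @export
looCV <- function(set3d, set2d, corr = NULL, opts = solverOptions()) {
  if (is.null(corr)) {
    shared <- intersect(set3d@ids, set2d@ids)
    corr <- correspondence(shared, shared)
  }
  n <- nMarkers(corr)
  if (n < 4L) stop("leave-one-out requires at least 4 correspondences")
  dev <- stats::setNames(rep(NA_real_, n), corr@ids3d)
  for (i in seq_len(n)) {
    sub <- correspondence(corr@ids3d[-i], corr@ids2d[-i])
    fit <- tryCatch(
      suppressWarnings(solveRotation(set3d, set2d, sub, opts)),
      error = function(e) NULL)
    if (is.null(fit)) next
    m <- matchedPositions(set3d, set2d,
                          correspondence(corr@ids3d[i], corr@ids2d[i]))
    pred <- applyModel(m$x3, fit)
    dev[i] <- sqrt(sum((pred - m$x2)^2))
  }
  list(deviations = dev, rms = sqrt(mean(dev^2, na.rm = TRUE)))
}

#' Closed-form expected residual under Gaussian localization noise
#'
#' When each 3D marker coordinate carries independent Gaussian
#' localization noise (sigmaXY laterally, sigmaZ axially) and each FIB
#' coordinate carries noise sigmaFib, the noise propagates through
#' rotate-then-project, and the expected squared residual per marker is
#' \deqn{E[SD^2] = \sum_{k=1}^{2} r_k\,\mathrm{diag}(\sigma_{xy}^2,
#'   \sigma_{xy}^2, \sigma_z^2)\,r_k^T + 2\,\sigma_{FIB}^2,}
#' with \eqn{r_k} the k-th row of the rotation matrix.  Since the rows
#' are unit vectors this reduces to
#' \eqn{\sigma_{xy}^2 (2 - c) + \sigma_z^2 c + 2 \sigma_{FIB}^2} with
#' \eqn{c = r_{13}^2 + r_{23}^2}.  This is the large-n limit: it ignores
#' the (order 1/n) noise absorbed by the fitted angles and centroids.
#' At zero tilt \eqn{c = 0} and z noise is invisible in the projection;
#' any tilt mixes the (much larger) axial error into the residual, which
#' is why z localization precision drives the achievable correlation
#' accuracy.
#'
#' @param sigmaXYSim lateral 1-sigma localization error of the volume
#'   markers, nm.
#' @param sigmaZSim axial 1-sigma error, nm.
#' @param sigmaFib 1-sigma error of the FIB-side marker coordinates, nm.
#' @param angles an [EulerAngles-class].
#' @return expected RMS residual, nm.
#' @examples
#' expectedSD(60, 300, 0, eulerAngles())  # sqrt(2) * 60
#' @export
expectedSD <- function(sigmaXYSim, sigmaZSim, sigmaFib,
                       angles = eulerAngles()) {
  stopifnot(sigmaXYSim >= 0, sigmaZSim >= 0, sigmaFib >= 0)
  r <- rotationMatrix(angles)
  cc <- r[1, 3]^2 + r[2, 3]^2
  sqrt(sigmaXYSim^2 * (2 - cc) + sigmaZSim^2 * cc + 2 * sigmaFib^2)
}
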