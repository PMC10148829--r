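## Synthetic correlative experiments
## ---------------------------------
## A virtual bead slab imaged by both modalities: ground-truth positions
## uniform in a rectangular slab, a known Z-Y-X rotation between the
## fluorescence and FIB frames, independent Gaussian localization noise
## per modality, and optional image rendering (Gaussian spots in the
## stack; bumps with the apex half a diameter before the centre along
## -y in the FIB image).  A single seed fixes everything; each stage
## draws from its own substream so stage-level results do not depend on
## upstream draw counts.

## run expr with a derived, restored RNG state; offset selects the
## substream
withSubstream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 101L + offset) %% 2147483647L)
  expr
}

#' Generate a synthetic bead scene
#'
#' Bead positions are uniform in a rectangular slab with the origin at
#' one corner.  Degenerate modes support geometry testing: "planar"
#' fixes all z at mid-slab; "one-sided-y" confines beads to the lower
#' half of the y range.
#'
#' @param nBeads number of beads (>= 1).
#' @param extents slab extents c(x, y, z), nm.  Default 100 x 100 x 15
#'   um, a full field of view with beads settled through the ice
#'   thickness.
#' @param trueAngles ground-truth [EulerAngles-class].  Default
#'   c(15, 8, 30) degrees: a moderate compound tilt representative of
#'   the FIB viewing geometry plus an in-plane rotation.
#' @param seed integer seed fixing all downstream randomness.
#' @param beadDiameter nm (default 1000: 1 um fiducial microspheres).
#' @param noise named numeric c(sigmaXY=, sigmaZ=, sigmaFIB=), nm.
#'   Defaults 100/250/20: half the typical ~200 nm lateral and ~500 nm
#'   axial optical resolution of a cryo-SIM acquisition for the volume
#'   side, and a small sub-pixel error for FIB-side bead centres.
#' @param mode "uniform" (default), "planar" or "one-sided-y".
#' @return a [SyntheticScene-class].
#' @examples
#' sc <- makeScene(20, seed = 1)
#' @export
makeScene <- function(nBeads, extents = c(1e5, 1e5, 1.5e4),
                      trueAngles = eulerAngles(15, 8, 30, degrees = TRUE),
                      seed = 1L, beadDiameter = 1000,
                      noise = c(sigmaXY = 100, sigmaZ = 250,
                                sigmaFIB = 20),
                      mode = c("uniform", "planar", "one-sided-y")) {
  mode <- match.arg(mode)
  if (nBeads < 1L) stop("nBeads must be >= 1")
  if (any(extents <= 0)) stop("slab extents must be positive")
  seed <- as.integer(seed)
  pos <- withSubstream(seed, 0L, {
    p <- cbind(x = stats::runif(nBeads, 0, extents[1]),
               y = stats::runif(nBeads, 0, extents[2]),
               z = stats::runif(nBeads, 0, extents[3]))
    p
  })
  if (mode == "planar") pos[, "z"] <- extents[3] / 2
  if (mode == "one-sided-y") pos[, "y"] <- pos[, "y"] / 2
  fibOffset <- withSubstream(seed, 1L,
                             stats::runif(2, 0, 2e4))
  noise <- noise[c("sigmaXY", "sigmaZ", "sigmaFIB")]
  new("SyntheticScene", positions = pos, trueAngles = trueAngles,
      extents = as.numeric(extents), beadDiameter = beadDiameter,
      noise = noise, fibOffset = fibOffset, seed = seed)
}

#' Simulate marker localization in both modalities
#'
#' The forward model of the registration itself: the 3D marker set is
#' the true positions plus Gaussian localization noise (sigmaXY on x and
#' y, sigmaZ on z); the 2D set is the rotate-then-project image of the
#' TRUE positions (centred on their centroid), re-anchored to the
#' scene's arbitrary FIB offset, plus sigmaFIB noise per coordinate.
#' The correspondence is the identity pairing.
#'
#' @param scene a [SyntheticScene-class].
#' @return list: \code{set3d} ([MarkerSet3D-class]), \code{set2d}
#'   ([MarkerSet2D-class]), \code{corr} ([Correspondence-class]),
#'   \code{truth} (list with the noise-free projected positions and the
#'   true angles).
#' @export
simulateLocalizations <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  n <- nrow(scene@positions)
  ids <- paste0("b", seq_len(n))
  r12 <- rotationMatrix(scene@trueAngles)[1:2, , drop = FALSE]
  mu <- colMeans(scene@positions)
  projTrue <- sweep(scene@positions, 2, mu) %*% t(r12)
  projTrue <- sweep(projTrue, 2, scene@fibOffset, "+")
  colnames(projTrue) <- c("x", "y")
  rownames(projTrue) <- ids
  pos3 <- withSubstream(scene@seed, 2L, {
    scene@positions +
      cbind(stats::rnorm(n, 0, scene@noise[["sigmaXY"]]),
            stats::rnorm(n, 0, scene@noise[["sigmaXY"]]),
            stats::rnorm(n, 0, scene@noise[["sigmaZ"]]))
  })
  pos2 <- withSubstream(scene@seed, 3L, {
    projTrue + cbind(stats::rnorm(n, 0, scene@noise[["sigmaFIB"]]),
                     stats::rnorm(n, 0, scene@noise[["sigmaFIB"]]))
  })
  list(set3d = markerSet3D(ids, pos3),
       set2d = markerSet2D(ids, pos2),
       corr = correspondence(ids, ids),
       truth = list(projected = projTrue, angles = scene@trueAngles,
                    centroid3d = mu))
}

#' Render the fluorescence stack of a scene
#'
#' Beads become anisotropic Gaussian spots: the apparent widths combine
#' the bead radius with the diffraction-limited blur (sigma =
#' sqrt((d/4)^2 + (res/2.355)^2) with res ~200 nm laterally, ~500 nm
#' axially).  Beads outside the rendered field are clipped silently.
#'
#' @param scene a [SyntheticScene-class].
#' @param pitch voxel pitch c(x=, y=, z=), nm; default c(120, 120, 250),
#'   a typical 3D-SIM grid.
#' @param noiseSd Gaussian read-noise sigma added to the rendered
#'   intensities (0 = noise-free); Poisson shot noise is added when
#'   \code{poisson = TRUE}.  Seeded from the scene.
#' @param poisson add Poisson shot noise (photon budget 1000 at peak).
#' @return a [VolumeStack-class].
#' @export
renderSimStack <- function(scene, pitch = c(x = 120, y = 120, z = 250),
                           noiseSd = 0, poisson = FALSE) {
  stopifnot(is(scene, "SyntheticScene"))
  pitch <- as.numeric(pitch); names(pitch) <- c("x", "y", "z")
  d <- scene@beadDiameter
  sigma <- c(x = sqrt((d / 4)^2 + (200 / 2.355)^2),
             y = sqrt((d / 4)^2 + (200 / 2.355)^2),
             z = sqrt((d / 4)^2 + (500 / 2.355)^2))
  nx <- floor(scene@extents[1] / pitch[["x"]]) + 1L
  ny <- floor(scene@extents[2] / pitch[["y"]]) + 1L
  nz <- floor(scene@extents[3] / pitch[["z"]]) + 1L
  vol <- array(0, c(ny, nx, nz))
  gx <- (seq_len(nx) - 1) * pitch[["x"]]
  gy <- (seq_len(ny) - 1) * pitch[["y"]]
  gz <- (seq_len(nz) - 1) * pitch[["z"]]
  for (i in seq_len(nrow(scene@positions))) {
    p <- unname(scene@positions[i, ])  # columns are x, y, z
    ix <- which(abs(gx - p[1]) < 4 * sigma["x"])
    iy <- which(abs(gy - p[2]) < 4 * sigma["y"])
    iz <- which(abs(gz - p[3]) < 4 * sigma["z"])
    if (!length(ix) || !length(iy) || !length(iz)) next
    ex <- exp(-(gx[ix] - p[1])^2 / (2 * sigma["x"]^2))
    ey <- exp(-(gy[iy] - p[2])^2 / (2 * sigma["y"]^2))
    ez <- exp(-(gz[iz] - p[3])^2 / (2 * sigma["z"]^2))
    spot <- outer(outer(ey, ex), ez)
    vol[iy, ix, iz] <- vol[iy, ix, iz] + spot
  }
  if (poisson || noiseSd > 0) {
    vol <- withSubstream(scene@seed, 4L, {
      v <- vol
      if (poisson) v <- stats::rpois(length(v), v * 1000) / 1000
      if (noiseSd > 0) v <- v + stats::rnorm(length(v), 0, noiseSd)
      array(v, dim(vol))
    })
  }
  volumeStack(vol, pitch = pitch, channel = "green")
}

#' Render the FIB image of a scene
#'
#' Each bead appears as a bright bump whose apex lies half a bead
#' diameter BEFORE the true centre along the milling direction (apex at
#' centre - (0, d/2)), so the bump-apex rule of [fibCenterFromApex()]
#' recovers the centre by construction.  The image frame covers the
#' projected bead cloud with a margin; like the marker simulation, the
#' projected cloud is anchored at the scene's FIB offset.
#'
#' @param scene a [SyntheticScene-class].
#' @param pixelSize nm per pixel (default 50, a typical ion-beam imaging
#'   magnification for targeting).
#' @param noiseSd Gaussian noise sigma (0 = noise-free), seeded from the
#'   scene.
#' @return list: \code{img} ([FibImage-class]), \code{origin} (nm
#'   coordinates of pixel (0,0), so marker positions from the image can
#'   be compared with [simulateLocalizations()] output), \code{centers}
#'   (true projected bead centres, nm, in image-frame coordinates).
#' @export
renderFibImage <- function(scene, pixelSize = 50, noiseSd = 0) {
  stopifnot(is(scene, "SyntheticScene"))
  r12 <- rotationMatrix(scene@trueAngles)[1:2, , drop = FALSE]
  mu <- colMeans(scene@positions)
  ctr <- sweep(sweep(scene@positions, 2, mu) %*% t(r12), 2,
               scene@fibOffset, "+")
  colnames(ctr) <- c("x", "y")
  d <- scene@beadDiameter
  margin <- 2 * d
  origin <- c(x = min(ctr[, "x"]) - margin, y = min(ctr[, "y"]) - margin)
  nx <- ceiling((max(ctr[, "x"]) + margin - origin["x"]) / pixelSize) + 1L
  ny <- ceiling((max(ctr[, "y"]) + margin - origin["y"]) / pixelSize) + 1L
  img <- matrix(0, ny, nx)
  gx <- origin[["x"]] + (seq_len(nx) - 1) * pixelSize
  gy <- origin[["y"]] + (seq_len(ny) - 1) * pixelSize
  sig <- d / 4
  for (i in seq_len(nrow(ctr))) {
    apex <- c(ctr[i, "x"], ctr[i, "y"] - d / 2)
    ix <- which(abs(gx - apex[1]) < 4 * sig)
    iy <- which(abs(gy - apex[2]) < 4 * sig)
    if (!length(ix) || !length(iy)) next
    bump <- outer(exp(-(gy[iy] - apex[2])^2 / (2 * sig^2)),
                  exp(-(gx[ix] - apex[1])^2 / (2 * sig^2)))
    img[iy, ix] <- pmax(img[iy, ix], bump)
  }
  if (noiseSd > 0)
    img <- withSubstream(scene@seed, 5L,
                         img + matrix(stats::rnorm(length(img), 0,
                                                   noiseSd), nrow(img)))
  ctrImg <- sweep(ctr, 2, origin)
  list(img = fibImage(img, pixelSize), origin = origin,
       centers = ctrImg)
}
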