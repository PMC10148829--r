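## Marker localization
## -------------------
## Volume side: scale-matched blob detection (Gaussian smoothing at the
## bead scale, 26-neighbour local maxima, minimum-separation pruning)
## followed by iterative background-subtracted weighted centroids for
## sub-voxel centres.  FIB side: a bead embedded in ice appears as a
## bump whose apex marks the bead EDGE facing the advancing ion beam,
## so the centre lies half a bead diameter from the apex along the
## milling direction (+y).

## separable Gaussian smoothing of a 3D array; sigma in voxels per
## dimension of `x` ([y, x, z] order).  Replicated-edge padding.
gaussSmooth3D <- function(x, sigma) {
  smooth1 <- function(arr, s, dim) {
    if (s <= 0) return(arr)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    d <- dim(arr)
    n <- d[dim]
    out <- array(0, d)
    for (j in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      sl <- switch(dim,
                   arr[idx, , , drop = FALSE],
                   arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      out <- out + k[j + r + 1L] * sl
    }
    out
  }
  x <- smooth1(x, sigma[1], 1L)
  x <- smooth1(x, sigma[2], 2L)
  smooth1(x, sigma[3], 3L)
}

## strict 26-neighbour local maxima of a 3D array above `thr`
localMaxima3D <- function(x, thr) {
  d <- dim(x)
  ok <- x > thr
  shifts <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  pad <- function(idx, n) pmin(pmax(idx, 1L), n)
  for (s in seq_len(nrow(shifts))) {
    iy <- pad(seq_len(d[1]) + shifts$dy[s], d[1])
    ix <- pad(seq_len(d[2]) + shifts$dx[s], d[2])
    iz <- pad(seq_len(d[3]) + shifts$dz[s], d[3])
    ok <- ok & (x >= x[iy, ix, iz, drop = FALSE])
    if (!any(ok)) break
  }
  which(ok, arr.ind = TRUE)
}

#' Detect fiducial beads in a 3D fluorescence stack
#'
#' Scale-matched blob detection: the stack is smoothed with an
#' anisotropic Gaussian matched to the bead size, strict local maxima
#' above a contrast threshold become candidates, candidates closer than
#' one bead diameter are merged (brightest wins), and each survivor is
#' refined to sub-voxel precision with [refineCentroid3D()].
#' Deterministic given its inputs.
#'
#' @param stack a [VolumeStack-class].
#' @param expectedDiameter bead diameter, nm; must be at least twice the
#'   lateral voxel pitch.
#' @param minContrast fraction (0..1) of the stack's background-to-peak
#'   intensity range a candidate must exceed (default 0.1).
#' @return a [MarkerSet3D-class] (possibly empty, with a warning).
#' @export
detectBeads3D <- function(stack, expectedDiameter, minContrast = 0.1) {
  stopifnot(is(stack, "VolumeStack"))
  pitch <- stack@pitch
  if (expectedDiameter < 2 * max(pitch[c("x", "y")]))
    stop("expectedDiameter must be at least twice the lateral voxel pitch")
  sigmaNm <- expectedDiameter / 4
  sig <- c(sigmaNm / pitch["y"], sigmaNm / pitch["x"],
           sigmaNm / pitch["z"])
  sm <- gaussSmooth3D(stack@data, sig)
  bg <- stats::median(sm)
  peak <- max(sm)
  if (peak <= bg) {
    warning("no beads found: stack has no contrast")
    return(markerSet3D(character(0),
                       matrix(numeric(0), 0, 3), character(0)))
  }
  thr <- bg + minContrast * (peak - bg)
  cand <- localMaxima3D(sm, thr)
  if (nrow(cand) == 0L) {
    warning("no beads found above the contrast threshold")
    return(markerSet3D(character(0),
                       matrix(numeric(0), 0, 3), character(0)))
  }
  ## nm positions of candidate voxel centres (0-based index * pitch)
  pos <- cbind(x = (cand[, 2] - 1) * pitch["x"],
               y = (cand[, 1] - 1) * pitch["y"],
               z = (cand[, 3] - 1) * pitch["z"])
  inten <- sm[cand]
  ## minimum-separation pruning, brightest first
  ord <- order(-inten, pos[, "x"], pos[, "y"], pos[, "z"])
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        all(rowSums(sweep(pos[keep, , drop = FALSE], 2,
                          pos[i, ])^2) > expectedDiameter^2))
      keep <- c(keep, i)
  }
  refined <- t(vapply(keep, function(i)
    refineCentroid3D(stack, pos[i, ], radius = 0.75 * expectedDiameter),
    numeric(3)))
  colnames(refined) <- c("x", "y", "z")
  ## refinement can pull two candidates from the shoulders of
  ## overlapping spots to nearly the same place: deduplicate again,
  ## brighter candidate first
  final <- integer(0)
  for (i in seq_along(keep)) {
    if (length(final) == 0L ||
        all(rowSums(sweep(refined[final, , drop = FALSE], 2,
                          refined[i, ])^2) > (expectedDiameter / 2)^2))
      final <- c(final, i)
  }
  markerSet3D(paste0("m", seq_along(final)),
              refined[final, , drop = FALSE],
              channels = stack@channel)
}

#' Sub-voxel bead centre by iterative weighted centroid
#'
#' Around a seed position, intensities inside a window of the given
#' radius are background-subtracted (background = median of the window's
#' border shell, a robust parameter-free estimate) and the
#' intensity-weighted centroid of the voxel centres is computed; the
#' window recentres on the result and the step repeats to a fixed point
#' (at most 10 iterations).
#'
#' @param stack a [VolumeStack-class].
#' @param seed numeric c(x, y, z), nm, inside the stack.
#' @param radius window half-size, nm.
#' @return named numeric c(x, y, z) nm.  When the window is empty or
#'   flat the seed is returned unchanged with attribute
#'   \code{flagged = TRUE} and a warning.
#' @export
refineCentroid3D <- function(stack, seed, radius) {
  stopifnot(is(stack, "VolumeStack"))
  pitch <- stack@pitch
  d <- dim(stack@data)
  maxNm <- c((d[2] - 1) * pitch["x"], (d[1] - 1) * pitch["y"],
             (d[3] - 1) * pitch["z"])
  if (any(seed < -pitch[c("x", "y", "z")]) || any(seed > maxNm +
        pitch[c("x", "y", "z")]))
    stop("seed position lies outside the stack")
  cur <- as.numeric(seed)
  rVox <- pmax(1, round(radius / pitch[c("x", "y", "z")]))
  names(rVox) <- c("x", "y", "z")
  for (iter in 1:10) {
    cx <- round(cur[1] / pitch[["x"]]) + 1
    cy <- round(cur[2] / pitch[["y"]]) + 1
    cz <- round(cur[3] / pitch[["z"]]) + 1
    ix <- max(1, cx - rVox[["x"]]):min(d[2], cx + rVox[["x"]])
    iy <- max(1, cy - rVox[["y"]]):min(d[1], cy + rVox[["y"]])
    iz <- max(1, cz - rVox[["z"]]):min(d[3], cz + rVox[["z"]])
    win <- stack@data[iy, ix, iz, drop = FALSE]
    if (length(win) == 0L) break
    border <- win
    if (all(dim(win) > 2L))
      border[2:(dim(win)[1] - 1), 2:(dim(win)[2] - 1),
             2:(dim(win)[3] - 1)] <- NA
    bg <- stats::median(border, na.rm = TRUE)
    w <- pmax(win - bg, 0)
    sw <- sum(w)
    if (sw <= 0) {
      warning("flat intensity window: seed returned unchanged")
      out <- as.numeric(seed)
      names(out) <- c("x", "y", "z")
      attr(out, "flagged") <- TRUE
      return(out)
    }
    gx <- (ix - 1) * pitch[["x"]]
    gy <- (iy - 1) * pitch[["y"]]
    gz <- (iz - 1) * pitch[["z"]]
    wy <- apply(w, 1, sum); wx <- apply(w, 2, sum); wz <- apply(w, 3, sum)
    new <- c(sum(gx * wx), sum(gy * wy), sum(gz * wz)) / sw
    if (sqrt(sum((new - cur)^2)) < 1e-3) { cur <- new; break }
    cur <- new
  }
  names(cur) <- c("x", "y", "z")
  cur
}

#' Bead centre from a FIB bump apex
#'
#' A bead embedded in ice shows up in the FIB image as a bump; the apex
#' of the bump marks the bead edge facing the beam, so the centre lies
#' half a bead diameter further along the milling direction (+y):
#' \code{centre = apex_nm + (0, d/2)}.  The offset is applied in
#' image-plane nm exactly as stated by the rule; an optional
#' foreshortening factor can scale it for a tilted viewing geometry
#' (default 1, i.e. off).
#'
#' @param apex numeric c(x, y): apex position in 0-based pixel indices
#'   (may be fractional).
#' @param beadDiameter bead diameter, nm.
#' @param img a [FibImage-class].
#' @param foreshortening multiplier applied to the d/2 offset.
#' @return named numeric c(x, y), nm.
#' @examples
#' img <- fibImage(matrix(0, 200, 200), pixelSize = 20)
#' fibCenterFromApex(c(100, 100), beadDiameter = 1000, img)
#' # x = 2000 nm, y = 2000 + 500 nm
#' @export
fibCenterFromApex <- function(apex, beadDiameter, img,
                              foreshortening = 1) {
  stopifnot(is(img, "FibImage"), beadDiameter >= 0)
  d <- dim(img@data)
  if (apex[1] < 0 || apex[1] > d[2] - 1 ||
      apex[2] < 0 || apex[2] > d[1] - 1)
    stop("apex lies outside the image")
  out <- c(x = apex[1] * img@pixelSize,
           y = apex[2] * img@pixelSize +
             foreshortening * beadDiameter / 2)
  out
}

#' Detect bump apexes in a FIB image
#'
#' 2D analogue of [detectBeads3D()]: Gaussian smoothing at the bead
#' scale, local maxima above a contrast threshold, minimum-separation
#' pruning and a weighted-centroid sub-pixel refinement of each apex.
#' Combine with [fibCenterFromApex()] to obtain bead centres.
#'
#' @param img a [FibImage-class].
#' @param beadDiameter bead diameter, nm.
#' @param minContrast fraction of the background-to-peak range required
#'   (default 0.1).
#' @return numeric matrix of apex positions (columns x, y) in 0-based
#'   (fractional) pixel indices.
#' @export
detectApexes <- function(img, beadDiameter, minContrast = 0.1) {
  stopifnot(is(img, "FibImage"))
  sigPx <- beadDiameter / 4 / img@pixelSize
  sm <- gaussSmooth3D(array(img@data, c(dim(img@data), 1L)),
                      c(sigPx, sigPx, 0))[, , 1]
  bg <- stats::median(sm)
  peak <- max(sm)
  if (peak <= bg) return(matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("x", "y"))))
  thr <- bg + minContrast * (peak - bg)
  cand <- localMaxima3D(array(sm, c(dim(sm), 1L)), thr)[, 1:2,
                                                        drop = FALSE]
  if (nrow(cand) == 0L) return(matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("x", "y"))))
  px <- cbind(x = cand[, 2] - 1, y = cand[, 1] - 1)
  inten <- sm[cand[, , drop = FALSE]]
  dPx <- beadDiameter / img@pixelSize
  ord <- order(-inten, px[, 1], px[, 2])
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        all(rowSums(sweep(px[keep, , drop = FALSE], 2, px[i, ])^2) >
              dPx^2))
      keep <- c(keep, i)
  }
  ## sub-pixel apex: weighted centroid in a d/2 window
  r <- max(1L, round(dPx / 4))
  dimg <- dim(img@data)
  ref <- t(vapply(keep, function(i) {
    cx <- px[i, 1] + 1; cy <- px[i, 2] + 1
    ix <- max(1, cx - r):min(dimg[2], cx + r)
    iy <- max(1, cy - r):min(dimg[1], cy + r)
    w <- sm[iy, ix, drop = FALSE]
    w <- pmax(w - min(w), 0)
    if (sum(w) <= 0) return(c(px[i, 1], px[i, 2]))
    c(sum((rep(ix, each = length(iy)) - 1) * w) / sum(w),
      sum((rep(iy, times = length(ix)) - 1) * w) / sum(w))
  }, numeric(2)))
  colnames(ref) <- c("x", "y")
  ref
}

#' Detect FIB bead centres via the bump-apex rule
#'
#' Convenience wrapper: [detectApexes()] then [fibCenterFromApex()] for
#' each apex.
#'
#' @inheritParams detectApexes
#' @param foreshortening passed to [fibCenterFromApex()].
#' @return a [MarkerSet2D-class] in nm, carrying the image pixel size.
#' @export
detectFibBeads <- function(img, beadDiameter, minContrast = 0.1,
                           foreshortening = 1) {
  apexes <- detectApexes(img, beadDiameter, minContrast)
  if (nrow(apexes) == 0L)
    return(markerSet2D(character(0), matrix(numeric(0), 0, 2),
                       pixelSize = img@pixelSize))
  ctr <- t(apply(apexes, 1, fibCenterFromApex, beadDiameter = beadDiameter,
                 img = img, foreshortening = foreshortening))
  markerSet2D(paste0("f", seq_len(nrow(ctr))), ctr,
              pixelSize = img@pixelSize)
}

#' Set the z coordinate of one marker
#'
#' Functional update mirroring the manual z adjustment of a bead whose
#' axial position is ambiguous in the fluorescence stack: returns a new
#' set, the original is untouched, and the (derived) centroid reflects
#' the change.
#'
#' @param set3d a [MarkerSet3D-class].
#' @param id marker id.
#' @param newZ new z, nm.
#' @return the updated [MarkerSet3D-class].
#' @export
setMarkerZ <- function(set3d, id, newZ) {
  stopifnot(is(set3d, "MarkerSet3D"))
  j <- match(id, set3d@ids)
  if (is.na(j)) stop("unknown marker id: ", id)
  out <- set3d
  out@positions[j, "z"] <- newZ
  out
}
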