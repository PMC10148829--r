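## Overlay rendering
## -----------------
## The registered fluorescence volume is rendered into the FIB frame by
## forward splatting: every voxel centre is mapped through the fitted
## model, intensities are accumulated per output pixel by maximum (a
## maximum-intensity projection along the view axis), and a small
## morphological closing fills sampling cracks where the rotated voxel
## grid leaves output pixels unhit.

#' Project a fluorescence volume into the FIB frame
#'
#' @param stack a [VolumeStack-class].
#' @param result a [RegistrationResult-class].
#' @param set3d,set2d marker sets defining the centroids (see
#'   [applyModel()]); may be NULL to use the centroids stored in the
#'   result.
#' @param outPixel output pixel size, nm (default: the 2D set's pixel
#'   size, else the lateral stack pitch).
#' @param outDim output image size c(ny, nx) in pixels (default: sized
#'   to the mapped voxel cloud).  The output grid starts at FIB
#'   coordinate (0, 0).
#' @param close radius of the closing brush in pixels (0 disables).
#' @param threshold voxels at or below this intensity are not splatted
#'   (default 0).
#' @return numeric matrix \code{[y, x]} in the FIB frame; blank (all
#'   zero) with a warning when nothing maps inside the output.
#' @export
projectVolume <- function(stack, result, set3d = NULL, set2d = NULL,
                          outPixel = NULL, outDim = NULL, close = 1L,
                          threshold = 0) {
  stopifnot(is(stack, "VolumeStack"), is(result, "RegistrationResult"))
  if (is.null(outPixel)) {
    outPixel <- if (!is.null(set2d) && !is.na(set2d@pixelSize))
      set2d@pixelSize else unname(stack@pitch["x"])
  }
  d <- dim(stack@data)
  keep <- which(stack@data > threshold)
  if (length(keep) == 0L) {
    warning("no voxels above threshold: blank projection")
    if (is.null(outDim)) outDim <- c(1L, 1L)
    return(matrix(0, outDim[1], outDim[2]))
  }
  idx <- arrayInd(keep, d)
  vox <- cbind(x = (idx[, 2] - 1) * stack@pitch[["x"]],
               y = (idx[, 1] - 1) * stack@pitch[["y"]],
               z = (idx[, 3] - 1) * stack@pitch[["z"]])
  mapped <- applyModel(vox, result, set3d, set2d)
  px <- round(mapped / outPixel)
  if (is.null(outDim))
    outDim <- c(max(px[, "y"]) + 1L, max(px[, "x"]) + 1L)
  inb <- px[, "x"] >= 0 & px[, "x"] < outDim[2] &
    px[, "y"] >= 0 & px[, "y"] < outDim[1]
  out <- matrix(0, outDim[1], outDim[2])
  if (!any(inb)) {
    warning("projected volume does not overlap the output frame")
    return(out)
  }
  v <- stack@data[keep][inb]
  lin <- px[inb, "y"] + 1 + px[inb, "x"] * outDim[1]
  ## ascending assignment: the last (largest) value per pixel wins = MIP
  ord <- order(v)
  out[lin[ord]] <- v[ord]
  if (close > 0) {
    mask <- out > 0
    brush <- EBImage::makeBrush(2L * as.integer(close) + 1L,
                                shape = "diamond")
    closed <- EBImage::closing(out, brush)
    out <- pmax(out, closed * (!mask))
  }
  out
}

#' Merge a projected fluorescence image onto a FIB image
#'
#' Alpha-blended false-colour composite.  The FIB grayscale is preserved
#' exactly wherever the projection is zero; at alpha 1 a saturated
#' projection pixel becomes the pure overlay colour.
#'
#' @param fib a [FibImage-class].
#' @param proj numeric matrix from [projectVolume()], same size.
#' @param color overlay colour (any R colour; default "green").
#' @param alpha blend weight in 0..1 (default 0.5).
#' @return numeric array \code{[y, x, 3]} with values in 0..1.
#' @export
mergeOverlay <- function(fib, proj, color = "green", alpha = 0.5) {
  stopifnot(is(fib, "FibImage"))
  if (!all(dim(proj) == dim(fib@data)))
    stop("projection and FIB image have different shapes")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  g <- fib@data
  rngG <- range(g)
  if (rngG[1] < 0 || rngG[2] > 1)   # bring to display range if needed
    g <- (g - rngG[1]) / max(rngG[2] - rngG[1], .Machine$double.eps)
  p <- proj
  if (max(p) > 0) p <- p / max(p)
  rgbCol <- grDevices::col2rgb(color)[, 1] / 255
  w <- alpha * p
  out <- array(0, c(dim(g), 3L))
  for (k in 1:3) out[, , k] <- (1 - w) * g + w * rgbCol[k]
  out
}

#' Export milling targets mapped into the FIB image
#'
#' Maps 3D target positions through the registration, writes a CSV
#' (\code{id,x_px,y_px,x_nm,y_nm,in_frame}) and, when a path is given,
#' an annotated PNG with a cross drawn at each target.  Targets mapping
#' outside the image are kept in the table and flagged, never dropped.
#'
#' @param targets a [MarkerSet3D-class] of target positions.
#' @param result a [RegistrationResult-class].
#' @param set3d,set2d marker sets defining the centroids (see
#'   [applyModel()]).
#' @param fib a [FibImage-class] (frame and pixel size of the export).
#' @param csvPath path of the CSV to write (NULL skips writing).
#' @param pngPath path of the annotated PNG (NULL skips).
#' @param crossSize cross half-size in pixels.
#' @return the target table, invisibly.
#' @export
exportTargets <- function(targets, result, set3d = NULL, set2d = NULL,
                          fib, csvPath = NULL, pngPath = NULL,
                          crossSize = 6L) {
  stopifnot(is(targets, "MarkerSet3D"), is(fib, "FibImage"))
  nm <- applyModel(targets, result, set3d, set2d)
  px <- nm / fib@pixelSize
  d <- dim(fib@data)
  inFrame <- px[, "x"] >= 0 & px[, "x"] <= d[2] - 1 &
    px[, "y"] >= 0 & px[, "y"] <= d[1] - 1
  tab <- data.frame(id = targets@ids,
                    x_px = px[, "x"], y_px = px[, "y"],
                    x_nm = nm[, "x"], y_nm = nm[, "y"],
                    in_frame = inFrame, row.names = NULL)
  if (!is.null(csvPath))
    utils::write.csv(tab, csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(pngPath)) {
    g <- fib@data
    rngG <- range(g)
    if (rngG[1] < 0 || rngG[2] > 1)
      g <- (g - rngG[1]) / max(rngG[2] - rngG[1], .Machine$double.eps)
    rgb <- array(rep(g, 3L), c(d, 3L))
    for (i in which(inFrame)) {
      cx <- round(px[i, "x"]) + 1L
      cy <- round(px[i, "y"]) + 1L
      xs <- max(1L, cx - crossSize):min(d[2], cx + crossSize)
      ys <- max(1L, cy - crossSize):min(d[1], cy + crossSize)
      rgb[cy, xs, 1] <- 1; rgb[cy, xs, 2:3] <- 0
      rgb[ys, cx, 1] <- 1; rgb[ys, cx, 2:3] <- 0
    }
    png::writePNG(rgb, pngPath)
  }
  invisible(tab)
}
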