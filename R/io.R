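## File formats
## ------------
## Marker tables are CSV with mandatory header:
##   3D: id,x_nm,y_nm,z_nm,channel    2D: id,x_nm,y_nm
## Pixel-unit variants (x_px,y_px[,z_px]) are accepted when the caller
## supplies the conversion pitch, since units are load-bearing for the
## registration.  Stacks and FIB images are (OME-)TIFF; voxel pitch is
## taken from OME PhysicalSize metadata when present, but an explicitly
## configured pitch always wins (with a notice).

#' Read a 3D marker CSV
#'
#' Expects columns \code{id,x_nm,y_nm,z_nm[,channel]}, or
#' \code{id,x_px,y_px,z_px} together with \code{voxelSize}.
#'
#' @param path CSV file.
#' @param voxelSize numeric c(x, y, z) nm per voxel, required for
#'   pixel-unit tables.
#' @return a [MarkerSet3D-class].
#' @export
readMarkers3D <- function(path, voxelSize = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ch <- if ("channel" %in% names(tab)) tab$channel else "green"
  if (all(c("x_nm", "y_nm", "z_nm") %in% names(tab))) {
    pos <- cbind(tab$x_nm, tab$y_nm, tab$z_nm)
  } else if (all(c("x_px", "y_px", "z_px") %in% names(tab))) {
    if (is.null(voxelSize))
      stop("marker table is in pixel units: a voxel size (nm) is ",
           "required to convert")
    pos <- cbind(tab$x_px * voxelSize[1], tab$y_px * voxelSize[2],
                 tab$z_px * voxelSize[3])
  } else stop("expected columns id,x_nm,y_nm,z_nm or id,x_px,y_px,z_px")
  markerSet3D(tab$id, pos, ch)
}

#' Read a 2D marker CSV
#'
#' Expects columns \code{id,x_nm,y_nm}, or \code{id,x_px,y_px} together
#' with \code{pixelSize}.
#'
#' @param path CSV file.
#' @param pixelSize nm per pixel, required for pixel-unit tables.
#' @return a [MarkerSet2D-class].
#' @export
readMarkers2D <- function(path, pixelSize = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("x_nm", "y_nm") %in% names(tab))) {
    pos <- cbind(tab$x_nm, tab$y_nm)
    ps <- if (is.null(pixelSize)) NA_real_ else pixelSize
  } else if (all(c("x_px", "y_px") %in% names(tab))) {
    if (is.null(pixelSize))
      stop("marker table is in pixel units: a pixel size (nm) is ",
           "required to convert")
    pos <- cbind(tab$x_px * pixelSize, tab$y_px * pixelSize)
    ps <- pixelSize
  } else stop("expected columns id,x_nm,y_nm or id,x_px,y_px")
  markerSet2D(tab$id, pos, pixelSize = ps)
}

#' Write a marker set to CSV
#'
#' Writes nm coordinates with the standard header; lossless round-trip
#' with the readers.
#'
#' @param set a [MarkerSet3D-class] or [MarkerSet2D-class].
#' @param path output CSV.
#' @export
writeMarkers <- function(set, path) {
  if (is(set, "MarkerSet3D")) {
    tab <- data.frame(id = set@ids, x_nm = set@positions[, "x"],
                      y_nm = set@positions[, "y"],
                      z_nm = set@positions[, "z"],
                      channel = set@channels)
  } else if (is(set, "MarkerSet2D")) {
    tab <- data.frame(id = set@ids, x_nm = set@positions[, "x"],
                      y_nm = set@positions[, "y"])
  } else stop("not a marker set")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## parse PhysicalSizeX/Y/Z (um unless PhysicalSize*Unit says nm) from an
## OME-XML description string; returns named nm triple or NULL
parseOmePitch <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("PhysicalSize", desc))
    return(NULL)
  get1 <- function(axis) {
    m <- regmatches(desc, regexec(
      sprintf('PhysicalSize%s="([0-9.eE+-]+)"', axis), desc))[[1]]
    if (length(m) < 2L) return(NA_real_)
    val <- as.numeric(m[2])
    u <- regmatches(desc, regexec(
      sprintf('PhysicalSize%sUnit="([^"]+)"', axis), desc))[[1]]
    unit <- if (length(u) >= 2L) u[2] else "µm"
    val * switch(unit, "nm" = 1, "mm" = 1e6, 1e3)  # default micrometres
  }
  p <- c(x = get1("X"), y = get1("Y"), z = get1("Z"))
  if (anyNA(p)) NULL else p
}

#' Read a TIFF z-stack
#'
#' Multi-page TIFF (one page per z slice) into a [VolumeStack-class].
#' Voxel pitch resolution order: an explicit \code{pitch} argument wins
#' (with a notice when it disagrees with embedded metadata); otherwise
#' OME PhysicalSize metadata from the TIFF description; otherwise the
#' YAML sidecar written by [writeStack()]; otherwise an error, because
#' registration math is meaningless without physical units.
#'
#' @param path TIFF file.
#' @param pitch optional c(x, y, z) nm per voxel.
#' @param channel channel label.
#' @return a [VolumeStack-class].
#' @export
readStack <- function(path, pitch = NULL, channel = "green") {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  desc <- attr(pages[[1]], "description")
  ome <- parseOmePitch(desc)
  if (is.null(ome)) {
    side <- readSidecar(path)
    if (!is.null(side$physical_size_nm))
      ome <- unlist(side$physical_size_nm)[c("x", "y", "z")]
  }
  if (!is.null(pitch)) {
    pitch <- as.numeric(pitch)
    if (!is.null(ome) && any(abs(ome - pitch) > 1e-6))
      message("configured voxel pitch overrides OME metadata (",
              paste(signif(ome, 6), collapse = "/"), " nm)")
  } else if (!is.null(ome)) {
    pitch <- as.numeric(ome)
  } else {
    stop("no voxel pitch available: supply `pitch` or use an OME-TIFF ",
         "with PhysicalSize metadata")
  }
  vol <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    vol[, , i] <- pg
  }
  volumeStack(vol, pitch = pitch, channel = channel)
}

## companion metadata file (<image>.meta.yaml) written next to TIFFs we
## produce, since the TIFF writer available here cannot embed an
## ImageDescription tag
sidecarPath <- function(path) paste0(path, ".meta.yaml")

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  yaml::read_yaml(sp)
}

#' Write a volume stack as multi-page TIFF
#'
#' Intensities are rescaled to 0..1 (TIFF storage range).  The voxel
#' pitch is recorded in a YAML sidecar (\code{<path>.meta.yaml}) that
#' [readStack()] recovers automatically.
#'
#' @param stack a [VolumeStack-class].
#' @param path output TIFF.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "VolumeStack"))
  v <- stack@data
  if (max(v) > 1 || min(v) < 0)
    v <- (v - min(v)) / max(max(v) - min(v), .Machine$double.eps)
  slices <- lapply(seq_len(dim(v)[3]), function(i) v[, , i])
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  yaml::write_yaml(list(physical_size_nm = list(
    x = stack@pitch[["x"]], y = stack@pitch[["y"]],
    z = stack@pitch[["z"]]), channel = stack@channel),
    sidecarPath(path))
  invisible(path)
}

#' Read a 2D FIB image (TIFF or PNG)
#'
#' @param path image file.
#' @param pixelSize nm per pixel; required unless the TIFF carries OME
#'   PhysicalSizeX metadata (an explicit value wins, with a notice).
#' @return a [FibImage-class].
#' @export
readFib <- function(path, pixelSize = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    ome <- NULL
  } else {
    img <- tiff::readTIFF(path, info = TRUE)
    ome <- parseOmePitch(attr(img, "description"))
    if (is.null(ome)) {
      side <- readSidecar(path)
      if (!is.null(side$physical_size_nm))
        ome <- c(x = side$physical_size_nm$x)
    }
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (is.null(pixelSize)) {
    if (is.null(ome))
      stop("no pixel size available: supply `pixelSize` (nm)")
    pixelSize <- unname(ome["x"])
  } else if (!is.null(ome) && abs(ome[["x"]] - pixelSize) > 1e-6) {
    message("configured pixel size overrides OME metadata (",
            signif(ome[["x"]], 6), " nm)")
  }
  fibImage(img, pixelSize)
}

#' Write a FIB image as TIFF
#'
#' The pixel size is recorded in a YAML sidecar (\code{<path>.meta.yaml})
#' that [readFib()] recovers automatically.
#'
#' @param img a [FibImage-class].
#' @param path output TIFF.
#' @export
writeFib <- function(img, path) {
  stopifnot(is(img, "FibImage"))
  v <- img@data
  if (max(v) > 1 || min(v) < 0)
    v <- (v - min(v)) / max(max(v) - min(v), .Machine$double.eps)
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  yaml::write_yaml(list(physical_size_nm = list(x = img@pixelSize,
                                                y = img@pixelSize)),
                   sidecarPath(path))
  invisible(path)
}

## deterministic 32-bit djb2 hash of a string (config fingerprinting)
djb2 <- function(s) {
  h <- 5381
  for (c in utf8ToInt(s)) h <- (h * 33 + c) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Serialize solver/refinement configuration to a list
#' @param opts a [SolverOptions-class].
#' @param policy a [RefinementPolicy-class] or NULL.
#' @return plain list suitable for YAML/JSON.
#' @export
configAsList <- function(opts = solverOptions(), policy = NULL) {
  cfg <- list(solver = list(grid_step_deg = opts@gridStepDeg,
                            bounds_deg = opts@boundsDeg,
                            tol = opts@tol,
                            prior_deg = unname(anglesDeg(opts@prior)),
                            fit_scale = opts@fitScale,
                            n_starts = opts@nStarts))
  if (!is.null(policy))
    cfg$refinement <- list(outlier_factor = policy@outlierFactor,
                           min_markers = policy@minMarkers,
                           z_bound_nm = policy@zBound,
                           max_rounds = policy@maxRounds,
                           sd_tol_nm = policy@sdTol)
  cfg
}

#' Read a YAML run configuration
#'
#' Validates every field and reports all problems at once.
#'
#' @param path YAML file mirroring [solverOptions()] and
#'   [refinementPolicy()] (sections \code{solver}, \code{refinement}).
#' @return list with elements \code{opts}, \code{policy} (NULL when the
#'   section is absent) and \code{raw}.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  s <- raw$solver
  opts <- solverOptions()
  if (!is.null(s)) {
    if (!is.null(s$grid_step_deg)) {
      if (!is.numeric(s$grid_step_deg) || s$grid_step_deg <= 0)
        note("solver.grid_step_deg must be a positive number")
    }
    if (!is.null(s$bounds_deg) &&
        (length(s$bounds_deg) != 2L || s$bounds_deg[1] >= s$bounds_deg[2]))
      note("solver.bounds_deg must be [lower, upper] with lower < upper")
    if (!is.null(s$tol) && (!is.numeric(s$tol) || s$tol <= 0))
      note("solver.tol must be a positive number")
    if (!is.null(s$prior_deg) && length(s$prior_deg) != 3L)
      note("solver.prior_deg must have 3 entries")
    if (length(problems) == 0L)
      opts <- solverOptions(
        gridStepDeg = s$grid_step_deg %||% 15,
        boundsDeg = unlist(s$bounds_deg %||% c(-90, 90)),
        tol = s$tol %||% 1e-9,
        prior = do.call(eulerAngles,
                        c(as.list(s$prior_deg %||% c(0, 0, 0)),
                          degrees = TRUE)),
        fitScale = isTRUE(s$fit_scale),
        nStarts = s$n_starts %||% 8L)
  }
  p <- raw$refinement
  policy <- NULL
  if (!is.null(p)) {
    if (!is.null(p$outlier_factor) && p$outlier_factor <= 1)
      note("refinement.outlier_factor must be > 1")
    if (!is.null(p$min_markers) && p$min_markers < 3)
      note("refinement.min_markers must be >= 3")
    if (!is.null(p$z_bound_nm) && p$z_bound_nm < 0)
      note("refinement.z_bound_nm must be >= 0")
    if (length(problems) == 0L)
      policy <- refinementPolicy(
        outlierFactor = p$outlier_factor %||% 2,
        minMarkers = p$min_markers %||% 4L,
        zBound = p$z_bound_nm %||% 500,
        maxRounds = p$max_rounds %||% 10L,
        sdTol = p$sd_tol_nm %||% 0.1)
  }
  if (length(problems) > 0L)
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  list(opts = opts, policy = policy, raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a registration result as JSON
#'
#' Angles in degrees (user-facing convention), SD in nm, plus a
#' reproducibility block (package version and a hash of the solver
#' configuration).
#'
#' @param result a [RegistrationResult-class].
#' @param path output JSON; NULL returns the list without writing.
#' @param opts the [SolverOptions-class] used (for the config hash).
#' @param policy optional [RefinementPolicy-class] used.
#' @return the result list, invisibly.
#' @export
writeRegistrationResult <- function(result, path = NULL,
                                    opts = solverOptions(),
                                    policy = NULL) {
  stopifnot(is(result, "RegistrationResult"))
  cfg <- configAsList(opts, policy)
  out <- list(
    angles_deg = unname(round(anglesDeg(result), 6)),
    sd_nm = round(result@sd, 3),
    per_marker_deviation_nm = as.list(round(result@perMarkerDeviation,
                                            3)),
    used_ids = result@usedIds,
    rejected_ids = result@rejectedIds,
    scale = result@scale,
    converged = result@converged,
    n_iterations = result@nIterations,
    mirror_ambiguity = result@mirrorAmbiguity,
    software_version = as.character(utils::packageVersion("cryoFidReg")),
    config_hash = djb2(jsonlite::toJSON(cfg, auto_unbox = TRUE)))
  if (length(result@rounds) > 0L)
    out$rounds <- lapply(result@rounds, function(r)
      list(round = r$round, sd_nm = round(r$sd, 3),
           angles_deg = round(r$anglesDeg, 6), rejected = r$rejected,
           delta_z_nm = as.list(round(r$deltaZ, 3))))
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(out)
}

#' Write a held-out precision report
#'
#' JSON summary plus a per-marker CSV of deviations (one row per
#' held-out bead).
#'
#' @param report list from [heldoutDeviation()].
#' @param jsonPath output JSON (NULL skips).
#' @param csvPath output CSV (NULL skips).
#' @return the report list, invisibly.
#' @export
writePrecisionReport <- function(report, jsonPath = NULL,
                                 csvPath = NULL) {
  out <- list(heldout_sd_nm = round(report$sd, 3),
              n_heldout = report$n,
              deviations_nm = as.list(round(report$deviations, 3)),
              fit_angles_deg = unname(round(anglesDeg(report$fit), 6)),
              fit_sd_nm = round(registrationSD(report$fit), 3),
              software_version =
                as.character(utils::packageVersion("cryoFidReg")))
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(csvPath))
    utils::write.csv(data.frame(id = names(report$deviations),
                                deviation_nm = report$deviations,
                                row.names = NULL),
                     csvPath, row.names = FALSE, quote = FALSE)
  invisible(out)
}
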