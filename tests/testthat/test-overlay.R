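## registration result with prescribed angles/centroids, for driving the
## renderer without a solve
fixedResult <- function(angles = eulerAngles(), mu3 = c(0, 0, 0),
                        mu2 = c(0, 0)) {
  new("RegistrationResult", angles = angles, sd = 0,
      perMarkerDeviation = numeric(0), usedIds = character(0),
      rejectedIds = character(0), nIterations = 1L, converged = TRUE,
      centroid3d = mu3, centroid2d = mu2)
}

test_that("identity projection equals the plain z-MIP", {
  set.seed(55)
  vol <- array(runif(20 * 24 * 6), c(20, 24, 6))
  stack <- volumeStack(vol, pitch = c(x = 100, y = 100, z = 250))
  ## centroids chosen so that the mapped positions equal voxel nm coords
  res <- fixedResult()
  out <- projectVolume(stack, res, outPixel = 100, outDim = c(20, 24),
                       close = 0)
  mip <- apply(vol, c(1, 2), max)
  expect_equal(out, mip)
  ## an integer-pixel centroid shift moves the MIP rigidly
  res2 <- fixedResult(mu3 = c(0, 0, 0), mu2 = c(300, 200))
  out2 <- projectVolume(stack, res2, outPixel = 100,
                        outDim = c(22, 27), close = 0)
  expect_equal(out2[2 + seq_len(20), 3 + seq_len(24)], mip)
})

test_that("a single bright voxel lands at its applyModel position", {
  vol <- array(0, c(30, 30, 10))
  vol[12, 21, 4] <- 1   # y index 12, x index 21, z index 4
  stack <- volumeStack(vol, pitch = c(x = 100, y = 100, z = 250))
  a <- eulerAngles(0.2, -0.1, 0.4)
  res <- fixedResult(a, mu3 = c(1500, 1500, 1200), mu2 = c(1400, 1500))
  out <- projectVolume(stack, res, outPixel = 100, outDim = c(40, 40),
                       close = 0)
  hit <- which(out > 0, arr.ind = TRUE)
  expect_equal(nrow(hit), 1)
  want <- applyModel(rbind(c(20 * 100, 11 * 100, 3 * 250)), res) / 100
  expect_lte(abs(hit[1, "col"] - 1 - want[1, "x"]), 1)
  expect_lte(abs(hit[1, "row"] - 1 - want[1, "y"]), 1)
})

test_that("a quarter-turn about z rotates the projected pattern", {
  vol <- array(0, c(21, 21, 4))
  ## asymmetric three-point pattern, mid-grid centroid
  vol[11, 18, 2] <- 1    # +x arm
  vol[15, 11, 3] <- 0.8  # +y arm
  vol[11, 11, 2] <- 0.6  # centre
  stack <- volumeStack(vol, pitch = c(x = 100, y = 100, z = 100))
  ctr <- c(1000, 1000, 150)
  res <- fixedResult(eulerAngles(thetaZ = pi / 2), mu3 = ctr,
                     mu2 = c(1000, 1000))
  out <- projectVolume(stack, res, outPixel = 100, outDim = c(21, 21),
                       close = 0)
  ## the +x arm must now point along +y: (x,y) = (0, +700) from centre
  hitArm <- which(abs(out - 1) < 1e-9, arr.ind = TRUE)
  expect_equal(nrow(hitArm), 1)
  expect_lte(abs(hitArm[1, "col"] - 1 - 10), 1)
  expect_lte(abs(hitArm[1, "row"] - 1 - 17), 1)
  ## and the +y arm along -x
  hitY <- which(abs(out - 0.8) < 1e-9, arr.ind = TRUE)
  expect_lte(abs(hitY[1, "col"] - 1 - 6), 1)
  expect_lte(abs(hitY[1, "row"] - 1 - 10), 1)
})

test_that("overlay blending preserves the FIB image outside the projection", {
  set.seed(66)
  fib <- fibImage(matrix(runif(400), 20, 20), pixelSize = 50)
  proj <- matrix(0, 20, 20)
  proj[5, 5] <- 2; proj[9, 14] <- 1
  ## alpha 0: untouched everywhere
  out0 <- mergeOverlay(fib, proj, alpha = 0)
  for (k in 1:3) expect_equal(out0[, , k], fib@data)
  ## all-zero projection: untouched
  outZ <- mergeOverlay(fib, matrix(0, 20, 20), alpha = 0.8)
  for (k in 1:3) expect_equal(outZ[, , k], fib@data)
  ## saturated pixel at alpha 1 becomes the pure overlay colour
  out1 <- mergeOverlay(fib, proj, color = "green", alpha = 1)
  expect_equal(out1[5, 5, ], c(0, 1, 0))
  ## FIB grayscale preserved where proj == 0
  mask <- proj == 0
  for (k in 1:3) expect_equal(out1[, , k][mask], fib@data[mask])
  expect_error(mergeOverlay(fib, matrix(0, 5, 5)), "shape")
})

test_that("targets export with pixel coordinates, flags and crosses", {
  inst <- makeExactInstance(77, n = 10)
  fit <- solveRotation(inst$set3d, inst$set2d, inst$corr)
  fib <- fibImage(matrix(0.5, 300, 300), pixelSize = 200)
  targets <- markerSet3D(paste0("B", 1:5),
                         markerPositions(inst$set3d)[1:5, ])
  csv <- tempfile(fileext = ".csv")
  png <- tempfile(fileext = ".png")
  tab <- exportTargets(targets, fit, inst$set3d, inst$set2d, fib,
                       csvPath = csv, pngPath = png)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$id, paste0("B", 1:5))
  ## a registration marker maps within its stored deviation (+eps)
  obs <- markerPositions(inst$set2d)[1:5, ]
  d <- sqrt((tab$x_nm - obs[, "x"])^2 + (tab$y_nm - obs[, "y"])^2)
  expect_true(all(d <= markerDeviations(fit)[1:5] + 1e-6))
  ## CSV round-trips
  back <- utils::read.csv(csv)
  expect_equal(back$x_px, tab$x_px, tolerance = 1e-9)
  expect_equal(back$in_frame, tab$in_frame)
  expect_true(file.exists(png))
  ## far-away target: kept but flagged out of frame
  far <- markerSet3D("far", rbind(c(1e7, 1e7, 0)))
  tabF <- exportTargets(far, fit, inst$set3d, inst$set2d, fib)
  expect_equal(nrow(tabF), 1)
  expect_false(tabF$in_frame)
})
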