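## scene with one grossly mislocalized marker and perturbed z values
makeCorruptedInstance <- function(seed, n = 10, zErr = 0) {
  inst <- makeExactInstance(seed, n = n)
  pos <- markerPositions(inst$set3d)
  if (zErr > 0) {
    set.seed(seed + 1000)
    pos[, "z"] <- pos[, "z"] + rnorm(n, 0, zErr)
  }
  ## corrupt the FIB-side centre of the first marker
  p2 <- markerPositions(inst$set2d)
  p2[1, ] <- p2[1, ] + c(1500, -1200)
  list(set3d = markerSet3D(markerIds(inst$set3d), pos),
       set2d = markerSet2D(markerIds(inst$set2d), p2),
       corr = inst$corr, truth = inst$truth,
       truePos = markerPositions(inst$set3d))
}

test_that("outlier rejection drops only large-deviation markers", {
  ## all deviations equal: nothing rejected
  dev <- stats::setNames(rep(2.5, 8), paste0("m", 1:8))
  res <- new("RegistrationResult", angles = eulerAngles(), sd = 2.5,
             perMarkerDeviation = dev, usedIds = names(dev),
             rejectedIds = character(0), nIterations = 1L,
             converged = TRUE, centroid3d = c(0, 0, 0),
             centroid2d = c(0, 0))
  sel <- rejectOutliers(res)
  expect_length(sel$rejected, 0)
  ## one marker at 10x the RMS among 8: exactly that one goes
  dev2 <- dev; dev2["m3"] <- 10 * sqrt(mean(dev^2))
  res@perMarkerDeviation <- dev2
  sel2 <- rejectOutliers(res)
  expect_equal(sel2$rejected, "m3")
  ## floor rule: with minMarkers = 4 and 4 markers nothing is dropped
  dev3 <- stats::setNames(c(1, 1, 1, 100), paste0("m", 1:4))
  res3 <- new("RegistrationResult", angles = eulerAngles(), sd = 50,
              perMarkerDeviation = dev3, usedIds = names(dev3),
              rejectedIds = character(0), nIterations = 1L,
              converged = TRUE, centroid3d = c(0, 0, 0),
              centroid2d = c(0, 0))
  sel3 <- rejectOutliers(res3, refinementPolicy(minMarkers = 4L))
  expect_length(sel3$rejected, 0)
})

test_that("closed-form z update matches a brute-force scan and respects bounds", {
  inst <- makeExactInstance(51, n = 8)
  ## corrupt one z by +300 nm; the model is otherwise exact
  bad <- setMarkerZ(inst$set3d, "m4",
                    markerPositions(inst$set3d)["m4", "z"] + 300)
  fit <- solveRotation(inst$set3d, inst$set2d, inst$corr)
  zopt <- optimizeMarkerZ(bad, inst$set2d, inst$corr, inst$truth,
                          refinementPolicy(zBound = 500))
  ## z is identified only relative to the set (a common z shift leaves
  ## the centred projection unchanged), so compare centred z values
  zGot <- markerPositions(zopt$set3d)[, "z"]
  zTrue <- markerPositions(inst$set3d)[, "z"]
  expect_lt(abs((zGot["m4"] - mean(zGot)) -
                  (zTrue["m4"] - mean(zTrue))), 1)

  ## brute-force 1 nm scan oracle for every marker
  r <- rotationMatrix(inst$truth)
  pol <- refinementPolicy(zBound = 500)
  m <- markerPositions(bad)
  mu3 <- centroid(bad); mu2 <- centroid(inst$set2d)
  f <- markerPositions(inst$set2d)
  for (id in c("m1", "m4", "m7")) {
    grid <- seq(m[id, "z"] - 500, m[id, "z"] + 500, by = 1)
    vals <- vapply(grid, function(z) {
      p <- m[id, ]; p["z"] <- z
      pr <- r[1:2, ] %*% (p - mu3)
      sum((pr - (f[id, ] - mu2))^2)
    }, numeric(1))
    zScan <- grid[which.min(vals)]
    zClosed <- markerPositions(zopt$set3d)[id, "z"]
    expect_lt(abs(zClosed - zScan), 1)
  }

  ## clamp: a huge corruption is pulled at most zBound from measured z
  far <- setMarkerZ(inst$set3d, "m2",
                    markerPositions(inst$set3d)["m2", "z"] + 5000)
  zopt2 <- optimizeMarkerZ(far, inst$set2d, inst$corr, inst$truth, pol)
  moved <- markerPositions(zopt2$set3d)["m2", "z"] -
    markerPositions(far)["m2", "z"]
  expect_lte(abs(moved), 500 + 1e-9)
})

test_that("z is unobservable at zero tilt and markers are flagged", {
  inst <- makeExactInstance(52, angles = c(0, 0, 0))
  zopt <- optimizeMarkerZ(inst$set3d, inst$set2d, inst$corr,
                          eulerAngles())
  expect_equal(zopt$flagged, markerIds(inst$set3d))
  expect_equal(markerPositions(zopt$set3d),
               markerPositions(inst$set3d))
})

test_that("iterated refinement converges, rejects the outlier and never increases SD", {
  inst <- makeCorruptedInstance(61, n = 10)
  first <- suppressWarnings(
    solveRotation(inst$set3d, inst$set2d, inst$corr))
  ref <- suppressWarnings(
    iterateRegistration(inst$set3d, inst$set2d, inst$corr))
  expect_lte(registrationSD(ref), registrationSD(first))
  expect_true("m1" %in% rejectedIds(ref))
  ## audit trail exists and SD is non-increasing across rounds
  sds <- vapply(ref@rounds, `[[`, 0, "sd")
  expect_true(all(diff(sds) <= 1e-9))

  ## noiseless input converges immediately with ~zero SD
  clean <- makeExactInstance(62)
  ref0 <- iterateRegistration(clean$set3d, clean$set2d, clean$corr)
  expect_lt(registrationSD(ref0), 1e-6)
  expect_length(rejectedIds(ref0), 0)

  ## huge sd_tol: exactly one round
  ref1 <- suppressWarnings(
    iterateRegistration(inst$set3d, inst$set2d, inst$corr,
                        policy = refinementPolicy(sdTol = 1e9)))
  expect_length(ref1@rounds, 1)
})

test_that("refinement with zBound 0 and no rejection reduces to the plain solve", {
  inst <- makeExactInstance(63, n = 8)
  plain <- solveRotation(inst$set3d, inst$set2d, inst$corr)
  ref <- iterateRegistration(inst$set3d, inst$set2d, inst$corr,
                             policy = refinementPolicy(
                               zBound = 0, outlierFactor = 1e18))
  expect_equal(anglesRad(ref), anglesRad(plain), tolerance = 1e-10)
  expect_equal(registrationSD(ref), registrationSD(plain),
               tolerance = 1e-10)
  expect_length(rejectedIds(ref), 0)
})

test_that("refinement recovers corrupted z coordinates on noisy scenes", {
  ## 20 seeded noisy scenes: SD never increases through refinement
  for (s in 1:20) {
    sc <- makeScene(12, seed = s, extents = c(5e4, 5e4, 1e4))
    sim <- simulateLocalizations(sc)
    f0 <- solveRotation(sim$set3d, sim$set2d, sim$corr)
    fr <- iterateRegistration(sim$set3d, sim$set2d, sim$corr)
    kept <- correspondence(usedIds(fr))
    f1 <- solveRotation(refinedMarkers(fr), sim$set2d, kept)
    ## over the final kept set, the refined state beats the unrefined
    f0k <- solveRotation(sim$set3d, sim$set2d, kept)
    expect_lte(registrationSD(f1), registrationSD(f0k) + 1e-9)
    ## clamp respected for every marker
    dz <- markerPositions(refinedMarkers(fr))[, "z"] -
      markerPositions(sim$set3d)[, "z"]
    expect_lte(max(abs(dz)), 500 + 1e-9)
  }
})
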