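test_that("centroid is the per-coordinate arithmetic mean", {
  s <- markerSet3D(positions = rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(unname(centroid(s)), c(1, 0, 0))

  s1 <- markerSet3D(positions = rbind(c(3.5, -2, 7)))
  expect_equal(unname(centroid(s1)), c(3.5, -2, 7))

  set.seed(11)
  p <- matrix(runif(27, -1e4, 1e4), 9, 3)
  ## independent summation oracle
  ora <- c(sum(p[, 1]), sum(p[, 2]), sum(p[, 3])) / 9
  expect_equal(unname(centroid(markerSet3D(positions = p))), ora,
               tolerance = 1e-12)

  p2 <- matrix(runif(10, -5e3, 5e3), 5, 2)
  expect_equal(unname(centroid(markerSet2D(positions = p2))),
               colMeans(p2))
  expect_error(centroid(markerSet3D(character(0),
                                    matrix(numeric(0), 0, 3),
                                    character(0))),
               "empty")
})

test_that("rotation matrix matches the closed-form Z-Y-X composite", {
  expect_equal(rotationMatrix(eulerAngles()), diag(3))
  ## quarter turn about z maps x onto y
  r <- rotationMatrix(eulerAngles(thetaZ = pi / 2))
  expect_equal(as.numeric(r %*% c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    th <- runif(3, -pi, pi)
    r <- rotationMatrix(eulerAngles(th[1], th[2], th[3]))
    expect_equal(r, oracleRotation(th[1], th[2], th[3]),
                 tolerance = 1e-12)
    expect_equal(crossprod(r), diag(3), tolerance = 1e-12)
    expect_equal(det(r), 1, tolerance = 1e-12)
  }
})

test_that("projection centres, rotates and drops z", {
  s <- markerSet3D(positions = rbind(c(0, 0, 0), c(1000, 500, 200),
                                     c(-400, 300, 900)))
  ## zero angles: centred (x, y)
  p <- projectToFib(s, eulerAngles())
  ctr <- centroid(s)
  expect_equal(unname(p),
               unname(sweep(markerPositions(s)[, 1:2], 2, ctr[1:2])))
  ## 90 deg about y maps centred (0,0,d) to (d,0)
  s2 <- markerSet3D(positions = rbind(c(0, 0, 0), c(0, 0, 1000)))
  p2 <- projectToFib(s2, eulerAngles(thetaY = pi / 2))
  expect_equal(unname(p2[2, ] - p2[1, ]), c(1000, 0), tolerance = 1e-9)
  ## linearity: projected centroid is (0,0) for any input
  set.seed(21)
  for (i in 1:10) {
    sr <- markerSet3D(positions = matrix(runif(18, -1e4, 1e4), 6, 3))
    th <- runif(3, -pi, pi)
    pr <- projectToFib(sr, eulerAngles(th[1], th[2], th[3]))
    expect_lt(max(abs(colMeans(pr))), 1e-9)
  }
})

test_that("FIB centring subtracts the centroid exactly", {
  s <- markerSet2D(positions = rbind(c(10, 10), c(30, 10)))
  expect_equal(unname(centerFib(s)), rbind(c(-10, 0), c(10, 0)))
  s1 <- markerSet2D(positions = rbind(c(123, -45)))
  expect_equal(unname(centerFib(s1)), rbind(c(0, 0)))
  set.seed(5)
  sr <- markerSet2D(positions = matrix(runif(40, -1e5, 1e5), 20, 2))
  expect_lt(max(abs(colMeans(centerFib(sr)))), 1e-9)
  expect_error(centerFib(markerSet2D(character(0),
                                     matrix(numeric(0), 0, 2))),
               "empty")
})

test_that("residual SD is the RMS pair distance", {
  a <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("p", "q"), c("x", "y")))
  expect_equal(residualSD(a, a), 0)
  ## single pair offset by (3,4): 3-4-5
  b <- a; b["p", ] <- b["p", ] + c(3, 4)
  expect_equal(residualSD(b["p", , drop = FALSE],
                          a["p", , drop = FALSE]), 5)
  set.seed(9)
  x <- matrix(rnorm(18), 9, 2, dimnames = list(paste0("m", 1:9), NULL))
  y <- matrix(rnorm(18), 9, 2, dimnames = list(paste0("m", 1:9), NULL))
  expect_equal(residualSD(x, y), unname(oracleSD(x, y)),
               tolerance = 1e-9)
  ## invariant under relabelling of pairs
  perm <- sample(9)
  expect_equal(residualSD(x[perm, ], y[perm, ],
                          correspondence(paste0("m", perm))),
               residualSD(x, y), tolerance = 1e-12)
  ## unmatched id errors
  rownames(y)[1] <- "zz"
  expect_error(residualSD(x, y, correspondence(paste0("m", 1:9))),
               "unknown 2D")
})

test_that("noiseless solves recover the generating angles exactly", {
  inst <- makeExactInstance(42)
  fit <- solveRotation(inst$set3d, inst$set2d, inst$corr)
  expect_lt(max(abs(anglesRad(fit) - anglesRad(inst$truth))), 1e-4)
  expect_lt(registrationSD(fit), 1e-6)
  expect_true(fit@converged)
  ## markers already in the FIB frame: zero angles, zero SD
  s3 <- inst$set3d
  flat <- markerSet3D(markerIds(s3), markerPositions(s3))
  p0 <- markerPositions(s3)[, 1:2]
  s20 <- markerSet2D(markerIds(s3), p0)
  fit0 <- solveRotation(flat, s20, inst$corr)
  expect_lt(max(abs(anglesRad(fit0))), 1e-6)
  expect_lt(registrationSD(fit0), 1e-6)
})

test_that("solver matches a 1-degree exhaustive grid on a 6-bead instance", {
  inst <- makeExactInstance(3, n = 6)
  g <- oracleGridSearch(markerPositions(inst$set3d),
                        markerPositions(inst$set2d), stepDeg = 1)
  fit <- solveRotation(inst$set3d, inst$set2d, inst$corr)
  expect_lte(registrationSD(fit), g$sd + 1e-9)
  expect_lt(max(abs(anglesRad(fit) - g$angles)), 1 * pi / 180 + 1e-9)
})

test_that("degenerate geometries raise the specified errors", {
  inst <- makeExactInstance(8)
  short <- correspondence(markerIds(inst$set3d)[1:2])
  expect_error(solveRotation(inst$set3d, inst$set2d, short),
               "at least 3")
  ## collinear 3D configuration
  line <- markerSet3D(positions = cbind(1:6 * 1000, 1:6 * 500,
                                        1:6 * 200))
  l2 <- markerSet2D(ids = markerIds(line),
                    positions = cbind(1:6 * 900, 1:6 * 450))
  expect_error(solveRotation(line, l2, correspondence(markerIds(line))),
               "collinear")
  ## 3-4 markers warn about stability
  expect_warning(
    solveRotation(inst$set3d, inst$set2d,
                  correspondence(markerIds(inst$set3d)[1:4])),
    "5 or more")
})

test_that("planar configurations are flagged with their mirror solution", {
  set.seed(14)
  pos <- cbind(runif(8, 0, 5e4), runif(8, 0, 5e4), rep(3000, 8))
  s3 <- markerSet3D(positions = pos)
  truth <- eulerAngles(0.3, -0.2, 0.5)
  proj <- projectToFib(s3, truth)
  s2 <- markerSet2D(ids = rownames(proj), positions = proj)
  fit <- solveRotation(s3, s2, correspondence(markerIds(s3)))
  expect_true(fit@mirrorAmbiguity)
  ## solution is the truth or its documented mirror (-tx, -ty, tz)
  got <- anglesRad(fit)
  mirror <- c(-0.3, 0.2, 0.5)
  expect_true(max(abs(got - c(0.3, -0.2, 0.5))) < 1e-4 ||
                max(abs(got - mirror)) < 1e-4)
  expect_lt(registrationSD(fit), 1e-6)
  ## prior tie-break: a prior at the truth selects the truth
  optsP <- solverOptions(prior = truth)
  fitP <- solveRotation(s3, s2, correspondence(markerIds(s3)), optsP)
  expect_lt(max(abs(anglesRad(fitP) - anglesRad(truth))), 1e-4)
})

test_that("applyModel maps centroid to centroid and fits its own markers", {
  inst <- makeExactInstance(17)
  fit <- solveRotation(inst$set3d, inst$set2d, inst$corr)
  mu3 <- centroid(inst$set3d)
  mu2 <- centroid(inst$set2d)
  expect_equal(as.numeric(applyModel(rbind(mu3), fit, inst$set3d,
                                     inst$set2d)),
               unname(mu2), tolerance = 1e-9)
  ## a registration marker maps to within its stored deviation
  pred <- applyModel(inst$set3d, fit, inst$set3d, inst$set2d)
  obs <- markerPositions(inst$set2d)
  d <- sqrt(rowSums((pred - obs)^2))
  expect_true(all(d <= markerDeviations(fit) + 1e-9))
  ## zero angles: pure centroid shift
  flat3 <- markerSet3D(positions = rbind(c(0, 0, 0), c(1000, 0, 0),
                                         c(0, 1500, 400),
                                         c(800, 900, 100)))
  p0 <- markerPositions(flat3)[, 1:2]
  flat2 <- markerSet2D(ids = markerIds(flat3),
                       positions = sweep(p0, 2, c(100, -50), "+"))
  fit0 <- suppressWarnings(
    solveRotation(flat3, flat2, correspondence(markerIds(flat3))))
  tgt <- c(123, 456, 789)
  got <- as.numeric(applyModel(rbind(tgt), fit0, flat3, flat2))
  mu3f <- centroid(flat3); mu2f <- centroid(flat2)
  expect_equal(got, unname(c(tgt[1] - mu3f[1] + mu2f[1],
                             tgt[2] - mu3f[2] + mu2f[2])),
               tolerance = 1e-6)
})

test_that("configuration diagnostics report extents, planarity and straddling", {
  ## identical z: planarity 0, warning
  s <- markerSet3D(positions = cbind(c(0, 1e4, 2e4, 3e4),
                                     c(-1e4, -5e3, 5e3, 1e4),
                                     rep(2000, 4)))
  expect_warning(q <- configurationQuality(s), "planar")
  expect_equal(q$planarity, 0, tolerance = 1e-9)
  expect_true(any(grepl("planar", q$warnings)))
  ## straddling in y around a target at y = 0
  expect_true(q$straddlesY ||
                is.na(q$straddlesY))  # no target given yet
  q2 <- suppressWarnings(
    configurationQuality(s, target = c(0, 0, 0)))
  expect_true(q2$straddlesY)
  ## extents match a min/max oracle
  set.seed(33)
  p <- matrix(runif(30, -2e4, 2e4), 10, 3)
  s3 <- markerSet3D(positions = p)
  q3 <- suppressWarnings(configurationQuality(s3))
  expect_equal(q3$yExtent, max(p[, 2]) - min(p[, 2]))
  expect_equal(q3$zExtent, max(p[, 3]) - min(p[, 3]))
  ## one-sided configuration does not straddle
  oneSided <- markerSet3D(positions = cbind(runif(5), runif(5, 10, 20),
                                            runif(5, 0, 1e4)))
  q4 <- suppressWarnings(configurationQuality(oneSided,
                                              target = c(0, 0, 0)))
  expect_false(q4$straddlesY)
})

test_that("fitted scale recovers a pixel-size calibration error", {
  inst <- makeExactInstance(29)
  ## shrink the FIB coordinates by 3%
  bad2 <- markerSet2D(markerIds(inst$set2d),
                      markerPositions(inst$set2d) * 0.97)
  opts <- solverOptions(fitScale = TRUE)
  fit <- solveRotation(inst$set3d, bad2, inst$corr, opts)
  expect_equal(fit@scale, 0.97, tolerance = 1e-4)
  expect_lt(registrationSD(fit), 1e-4)
  ## faithful mode has no scale freedom
  fit1 <- solveRotation(inst$set3d, bad2, inst$corr)
  expect_equal(fit1@scale, 1)
})
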