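## Independent oracles used across the suite.  None of these call into
## the package's registration path: the rotation oracle is the
## hand-expanded closed form of the Z-Y-X composite, the residual oracle
## is an explicit loop sum, and the grid oracle is an exhaustive search
## evaluating the residual through its own moment algebra.

## closed-form entries of R_x(tx) R_y(ty) R_z(tz), expanded by hand
oracleRotation <- function(tx, ty, tz) {
  cx <- cos(tx); sx <- sin(tx)
  cy <- cos(ty); sy <- sin(ty)
  cz <- cos(tz); sz <- sin(tz)
  matrix(c(
    cy * cz,                 -cy * sz,                 sy,
    cx * sz + sx * sy * cz,   cx * cz - sx * sy * sz, -sx * cy,
    sx * sz - cx * sy * cz,   sx * cz + cx * sy * sz,  cx * cy),
    nrow = 3, byrow = TRUE)
}

## explicit loop-sum RMS distance over pairs
oracleSD <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  tot <- 0
  for (i in seq_len(nrow(a)))
    tot <- tot + (a[i, 1] - b[i, 1])^2 + (a[i, 2] - b[i, 2])^2
  sqrt(tot / nrow(a))
}

## exhaustive grid search over angle triples; returns the best node and
## its SD.  Evaluates n*SD^2 = tr(R2 S R2') - 2 tr(C R2') + sum(F^2)
## through precomputed moments of the centred coordinates (exact
## algebra, O(1) per node), chunked over nodes to bound memory.
oracleGridSearch <- function(x3, f2, stepDeg, boundsDeg = c(-90, 90)) {
  xc <- sweep(x3, 2, colMeans(x3))
  fc <- sweep(f2, 2, colMeans(f2))
  S <- crossprod(xc); C <- crossprod(fc, xc); F2 <- sum(fc^2)
  n <- nrow(xc)
  ax <- seq(boundsDeg[1], boundsDeg[2], by = stepDeg) * pi / 180
  na <- length(ax)
  cosA <- cos(ax); sinA <- sin(ax)
  bestVal <- Inf; bestIdx <- c(NA, NA, NA)
  ## chunk over tx; vectorize over (ty, tz) pairs
  ty <- rep(ax, times = na); tz <- rep(ax, each = na)
  cyv <- cos(ty); syv <- sin(ty); czv <- cos(tz); szv <- sin(tz)
  m11 <- cyv * czv; m12 <- -cyv * szv; m13 <- syv
  q11 <- S[1,1]*m11^2 + S[2,2]*m12^2 + S[3,3]*m13^2 +
    2*(S[1,2]*m11*m12 + S[1,3]*m11*m13 + S[2,3]*m12*m13)
  c1 <- C[1,1]*m11 + C[1,2]*m12 + C[1,3]*m13
  for (i in seq_len(na)) {
    cx <- cosA[i]; sx <- sinA[i]
    m21 <- cx * szv + sx * syv * czv
    m22 <- cx * czv - sx * syv * szv
    m23 <- -sx * cyv
    q22 <- S[1,1]*m21^2 + S[2,2]*m22^2 + S[3,3]*m23^2 +
      2*(S[1,2]*m21*m22 + S[1,3]*m21*m23 + S[2,3]*m22*m23)
    c2 <- C[2,1]*m21 + C[2,2]*m22 + C[2,3]*m23
    vals <- q11 + q22 - 2 * (c1 + c2) + F2
    j <- which.min(vals)
    if (vals[j] < bestVal) {
      bestVal <- vals[j]
      bestIdx <- c(i, (j - 1) %% na + 1, (j - 1) %/% na + 1)
    }
  }
  list(angles = c(ax[bestIdx[1]], ax[bestIdx[2]], ax[bestIdx[3]]),
       sd = sqrt(max(bestVal, 0) / n))
}

## reproducible non-planar bead configuration + its exact projection
makeExactInstance <- function(seed, n = 8, angles = c(0.3, -0.2, 0.5),
                              extents = c(5e4, 5e4, 8e3),
                              offset = c(4000, -2500)) {
  set.seed(seed)
  pos <- cbind(x = runif(n, 0, extents[1]), y = runif(n, 0, extents[2]),
               z = runif(n, 0, extents[3]))
  s3 <- markerSet3D(positions = pos)
  a <- eulerAngles(angles[1], angles[2], angles[3])
  proj <- projectToFib(s3, a)
  s2 <- markerSet2D(ids = rownames(proj),
                    positions = sweep(proj, 2, offset, "+"))
  list(set3d = s3, set2d = s2, corr = correspondence(markerIds(s3)),
       truth = a)
}
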