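## rendered-scene fixture: beads kept away from the stack borders and
## from each other, as one would prepare a bead slide for a
## localization / targeting accuracy measurement
smallScene <- function(seed = 201, n = 5, extents = c(2e4, 2e4, 6e3),
                       margin = 2000, minSep = 2600) {
  for (s in seed + 0:100) {
    sc <- makeScene(n, extents = extents, seed = s,
                    noise = c(sigmaXY = 0, sigmaZ = 0, sigmaFIB = 0))
    p <- sweep(sc@positions, 2, extents, "/")
    p <- sweep(sweep(p, 2, extents - 2 * margin, "*"), 2, margin, "+")
    sc@positions <- p
    if (n == 1L || min(dist(p)) >= minSep) return(sc)
  }
  stop("no admissible bead configuration found")
}
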