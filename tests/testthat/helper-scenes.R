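## Small fixture builders shared across test files.

## a compact FA scene: 12 x 12 um cell in a 25.6 um field
smallFaScene <- function(fociSpecs = NULL, seed = 1, ...) {
  poly <- cbind(c(6, 18, 18, 6), c(6, 6, 18, 18))
  faScene(poly, fociSpecs, imageShape = c(256L, 256L), pixelSize = 0.1,
          seed = seed, ...)
}

## standard mixed foci: five 1.0 um^2 disks and two 0.3 um^2 disks
mixedFociSpecs <- function() {
  data.frame(cx = c(8, 10, 14, 16, 9, 12, 15),
             cy = c(8, 10, 14, 16, 15, 7, 11),
             areaUm2 = c(rep(1.0, 5), 0.3, 0.3),
             peak = 20000)
}

## match localized pillars to generator ground truth by nearest true spot;
## returns truth rows aligned to the pillar table rows
matchToTruth <- function(pillarTable, truth) {
  tx <- truth$nodeX + truth$trueDx
  ty <- truth$nodeY + truth$trueDy
  idx <- vapply(seq_len(nrow(pillarTable)), function(i) {
    which.min((tx - pillarTable$cx[i])^2 + (ty - pillarTable$cy[i])^2)
  }, integer(1))
  truth[idx, , drop = FALSE]
}

## brute-force Benjamini-Hochberg step-up, straight from the definition
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m] * m / (i:m))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
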