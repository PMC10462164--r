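test_that("localization matches analytic spot centres", {
  ## single Gaussian spot at a known sub-pixel position
  img <- matrix(100, 64, 64)
  img <- cellmech:::addGaussianSpot(img, 3.217, 2.871, 1000, 0.15, 0.1)
  loc <- localizePillars(img, 1.0, 0.1, background = 100)
  expect_equal(nrow(loc), 1L)
  expect_lt(abs(loc$cx - 3.217), 1e-3)
  expect_lt(abs(loc$cy - 2.871), 1e-3)
  ## blank image: empty result with a warning
  expect_warning(empty <- localizePillars(matrix(100, 32, 32), 1, 0.1,
                                          background = 100,
                                          threshold = 200),
                 "no pillar")
  expect_equal(nrow(empty), 0L)
})

test_that("grid fit recovers exact, rotated and jittered lattices", {
  nodes <- expand.grid(i = 0:7, j = 0:7)
  xy <- data.frame(cx = nodes$i * 1.0 + 2, cy = nodes$j * 1.0 + 2)
  lat <- fitReferenceGrid(xy, 1.0)
  expect_equal(lat@rmsResidual, 0, tolerance = 1e-10)
  B <- lat@basis
  expect_equal(sort(abs(as.numeric(B))), c(0, 0, 1, 1), tolerance = 1e-9)
  ## 5 degree rotation: basis recovered within 0.1 degree and 0.005 um
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- as.matrix(xy) %*% t(R)
  latR <- fitReferenceGrid(data.frame(cx = rot[, 1], cy = rot[, 2]), 1.0)
  ang <- atan2(latR@basis[2, 1], latR@basis[1, 1]) %% (pi / 2)
  expect_lt(abs(ang - th), 0.1 * pi / 180)
  expect_lt(abs(sqrt(sum(latR@basis[, 1]^2)) - 1.0), 0.005)
  expect_equal(latR@rmsResidual, 0, tolerance = 1e-9)
  ## isotropic 0.02 um jitter shows up as the rms residual
  res <- vapply(1:10, function(s) {
    set.seed(s)
    jit <- xy + matrix(rnorm(nrow(xy) * 2, 0, 0.02), ncol = 2)
    fitReferenceGrid(jit, 1.0)@rmsResidual
  }, numeric(1))
  ## 2D rms of per-axis sd 0.02 is 0.0283; lattice fit absorbs a little
  expect_equal(mean(res), 0.0283, tolerance = 0.15)
  ## under-determined and broken-grid inputs are rejected
  expect_error(fitReferenceGrid(xy[1:5, ], 1.0), "6 reference")
  expect_error(fitReferenceGrid(xy * 2, 1.0), "pitch")
})

test_that("grid fit is translation- and rotation-equivariant", {
  set.seed(42)
  nodes <- expand.grid(i = 0:6, j = 0:6)
  xy <- as.matrix(nodes) * 1.0 +
    matrix(rnorm(nrow(nodes) * 2, 0, 0.01), ncol = 2) + 3
  lat <- fitReferenceGrid(data.frame(cx = xy[, 1], cy = xy[, 2]), 1.0)
  th <- 20 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(1.3, -0.7)
  xyT <- sweep(xy %*% t(R), 2, shift, "+")
  latT <- fitReferenceGrid(data.frame(cx = xyT[, 1], cy = xyT[, 2]), 1.0)
  expect_equal(latT@rmsResidual, lat@rmsResidual, tolerance = 1e-6)
  ## transformed basis spans the same lattice: R B and fitted basis agree
  ## up to column permutation/sign
  BT <- latT@basis
  RB <- R %*% lat@basis
  match1 <- min(apply(abs(cbind(BT[, 1] - RB[, 1], BT[, 1] + RB[, 1],
                                BT[, 1] - RB[, 2], BT[, 1] + RB[, 2])),
                      2, max))
  expect_lt(match1, 1e-6)
})

test_that("displacement assignment and magnitudes follow the lattice", {
  lat <- new("PillarLattice", origin = c(0, 0), basis = diag(2),
             rmsResidual = 0, nominalPitch = 1)
  cent <- data.frame(cx = c(2, 3.03, 5.4), cy = c(2, 4.04, 6.4))
  fld <- computeDisplacements(cent, lat, noiseFloor = 0.02)
  p <- pillars(fld)
  expect_equal(p$magnitude[1], 0)
  expect_equal(p$magnitude[2], 0.05)          # 3-4-5 arithmetic
  expect_true(p$aboveNoise[2])
  expect_false(p$assigned[3])                 # ~(0.4,0.4): beyond pitch/2
  expect_false(p$aboveNoise[3])
})

test_that("noise floor is the 95th percentile of reference magnitudes", {
  expect_equal(estimateNoiseFloor(rep(0, 10)), 0)
  ## sort-and-interpolate oracle on six values
  mags <- c(10, 10, 10, 10, 10, 30) / 1000
  s <- sort(mags)
  h <- (length(s) - 1) * 0.95 + 1
  oracle <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  expect_equal(estimateNoiseFloor(mags), oracle)
  expect_equal(oracle, 0.025)
  ## Rayleigh magnitudes from 0.01 um/axis jitter: floor near 0.0245
  set.seed(1)
  m <- sqrt(rnorm(20000, 0, 0.01)^2 + rnorm(20000, 0, 0.01)^2)
  expect_equal(estimateNoiseFloor(m), 0.01 * sqrt(-2 * log(0.05)),
               tolerance = 0.02)
  expect_error(estimateNoiseFloor(c(0, 0)), "6 reference")
})

test_that("stiffness model reproduces closed-form and symbolic values", {
  g <- pillarGeometry(diameter = 0.5, height = 1.3)
  m <- pillarMaterial(2e6, 0.5)
  sm <- pillarStiffness(g, m)
  ## direct arithmetic of the bending formula
  expect_equal(bendingStiffness(sm), 0.008378593288405865,
               tolerance = 1e-12)
  ## power laws to machine precision
  sm2D <- pillarStiffness(pillarGeometry(diameter = 1.0, height = 1.3,
                                         pitch = 2.5), m)
  expect_equal(bendingStiffness(sm2D) / bendingStiffness(sm), 16,
               tolerance = 1e-12)
  sm2H <- pillarStiffness(pillarGeometry(diameter = 0.5, height = 2.6), m)
  expect_equal(bendingStiffness(sm2H) / bendingStiffness(sm), 1 / 8,
               tolerance = 1e-12)
  ## symbolic-evaluation oracle for the correction over a (L/D, v) grid
  frozen <- rbind(
    c(1.0, 0.0, 0.375757881940631),
    c(1.0, 0.3, 0.370679348225581),
    c(1.0, 0.5, 0.374340534272786),
    c(2.6, 0.0, 0.651293242899338),
    c(2.6, 0.3, 0.656683745136218),
    c(2.6, 0.5, 0.668939503974006),
    c(5.0, 0.0, 0.792231296996074),
    c(5.0, 0.3, 0.799009301469756),
    c(5.0, 0.5, 0.810193601538642))
  for (i in seq_len(nrow(frozen))) {
    ld <- frozen[i, 1]; v <- frozen[i, 2]
    sm_i <- pillarStiffness(pillarGeometry(diameter = 0.5, height = 0.5 * ld,
                                           pitch = 1),
                            pillarMaterial(2e6, v))
    expect_equal(sm_i@corr, frozen[i, 3], tolerance = 1e-12)
    ## independent compliance-sum route: corr = d_bend / (d_bend + d_shear
    ## + d_tilt) for a cylindrical cantilever on an elastic half-space
    E <- 2e6; D <- 0.5e-6; L <- 0.5e-6 * ld
    I <- pi * D^4 / 64; A <- pi * D^2 / 4; G <- E / (2 * (1 + v))
    dBend <- L^3 / (3 * E * I)
    kappa <- 6 * (1 + v) / (7 + 6 * v)       # Timoshenko circular section
    dShear <- L / (kappa * G * A)
    tT <- 1.3 * (1 + v) / (2 * pi^2 * (1 - v)) + 1 - 1 / (4 * (1 - v))
    dTilt <- 8 * tT * (L / D)^2 * 4 / (pi * E * D)
    expect_equal(sm_i@corr, dBend / (dBend + dShear + dTilt),
                 tolerance = 1e-10)
  }
  ## effective modulus definition and the incompressible-singularity guard
  expect_equal(effectiveModulus(sm), 9 * springConstant(sm) /
                 (4 * pi * 0.25e-6), tolerance = 1e-12)
})

test_that("correction stays in (0,1] and forces are linear", {
  for (ld in c(1, 2, 4, 8)) {
    for (v in c(0, 0.25, 0.49)) {
      sm <- pillarStiffness(pillarGeometry(0.5, 0.5 * ld, 1),
                            pillarMaterial(2e6, v))
      expect_gt(sm@corr, 0)
      expect_lte(sm@corr, 1)
      expect_lte(springConstant(sm), bendingStiffness(sm))
    }
  }
  ## F = k d with unit bookkeeping: k ~ 8.4e-3 N/m at |d| = 0.05 um
  lat <- new("PillarLattice", origin = c(0, 0), basis = diag(2),
             rmsResidual = 0, nominalPitch = 1)
  cent <- data.frame(cx = c(1.03, 2.05), cy = c(1.04, 2.0))
  fld <- computeDisplacements(cent, lat, noiseFloor = 0.01)
  sm <- pillarStiffness()
  f <- displacementToForce(fld, sm)
  expect_equal(f$force[1], sm@k * 1e3 * 0.05, tolerance = 1e-9)
  expect_equal(f$force[1], 0.28, tolerance = 0.02)  # nN scale
  ## doubling displacements doubles forces; doubling E doubles forces
  fld2 <- computeDisplacements(data.frame(cx = c(1.06, 2.10),
                                          cy = c(1.08, 2.0)),
                               lat, noiseFloor = 0.01)
  f2 <- displacementToForce(fld2, sm)
  expect_equal(f2$force, 2 * f$force, tolerance = 1e-9)
  smE <- pillarStiffness(pillarGeometry(), pillarMaterial(4e6, 0.5))
  fE <- displacementToForce(fld, smE)
  expect_equal(fE$force, 2 * f$force, tolerance = 1e-9)
})

test_that("edge-band summary selects pillars by distance to the cell edge", {
  px <- 0.1
  mask <- cellmech:::diskMask(12.8, 12.8, 10, c(256L, 256L), px)
  mkForces <- function(xy) {
    data.frame(cx = xy[, 1], cy = xy[, 2], insideCell = TRUE,
               aboveNoise = TRUE, force = 1)
  }
  ## pillars at the centre of a 10 um-radius disk, band 5 um: none in band
  ctr <- mkForces(cbind(c(12.8, 12.9), c(12.8, 12.7)))
  s <- edgeBandSummary(ctr, mask, px, bandWidth = 5)
  expect_equal(s$n, 0L)
  expect_true(s$empty)
  ## pillars near the rim fall in the band
  rim <- mkForces(cbind(12.8 + c(9, 8.5, 0), 12.8 + c(0, 0, 9)))
  s2 <- edgeBandSummary(rim, mask, px, bandWidth = 5)
  expect_equal(s2$n, 3L)
  ## band wider than the disk radius reduces to the whole-cell summary
  all3 <- mkForces(cbind(12.8 + c(9, 0, 3), 12.8 + c(0, 0, 3)))
  sWide <- edgeBandSummary(all3, mask, px, bandWidth = 20)
  expect_equal(sWide$n, 3L)
  expect_equal(sWide$totalForce, 3)
})

test_that("noise gating keeps sub-noise pillars quiet on undisplaced scenes", {
  sc <- pillarScene(imageShape = c(256L, 256L), seed = 31)
  out <- makePillarImage(sc)
  res <- tfmPipeline(out$image, sc$cellMask, sc$pixelSize)
  p <- pillars(res$field)
  ## no displacement imposed: above-noise fraction under the cell is near
  ## the 5% implied by the 95th-percentile floor (binomial slack, n ~ 130)
  frac <- mean(p$aboveNoise[p$insideCell])
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / sum(p$insideCell)))
})
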