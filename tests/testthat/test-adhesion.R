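test_that("cell segmentation thresholds above background and is monotone", {
  ## uniform raster: nothing exceeds background + offset
  expect_error(segmentCell(matrix(500, 64, 64), 0.1), "no cell")
  ## synthetic scene: mask area matches the polygon area within 2%
  sc <- smallFaScene(NULL)
  im <- makeFaImage(sc)
  mask <- segmentCell(im$image[, , 3], sc$pixelSize)
  expect_equal(cellArea(mask), 144, tolerance = 0.02)
  expect_equal(mask@threshold, mask@backgroundLevel + 100)
  ## higher offset gives a nested mask
  maskHi <- segmentCell(im$image[, , 3], sc$pixelSize, offset = 1000)
  expect_true(all(maskRaster(mask)[maskRaster(maskHi)]))
})

test_that("foci detection recovers planted disks and applies the filters", {
  sc <- smallFaScene(mixedFociSpecs())
  im <- makeFaImage(sc)
  mask <- segmentCell(im$image[, , 3], sc$pixelSize)
  fs <- detectFoci(im$image[, , 2], mask)
  ## the two 0.3 um^2 disks fall below the 0.5 um^2 minimum
  expect_equal(nrow(foci(fs)), 5L)
  expect_equal(foci(fs)$areaUm2, rep(1.0, 5), tolerance = 0.06)
  ## planted centroids recovered
  planted <- mixedFociSpecs()[1:5, ]
  f <- foci(fs)
  ord <- order(f$cx + 100 * f$cy)
  ordP <- order(planted$cx + 100 * planted$cy)
  expect_equal(f$cx[ord], planted$cx[ordP], tolerance = 0.05)
  expect_equal(f$cy[ord], planted$cy[ordP], tolerance = 0.05)
  ## blank channel: zero foci
  blank <- detectFoci(matrix(500, 256, 256), mask)
  expect_equal(nrow(foci(blank)), 0L)
  ## all foci pixels lie inside the cell mask
  expect_true(all(maskRaster(mask)[fociLabels(fs) > 0]))
  ## count is antitone in threshold and min area
  n1 <- nrow(foci(detectFoci(im$image[, , 2], mask, minArea = 1.5)))
  expect_lte(n1, nrow(foci(fs)))
  n2 <- nrow(foci(detectFoci(im$image[, , 2], mask,
                             intensityThreshold = 25000)))
  expect_lte(n2, nrow(foci(fs)))
})

test_that("detection count is antitone under threshold/area fuzzing", {
  set.seed(9)
  for (rep in 1:5) {
    img <- matrix(500 + 200 * runif(64 * 64), 64, 64)
    ## sprinkle bright blobs
    for (k in 1:8) {
      r <- sample(5:60, 1); c <- sample(5:60, 1)
      img[r + (-1:1), c + (-1:1)] <- 15000 + 10000 * runif(1)
    }
    mask <- new("CellMask", mask = matrix(TRUE, 64, 64), pixelSize = 0.2,
                backgroundLevel = 500, threshold = 600)
    thr <- sort(runif(3, 5000, 30000))
    counts <- vapply(thr, function(t)
      nrow(foci(detectFoci(img, mask, intensityThreshold = t,
                           minArea = 0))), integer(1))
    expect_true(all(diff(counts) <= 0))
    areas <- sort(runif(3, 0, 0.3))
    countsA <- vapply(areas, function(a)
      nrow(foci(detectFoci(img, mask, intensityThreshold = 10000,
                           minArea = a))), integer(1))
    expect_true(all(diff(countsA) <= 0))
  }
})

test_that("edge distances equal the exact distance transform", {
  px <- 0.1
  ## 20 um square mask in a larger field; single-pixel focus at the centre
  mask <- matrix(FALSE, 300, 300)
  mask[51:250, 51:250] <- TRUE
  cm <- new("CellMask", mask = mask, pixelSize = px, backgroundLevel = 0,
            threshold = 100)
  lab <- matrix(0L, 300, 300)
  lab[150, 150] <- 1L
  fs <- new("FociSet", labels = lab,
            foci = data.frame(id = 1L, areaUm2 = px^2, cx = 14.95,
                              cy = 14.95, meanVinculin = 1,
                              meanFarRed = 1, minEdgeDistance = NA_real_),
            pixelSize = px)
  fs <- edgeDistances(fs, cm)
  ## centre pixel is 100 px from the nearest outside pixel
  expect_equal(foci(fs)$minEdgeDistance, 10.0, tolerance = 0.05)
  ## focus adjacent to the boundary: distance at most one pixel
  lab2 <- matrix(0L, 300, 300)
  lab2[51, 150] <- 1L
  fs2 <- new("FociSet", labels = lab2, foci = foci(fs), pixelSize = px)
  expect_lte(foci(edgeDistances(fs2, cm))$minEdgeDistance, px)
  ## translating mask and focus together leaves the distance unchanged
  maskT <- matrix(FALSE, 300, 300); maskT[61:260, 71:270] <- TRUE
  labT <- matrix(0L, 300, 300); labT[160, 170] <- 1L
  cmT <- new("CellMask", mask = maskT, pixelSize = px,
             backgroundLevel = 0, threshold = 100)
  fsT <- new("FociSet", labels = labT, foci = foci(fs), pixelSize = px)
  expect_equal(foci(edgeDistances(fsT, cmT))$minEdgeDistance,
               foci(fs)$minEdgeDistance)
})

test_that("per-image summaries pool consistently across images", {
  sc <- smallFaScene(mixedFociSpecs())
  im <- makeFaImage(sc)
  mask <- segmentCell(im$image[, , 3], sc$pixelSize)
  fs <- edgeDistances(detectFoci(im$image[, , 2], mask,
                                 farRed = im$image[, , 1]), mask)
  s <- summarizeAdhesions(fs, mask)
  expect_equal(s$nFoci, 5L)
  expect_false(s$empty)
  f <- foci(fs)
  expect_equal(s$meanFocusAreaUm2, mean(f$areaUm2))
  expect_equal(s$meanEdgeDistanceUm, mean(f$minEdgeDistance))
  ## empty record is flagged
  blank <- detectFoci(matrix(500, 256, 256), mask)
  s0 <- summarizeAdhesions(blank, mask)
  expect_true(s0$empty)
  expect_true(is.na(s0$meanFocusAreaUm2))
  ## pooled recomputation: weighted mean over two images equals a direct
  ## mean over the concatenated focus tables
  f2 <- foci(fs)[1:3, ]
  pooledOracle <- mean(c(f$areaUm2, f2$areaUm2))
  w <- (s$nFoci * s$meanFocusAreaUm2 + 3 * mean(f2$areaUm2)) /
    (s$nFoci + 3)
  expect_equal(w, pooledOracle)
})

test_that("turnover index counts overlap-linked foci", {
  blob <- function(rows, cols, id = 1L, dim = c(40L, 40L)) {
    m <- matrix(0L, dim[1], dim[2]); m[rows, cols] <- id; m
  }
  ## identical frames: full persistence
  a <- blob(5:8, 5:8) + blob(20:23, 20:23, 2L)
  expect_equal(turnoverIndex(list(a, a))$series$index, 0)
  ## disjoint foci: full turnover
  b <- blob(30:33, 30:33)
  expect_equal(turnoverIndex(list(a, b))$series$index, 1)
  ## 4 vs 4 foci with 2 linked: index 0.5
  f4 <- blob(1:2, 1:2) + blob(1:2, 10:11, 2L) + blob(10:11, 1:2, 3L) +
    blob(10:11, 10:11, 4L)
  g4 <- blob(1:2, 2:3) + blob(2:3, 10:11, 2L) + blob(30:31, 30:31, 3L) +
    blob(35:36, 35:36, 4L)
  s <- turnoverIndex(list(f4, g4))$series
  expect_equal(s$nOverlap, 2L)
  expect_equal(s$index, 0.5)
  ## symmetric under frame exchange and invariant to relabeling
  expect_equal(turnoverIndex(list(g4, f4))$series$index, s$index)
  relab <- g4; relab[g4 == 2L] <- 9L
  relab[relab == 9L] <- 2L  # relabel round trip, then a genuine permutation
  perm <- g4; perm[g4 == 1L] <- 4L; perm[g4 == 4L] <- 1L
  expect_equal(turnoverIndex(list(f4, perm))$series$index, s$index)
  ## single frame: empty series
  expect_equal(nrow(turnoverIndex(list(a))$series), 0L)
})
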