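## Micropillar traction force microscopy.
##
## The measurement model: pillar tops are imaged as bright spots; a perfect
## lattice is fitted to reference pillars outside the cell; deviations of
## pillars under the cell from that grid, gated by a noise floor estimated
## from the references, are converted to forces through the
## warping-corrected pillar spring constant.

#' Sub-pixel localization of pillar tops
#'
#' Detects local intensity maxima and refines each to sub-pixel precision by
#' an intensity-weighted centre of mass (background-subtracted, recentred
#' iteratively) in a window of half the expected pitch.
#'
#' @param image numeric matrix (AU)
#' @param expectedPitch lattice pitch (um); must be >= 3 pixels
#' @param pixelSize um per pixel
#' @param background background level (AU); default: histogram mode
#' @param threshold detection threshold (AU); default: background plus 20%
#'   of the background-subtracted maximum
#' @return data.frame with columns \code{cx, cy} (um) and \code{peak} (AU);
#'   zero rows (with a warning) when no maxima are found
#' @export
localizePillars <- function(image, expectedPitch, pixelSize,
                            background = NULL, threshold = NULL) {
  stopifnot(is.matrix(image), expectedPitch / pixelSize >= 3)
  if (is.null(background)) background <- histogramMode(image)
  if (is.null(threshold))
    threshold <- background + 0.2 * (max(image) - background)
  pitchPx <- expectedPitch / pixelSize
  brushSize <- 2L * max(1L, floor(pitchPx / 2)) + 1L
  dil <- EBImage::dilate(EBImage::Image(image),
                         EBImage::makeBrush(brushSize, "box"))
  dil <- matrix(as.numeric(EBImage::imageData(dil)), nrow = nrow(image))
  cand <- which(image >= dil & image > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    warning("no pillar maxima found")
    return(data.frame(cx = numeric(), cy = numeric(), peak = numeric()))
  }
  ## non-maximum suppression: one seed per spot within pitch/2
  ord <- order(image[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  minD2 <- (pitchPx / 2)^2
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j][d2 < minD2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  wr <- max(2L, floor(pitchPx / 2) - 1L)
  nr <- nrow(image); nc <- ncol(image)
  res <- matrix(NA_real_, nrow(cand), 3)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    for (iter in 1:3) {       # recentre so the window truncates symmetrically
      r0 <- max(1L, r - wr); r1 <- min(nr, r + wr)
      c0 <- max(1L, c - wr); c1 <- min(nc, c + wr)
      ## unclamped weights: clipping negatives rectifies the noise and
      ## shrinks the centroid toward the window centre
      w <- image[r0:r1, c0:c1, drop = FALSE] - background
      s <- sum(w)
      if (s <= 0) break
      rc <- sum(rowSums(w) * (r0:r1)) / s
      cc <- sum(colSums(w) * (c0:c1)) / s
      rNew <- as.integer(round(rc)); cNew <- as.integer(round(cc))
      if (rNew == r && cNew == c) break
      r <- rNew; c <- cNew
    }
    res[i, ] <- c((cc - 0.5) * pixelSize, (rc - 0.5) * pixelSize,
                  image[cand[i, 1], cand[i, 2]])
  }
  out <- data.frame(cx = res[, 1], cy = res[, 2], peak = res[, 3])
  out[order(out$cy, out$cx), , drop = FALSE]
}

## circular mean of lattice orientation folded to 4-fold symmetry
latticeAngle <- function(vx, vy) {
  a4 <- atan2(vy, vx) * 4
  atan2(mean(sin(a4)), mean(cos(a4))) / 4
}

#' Fit an ideal lattice to reference pillar centroids
#'
#' Least-squares fit of a perfect 2D grid (origin + two basis vectors) to
#' the centroids of reference pillars outside the cell.  The orientation is
#' seeded from nearest-neighbour vectors, lattice indices are assigned by
#' rounding, and origin/basis are refined by linear least squares with one
#' re-assignment pass.
#'
#' @param centroids data.frame or matrix with columns \code{cx, cy} (um)
#' @param nominalPitch nominal centre-to-centre spacing (um)
#' @param reference logical vector selecting the reference rows
#'   (default: all rows are references)
#' @return a \code{\link{PillarLattice}}
#' @export
fitReferenceGrid <- function(centroids, nominalPitch, reference = NULL) {
  xy <- as.matrix(as.data.frame(centroids)[, c("cx", "cy")])
  if (is.null(reference)) reference <- rep(TRUE, nrow(xy))
  xy <- xy[reference, , drop = FALSE]
  if (nrow(xy) < 6L)
    stop("at least 6 reference pillars are required to fit the grid")
  ## nearest-neighbour vectors seed pitch and orientation
  d2 <- as.matrix(dist(xy))
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  v <- xy[nn, ] - xy
  nnd <- sqrt(rowSums(v^2))
  pitchHat <- median(nnd)
  if (abs(pitchHat - nominalPitch) > 0.2 * nominalPitch)
    stop("nearest-neighbour spacing deviates >20% from the nominal pitch")
  th <- latticeAngle(v[, 1], v[, 2])
  B <- pitchHat * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  origin <- xy[1, ]
  for (pass in 1:2) {
    N <- t(round(solve(B) %*% (t(xy) - origin)))
    fx <- lm(xy[, 1] ~ N[, 1] + N[, 2])
    fy <- lm(xy[, 2] ~ N[, 1] + N[, 2])
    origin <- c(coef(fx)[1], coef(fy)[1])
    B <- rbind(coef(fx)[2:3], coef(fy)[2:3])
  }
  pred <- t(B %*% t(N)) + matrix(origin, nrow(N), 2, byrow = TRUE)
  rms <- sqrt(mean(rowSums((xy - pred)^2)))
  if (rms > nominalPitch / 4)
    stop("grid fit residual exceeds pitch/4; perfect-grid assumption violated")
  new("PillarLattice", origin = unname(origin),
      basis = unname(B), rmsResidual = rms, nominalPitch = nominalPitch)
}

#' Noise floor from reference pillar deflections
#'
#' The displacement magnitude below which pillar deflections are considered
#' measurement noise: the 95th percentile of the reference (outside-cell)
#' displacement magnitudes.
#'
#' @param magnitudes reference displacement magnitudes (um)
#' @return noise floor (um)
#' @export
estimateNoiseFloor <- function(magnitudes) {
  magnitudes <- magnitudes[is.finite(magnitudes)]
  if (length(magnitudes) < 6L)
    stop("at least 6 reference displacements are required")
  unname(quantile(magnitudes, 0.95, type = 7))
}

#' Displacements of pillars relative to the fitted grid
#'
#' Assigns every centroid to its nearest ideal lattice node, records the
#' deviation vector and magnitude, flags pillars under the cell, and gates
#' deflections by the noise floor.  Centroids farther than pitch/2 from
#' every node are flagged unassigned and excluded from force computation.
#'
#' @param centroids data.frame with columns \code{cx, cy} (um)
#' @param lattice a fitted \code{\link{PillarLattice}}
#' @param cellMask logical matrix (TRUE under the cell) or NULL
#' @param pixelSize um per pixel (required when cellMask is given)
#' @param noiseFloor noise gate (um), or NULL to estimate it from the
#'   outside-cell pillars via \code{\link{estimateNoiseFloor}}
#' @return a \code{\link{DisplacementField}}
#' @export
computeDisplacements <- function(centroids, lattice, cellMask = NULL,
                                 pixelSize = NULL, noiseFloor = NULL) {
  xy <- as.matrix(as.data.frame(centroids)[, c("cx", "cy")])
  B <- lattice@basis
  N <- t(round(solve(B) %*% (t(xy) - lattice@origin)))
  node <- t(B %*% t(N)) + matrix(lattice@origin, nrow(N), 2, byrow = TRUE)
  d <- xy - node
  mag <- sqrt(rowSums(d^2))
  assigned <- mag <= lattice@nominalPitch / 2
  inside <- rep(FALSE, nrow(xy))
  if (!is.null(cellMask)) {
    stopifnot(!is.null(pixelSize))
    ## a pillar is under the cell based on its base (the lattice node),
    ## which does not move when the tip deflects; fall back to the
    ## centroid for unassigned pillars
    ax <- ifelse(assigned, node[, 1], xy[, 1])
    ay <- ifelse(assigned, node[, 2], xy[, 2])
    rr <- pmin(pmax(ceiling(ay / pixelSize), 1L), nrow(cellMask))
    cc <- pmin(pmax(ceiling(ax / pixelSize), 1L), ncol(cellMask))
    inside <- cellMask[cbind(rr, cc)]
  }
  if (is.null(noiseFloor))
    noiseFloor <- estimateNoiseFloor(mag[!inside & assigned])
  df <- data.frame(cx = xy[, 1], cy = xy[, 2], nodeX = node[, 1],
                   nodeY = node[, 2], dx = d[, 1], dy = d[, 2],
                   magnitude = mag, insideCell = inside,
                   aboveNoise = mag > noiseFloor & assigned,
                   assigned = assigned)
  new("DisplacementField", pillars = df, noiseFloor = noiseFloor,
      lattice = lattice)
}

#' Warping-corrected pillar spring constant
#'
#' Euler-Bernoulli bending stiffness of a cylindrical pillar,
#' \deqn{k_{bend} = \frac{3}{64}\,\pi E D^4 / H^3,}
#' multiplied by a correction for Timoshenko shear and elastic
#' warping/tilting of the pillar base in the substrate:
#' \deqn{corr = \frac{\tfrac{16}{3}(L/D)^3}{\tfrac{16}{3}(L/D)^3 +
#'   \tfrac{7+6\nu}{3}(L/D) + 8\,T_{tilt}(\nu)(L/D)^2},}
#' with \eqn{T_{tilt}(\nu) = a(1+\nu)/(2\pi^2(1-\nu)) + 1 - 1/(4(1-\nu))}
#' and the free bending length L identified with the pillar height H.
#' The corrected spring constant is \eqn{k = k_{bend}\,corr} and the
#' effective substrate modulus \eqn{E_{eff} = 9k/(4\pi a)} with a = D/2.
#'
#' The constant \code{tiltConstant} in \eqn{T_{tilt}} is a fitted constant
#' of the base-tilt compliance (default 1.3); it is deliberately exposed
#' because published typographies of the formula are ambiguous about it.
#'
#' @param geometry a \code{\link{pillarGeometry}} (lengths in um)
#' @param material a \code{\link{pillarMaterial}}
#' @param tiltConstant fitted constant in the base-tilt compliance
#' @return a \code{\link{StiffnessModel}}
#' @examples
#' pillarStiffness(pillarGeometry(), pillarMaterial())
#' @export
pillarStiffness <- function(geometry = pillarGeometry(),
                            material = pillarMaterial(),
                            tiltConstant = 1.3) {
  stopifnot(is(geometry, "PillarGeometry"), is(material, "PillarMaterial"))
  D <- geometry@diameter * 1e-6          # m
  H <- geometry@height * 1e-6            # m
  E <- material@youngsModulus
  v <- material@poissonRatio
  if (abs(1 - v) < 1e-12)
    stop("poisson ratio of 1 makes the tilt compliance singular")
  kBend <- (3 / 64) * pi * E * D^4 / H^3
  LD <- H / D
  tTilt <- tiltConstant * (1 + v) / (2 * pi^2 * (1 - v)) +
    1 - 1 / (4 * (1 - v))
  corr <- (16 / 3) * LD^3 /
    ((16 / 3) * LD^3 + (7 + 6 * v) / 3 * LD + 8 * tTilt * LD^2)
  k <- kBend * corr
  a <- D / 2
  eEff <- 9 * k / (4 * pi * a)
  new("StiffnessModel", geometry = geometry, material = material,
      tiltConstant = tiltConstant, kBend = kBend, tTilt = tTilt,
      corr = corr, k = k, eEff = eEff)
}

#' Convert pillar displacements to traction forces
#'
#' Linear spring model: F = k d, componentwise, applied to pillars whose
#' deflection exceeds the noise floor; sub-noise and unassigned pillars
#' carry zero force.
#'
#' @param field a \code{\link{DisplacementField}}
#' @param model a \code{\link{StiffnessModel}}
#' @return the per-pillar table of \code{field} with added columns
#'   \code{fx, fy, force} in nN
#' @export
displacementToForce <- function(field, model) {
  stopifnot(is(field, "DisplacementField"), is(model, "StiffnessModel"))
  p <- field@pillars
  scale <- model@k * 1e3                 # N/m * um -> nN
  gate <- as.numeric(p$aboveNoise)
  p$fx <- scale * p$dx * gate
  p$fy <- scale * p$dy * gate
  p$force <- scale * p$magnitude * gate
  p
}

#' Full traction-force pipeline on a single pillar image
#'
#' Localizes pillar tops, flags pillars under the cell, fits the perfect
#' grid to the reference (outside-cell) pillars, computes grid deviations
#' with a noise floor estimated from the references, converts above-noise
#' deflections to forces and summarizes traction in a band at the cell
#' edge.
#'
#' @param image pillar-top raster (AU)
#' @param cellMask logical matrix, TRUE under the cell
#' @param pixelSize um per pixel
#' @param pitch nominal lattice pitch (um)
#' @param model a \code{\link{StiffnessModel}}
#' @param bandWidth edge-band width (um)
#' @param noiseFloor noise gate (um) or NULL to estimate from references
#' @return list: \code{field} (\code{\link{DisplacementField}}),
#'   \code{forces} (per-pillar table, nN) and \code{band} (edge-band
#'   summary)
#' @export
tfmPipeline <- function(image, cellMask, pixelSize, pitch = 1.0,
                        model = pillarStiffness(), bandWidth = 10,
                        noiseFloor = NULL) {
  loc <- localizePillars(image, pitch, pixelSize)
  rr <- pmin(pmax(ceiling(loc$cy / pixelSize), 1L), nrow(cellMask))
  cc <- pmin(pmax(ceiling(loc$cx / pixelSize), 1L), ncol(cellMask))
  inside <- cellMask[cbind(rr, cc)]
  lattice <- fitReferenceGrid(loc, pitch, reference = !inside)
  field <- computeDisplacements(loc, lattice, cellMask, pixelSize,
                                noiseFloor)
  forces <- displacementToForce(field, model)
  band <- edgeBandSummary(forces, cellMask, pixelSize, bandWidth,
                          model@geometry@diameter)
  list(field = field, forces = forces, band = band)
}

#' Traction summary in a band at the cell edge
#'
#' Selects pillars under the cell whose distance to the cell boundary is at
#' most \code{bandWidth} and summarizes the above-noise traction forces
#' there.  When a pillar diameter is supplied, force per pillar
#' cross-sectional area is also reported (kPa).
#'
#' @param forces per-pillar table from \code{\link{displacementToForce}}
#' @param cellMask logical matrix, TRUE under the cell
#' @param pixelSize um per pixel
#' @param bandWidth band width measured inward from the cell edge (um)
#' @param pillarDiameter pillar diameter (um) for the stress conversion,
#'   or NULL to skip it
#' @return list: \code{n} pillars in the band with above-noise force,
#'   \code{meanForce}, \code{medianForce}, \code{totalForce} (nN),
#'   \code{meanStressKPa} (or NA), \code{nBand} pillars in the band in
#'   total, and \code{empty} flag (TRUE when n = 0, means undefined)
#' @export
edgeBandSummary <- function(forces, cellMask, pixelSize, bandWidth = 10,
                            pillarDiameter = NULL) {
  stopifnot(any(cellMask))
  dist <- distanceToOutside(cellMask, pixelSize)
  rr <- pmin(pmax(ceiling(forces$cy / pixelSize), 1L), nrow(cellMask))
  cc <- pmin(pmax(ceiling(forces$cx / pixelSize), 1L), ncol(cellMask))
  dEdge <- dist[cbind(rr, cc)]
  inBand <- forces$insideCell & dEdge <= bandWidth
  sel <- inBand & forces$aboveNoise
  n <- sum(sel)
  if (n == 0L) {
    return(list(n = 0L, meanForce = NA_real_, medianForce = NA_real_,
                totalForce = 0, meanStressKPa = NA_real_,
                nBand = sum(inBand), empty = TRUE))
  }
  f <- forces$force[sel]
  stress <- if (is.null(pillarDiameter)) NA_real_ else
    mean(f) / (pi * (pillarDiameter / 2)^2)   # nN/um^2 = kPa
  list(n = n, meanForce = mean(f), medianForce = median(f),
       totalForce = sum(f), meanStressKPa = stress,
       nBand = sum(inBand), empty = FALSE)
}
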