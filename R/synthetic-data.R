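## Seeded synthetic-data generators.  Every generator takes an explicit seed,
## restores the caller's RNG state on exit, and returns ground truth next to
## the rendered data so downstream modules can be tested without any
## external images or tables.

withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Describe a synthetic micropillar scene
#'
#' Defines a regular pillar lattice (defaults: 1 um pitch, 0.5 um diameter
#' pillars imaged at 0.1 um/px), a cell footprint, and the displacement
#' imposed on pillars under the cell.  Pillars outside the cell are
#' references and always carry zero imposed displacement.
#'
#' @param pitch lattice centre-to-centre spacing (um)
#' @param diameter pillar diameter (um); must be < pitch
#' @param imageShape integer length-2, raster size in pixels (rows, cols)
#' @param pixelSize um per pixel
#' @param psfSigma Gaussian spot sd of a rendered pillar top (um)
#' @param amplitude peak spot intensity above background (AU)
#' @param background constant background level (AU)
#' @param noiseSd additive Gaussian intensity noise sd (AU); the rendered
#'   image is clipped at zero.  The default reproduces a reference-pillar
#'   displacement noise floor on the order of 20 nm at the default optics.
#' @param rotation lattice rotation (degrees)
#' @param cellMask logical matrix matching \code{imageShape} (TRUE = under
#'   the cell) or NULL for a centred disk of radius 1/4 of the field width
#' @param displacement imposed displacement for pillars under the cell:
#'   NULL (none), a length-2 vector (um) applied to every such pillar, or a
#'   function(x, y) returning an n x 2 matrix of displacements (um)
#' @param seed integer seed (mandatory)
#' @return a list of class \code{"pillarScene"}
#' @export
pillarScene <- function(pitch = 1.0, diameter = 0.5,
                        imageShape = c(256L, 256L), pixelSize = 0.1,
                        psfSigma = 0.15, amplitude = 1000,
                        background = 100, noiseSd = 45, rotation = 0,
                        cellMask = NULL, displacement = NULL, seed) {
  stopifnot(pitch > diameter, diameter > 0, pixelSize > 0, psfSigma > 0,
            noiseSd >= 0, length(imageShape) == 2L)
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(cellMask)) {
    ext <- imageShape * pixelSize
    cellMask <- diskMask(ext[2] / 2, ext[1] / 2, min(ext) / 4,
                         imageShape, pixelSize)
  }
  stopifnot(all(dim(cellMask) == imageShape))
  structure(list(pitch = pitch, diameter = diameter,
                 imageShape = as.integer(imageShape), pixelSize = pixelSize,
                 psfSigma = psfSigma, amplitude = amplitude,
                 background = background, noiseSd = noiseSd,
                 rotation = rotation, cellMask = cellMask,
                 displacement = displacement, seed = seed),
            class = "pillarScene")
}

#' Render a synthetic micropillar image with ground truth
#'
#' Places one Gaussian spot per lattice node at the ideal node position plus
#' the imposed displacement, adds clipped Gaussian intensity noise, and
#' returns the raster together with a ground-truth table listing every
#' pillar's ideal node, true displacement and inside/outside-cell flag.
#'
#' @param scene a \code{\link{pillarScene}}
#' @return list with elements \code{image} (numeric matrix, AU) and
#'   \code{truth} (data.frame: id, nodeX, nodeY, trueDx, trueDy, insideCell)
#' @examples
#' sc <- pillarScene(imageShape = c(128, 128), noiseSd = 0, seed = 1)
#' out <- makePillarImage(sc)
#' head(out$truth)
#' @export
makePillarImage <- function(scene) {
  stopifnot(inherits(scene, "pillarScene"))
  ext <- scene$imageShape * scene$pixelSize
  th <- scene$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ## lattice indices generously covering the field
  nmax <- ceiling(max(ext) / scene$pitch) + 2L
  idx <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  origin <- c(scene$pitch / 2, scene$pitch / 2)
  xy <- t(R %*% (scene$pitch * t(as.matrix(idx)))) +
    matrix(origin, nrow(idx), 2, byrow = TRUE)
  margin <- 3 * scene$psfSigma
  keep <- xy[, 1] > margin & xy[, 1] < ext[2] - margin &
          xy[, 2] > margin & xy[, 2] < ext[1] - margin
  xy <- xy[keep, , drop = FALSE]
  ## inside-cell flag from the mask at the node position
  rr <- pmin(pmax(ceiling(xy[, 2] / scene$pixelSize), 1L),
             scene$imageShape[1])
  cc <- pmin(pmax(ceiling(xy[, 1] / scene$pixelSize), 1L),
             scene$imageShape[2])
  inside <- scene$cellMask[cbind(rr, cc)]
  d <- matrix(0, nrow(xy), 2)
  if (!is.null(scene$displacement) && any(inside)) {
    di <- if (is.function(scene$displacement)) {
      scene$displacement(xy[inside, 1], xy[inside, 2])
    } else {
      matrix(scene$displacement, sum(inside), 2, byrow = TRUE)
    }
    di <- matrix(as.numeric(di), ncol = 2)
    if (any(sqrt(rowSums(di^2)) >= scene$pitch / 2))
      stop("imposed displacement must be < pitch/2 (nearest-node ambiguity)")
    d[inside, ] <- di
  }
  truth <- data.frame(id = seq_len(nrow(xy)), nodeX = xy[, 1],
                      nodeY = xy[, 2], trueDx = d[, 1], trueDy = d[, 2],
                      insideCell = inside)
  img <- withSeed(scene$seed, {
    im <- matrix(scene$background, scene$imageShape[1], scene$imageShape[2])
    for (k in seq_len(nrow(xy))) {
      im <- addGaussianSpot(im, xy[k, 1] + d[k, 1], xy[k, 2] + d[k, 2],
                            scene$amplitude, scene$psfSigma,
                            scene$pixelSize)
    }
    if (scene$noiseSd > 0)
      im <- im + rnorm(length(im), 0, scene$noiseSd)
    pmax(im, 0)
  })
  list(image = img, truth = truth)
}

#' Describe a synthetic focal-adhesion scene
#'
#' A cell polygon filled in the membrane channel, vinculin foci rendered as
#' uniform disks of requested area and peak intensity, and a nucleus disk.
#'
#' @param cellPolygon matrix of polygon vertices (um), columns x, y
#' @param fociSpecs data.frame with columns \code{cx, cy} (um),
#'   \code{areaUm2}, \code{peak} (AU); may have zero rows
#' @param imageShape raster size in pixels (rows, cols)
#' @param pixelSize um per pixel
#' @param background background level in all channels (AU)
#' @param membraneLevel membrane-channel intensity inside the cell (AU)
#' @param noiseSd additive Gaussian noise sd (AU)
#' @param seed integer seed (mandatory)
#' @return a list of class \code{"faScene"}
#' @export
faScene <- function(cellPolygon, fociSpecs = NULL,
                    imageShape = c(256L, 256L), pixelSize = 0.1,
                    background = 500, membraneLevel = 5000,
                    noiseSd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(fociSpecs))
    fociSpecs <- data.frame(cx = numeric(), cy = numeric(),
                            areaUm2 = numeric(), peak = numeric())
  stopifnot(all(c("cx", "cy", "areaUm2", "peak") %in% names(fociSpecs)),
            all(fociSpecs$areaUm2 > 0), all(fociSpecs$peak >= 0))
  if (nrow(fociSpecs) > 0 &&
      !all(pointsInPolygon(fociSpecs$cx, fociSpecs$cy, cellPolygon)))
    stop("all foci centroids must lie inside the cell polygon")
  structure(list(cellPolygon = cellPolygon, fociSpecs = fociSpecs,
                 imageShape = as.integer(imageShape), pixelSize = pixelSize,
                 background = background, membraneLevel = membraneLevel,
                 noiseSd = noiseSd, seed = seed),
            class = "faScene")
}

#' Render a synthetic 3-channel focal-adhesion image
#'
#' Channel 1 is a nucleus disk, channel 2 the vinculin channel with foci as
#' uniform disks, channel 3 the membrane stain filling the cell polygon.
#'
#' @param scene a \code{\link{faScene}}
#' @return list with \code{image} (rows x cols x 3 array, AU) and
#'   \code{truth} (the foci table with disk radius and a \code{subMinimum}
#'   flag marking foci below the conventional 0.5 um^2 size filter)
#' @export
makeFaImage <- function(scene) {
  stopifnot(inherits(scene, "faScene"))
  dim <- scene$imageShape
  cellM <- polygonMask(scene$cellPolygon, dim, scene$pixelSize)
  withSeed(scene$seed, {
    base <- matrix(scene$background, dim[1], dim[2])
    membrane <- base
    membrane[cellM] <- scene$membraneLevel
    vinc <- base
    sp <- scene$fociSpecs
    radius <- sqrt(sp$areaUm2 / pi)
    for (k in seq_len(nrow(sp))) {
      dm <- diskMask(sp$cx[k], sp$cy[k], radius[k], dim, scene$pixelSize)
      vinc[dm] <- pmax(vinc[dm], sp$peak[k])
    }
    ctr <- colMeans(scene$cellPolygon)
    nucleus <- base
    nucleus[diskMask(ctr[1], ctr[2], 3, dim, scene$pixelSize)] <-
      scene$background + 4000
    img <- array(c(nucleus, vinc, membrane), dim = c(dim, 3L))
    if (scene$noiseSd > 0)
      img <- pmax(img + rnorm(length(img), 0, scene$noiseSd), 0)
    truth <- cbind(sp, radiusUm = radius, subMinimum = sp$areaUm2 < 0.5)
    list(image = img, truth = truth)
  })
}

#' Describe a biased persistent random walk cohort
#'
#' Step model: x[t+1] = x[t] + persistence * (x[t] - x[t-1]) + drift +
#' Gaussian noise.  The chemoattractant gradient axis is +y, so a positive
#' y-drift models chemotaxis toward the gradient.
#'
#' @param nTracks number of cells
#' @param nSteps steps per track (tracks have nSteps + 1 samples)
#' @param dt frame interval (s)
#' @param stepSd per-axis Gaussian step noise sd (um)
#' @param drift length-2 deterministic step component (um/step)
#' @param persistence directional persistence in [0, 1)
#' @param seed integer seed (mandatory)
#' @return a list of class \code{"walkModel"}
#' @export
walkModel <- function(nTracks, nSteps, dt = 600, stepSd = 1,
                      drift = c(0, 0), persistence = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nTracks >= 1, nSteps >= 1, dt > 0, stepSd >= 0,
            length(drift) == 2L, persistence >= 0, persistence < 1)
  structure(list(nTracks = as.integer(nTracks), nSteps = as.integer(nSteps),
                 dt = dt, stepSd = stepSd, drift = drift,
                 persistence = persistence, seed = seed),
            class = "walkModel")
}

#' Simulate cell migration tracks
#'
#' @param model a \code{\link{walkModel}}
#' @return data.frame with columns \code{track_id, frame, t, x, y}
#' @examples
#' trk <- simulateTracks(walkModel(5, 10, drift = c(0, 0.5), seed = 1))
#' head(trk)
#' @export
simulateTracks <- function(model) {
  stopifnot(inherits(model, "walkModel"))
  withSeed(model$seed, {
    n <- model$nSteps
    out <- vector("list", model$nTracks)
    for (i in seq_len(model$nTracks)) {
      x <- matrix(0, n + 1L, 2L)
      prev <- c(0, 0)
      for (t in seq_len(n)) {
        step <- model$persistence * prev + model$drift +
          rnorm(2, 0, model$stepSd)
        x[t + 1L, ] <- x[t, ] + step
        prev <- step
      }
      out[[i]] <- data.frame(track_id = i, frame = 0:n,
                             t = (0:n) * model$dt, x = x[, 1], y = x[, 2])
    }
    do.call(rbind, out)
  })
}

#' Describe a synthetic protein-abundance experiment
#'
#' Log-normal abundances for two groups with a chosen set of proteins
#' shifted by a true fold change in group 2.
#'
#' @param nProteins number of proteins
#' @param nPerGroup replicates per group (>= 2)
#' @param plantedDe data.frame with columns \code{protein} (integer row
#'   index or id string) and \code{foldChange} (> 0, group2 / group1); NULL
#'   for a null experiment
#' @param dispersion per-observation sd on the log2 scale
#' @param seed integer seed (mandatory)
#' @return a list of class \code{"omicsDesign"}
#' @export
omicsDesign <- function(nProteins, nPerGroup, plantedDe = NULL,
                        dispersion = 0.25, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nProteins >= 1, nPerGroup >= 2, dispersion >= 0)
  if (!is.null(plantedDe)) {
    stopifnot(all(c("protein", "foldChange") %in% names(plantedDe)),
              all(plantedDe$foldChange > 0))
  }
  structure(list(nProteins = as.integer(nProteins),
                 nPerGroup = as.integer(nPerGroup), plantedDe = plantedDe,
                 dispersion = dispersion, seed = seed),
            class = "omicsDesign")
}

#' Simulate a protein abundance table with planted differential proteins
#'
#' @param design an \code{\link{omicsDesign}}
#' @return list with \code{abundance} (linear-scale matrix, proteins x
#'   samples), \code{group} (factor of length 2 * nPerGroup) and
#'   \code{truth} (data.frame: protein, trueFoldChange, isDe)
#' @export
simulateOmics <- function(design) {
  stopifnot(inherits(design, "omicsDesign"))
  withSeed(design$seed, {
    p <- design$nProteins; n <- design$nPerGroup
    ids <- sprintf("P%04d", seq_len(p))
    fc <- rep(1, p)
    if (!is.null(design$plantedDe)) {
      idx <- design$plantedDe$protein
      if (is.character(idx)) idx <- match(idx, ids)
      fc[idx] <- design$plantedDe$foldChange
    }
    base <- runif(p, 18, 26)               # log2 baseline abundance
    log2ab <- matrix(rnorm(p * 2 * n, sd = design$dispersion), p, 2 * n) +
      base
    log2ab[, (n + 1):(2 * n)] <- log2ab[, (n + 1):(2 * n)] +
      matrix(log2(fc), p, n)
    ab <- 2^log2ab
    rownames(ab) <- ids
    colnames(ab) <- c(paste0("g1_", seq_len(n)), paste0("g2_", seq_len(n)))
    list(abundance = ab,
         group = factor(rep(c("group1", "group2"), each = n)),
         truth = data.frame(protein = ids, trueFoldChange = fc,
                            isDe = fc != 1))
  })
}
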