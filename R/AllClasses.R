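#' @import methods
#' @importFrom stats quantile rnorm runif sd median p.adjust t.test cor coef
#'   lm var cov dist
#' @importFrom utils read.csv write.csv head
NULL

#' Elastomer micropillar geometry
#'
#' Geometry of a cylindrical PDMS micropillar array used for traction force
#' microscopy: pillar diameter, pillar height and the centre-to-centre pitch
#' of the hexagonal/square lattice.  All lengths are in micrometres.
#'
#' @slot diameter pillar diameter D (um)
#' @slot height pillar height H (um); also the free bending length L
#' @slot pitch lattice centre-to-centre spacing (um)
#' @export
setClass("PillarGeometry",
  representation(diameter = "numeric", height = "numeric", pitch = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@diameter) != 1L || !is.finite(object@diameter) ||
        object@diameter <= 0)
      msg <- c(msg, "diameter must be a single positive number")
    if (length(object@height) != 1L || !is.finite(object@height) ||
        object@height <= 0)
      msg <- c(msg, "height must be a single positive number")
    if (length(object@pitch) != 1L || !is.finite(object@pitch) ||
        object@pitch <= object@diameter)
      msg <- c(msg, "pitch must exceed the pillar diameter")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PillarGeometry
#'
#' Defaults correspond to the fabricated array used throughout the package:
#' 0.5 um diameter, 1.3 um height, 1 um centre-to-centre.
#'
#' @param diameter pillar diameter (um)
#' @param height pillar height (um)
#' @param pitch lattice pitch (um)
#' @return a \code{PillarGeometry} object
#' @examples
#' pillarGeometry()
#' @export
pillarGeometry <- function(diameter = 0.5, height = 1.3, pitch = 1.0) {
  new("PillarGeometry", diameter = diameter, height = height, pitch = pitch)
}

#' Linear-elastic pillar material
#'
#' @slot youngsModulus Young's modulus E (Pa)
#' @slot poissonRatio Poisson ratio v (unitless); v = 0.5 is the
#'   incompressible limit typical of cured PDMS
#' @export
setClass("PillarMaterial",
  representation(youngsModulus = "numeric", poissonRatio = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@youngsModulus) != 1L || object@youngsModulus <= 0)
      msg <- c(msg, "youngsModulus must be positive")
    v <- object@poissonRatio
    if (length(v) != 1L || v < 0 || v > 0.5 + 1e-9)
      msg <- c(msg, "poissonRatio must lie in [0, 0.5]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PillarMaterial
#'
#' Defaults are typical of Sylgard 184 PDMS cured at a 10:1 base:curing-agent
#' ratio: E = 2 MPa, v = 0.5 (incompressible).
#'
#' @param youngsModulus Young's modulus (Pa)
#' @param poissonRatio Poisson ratio
#' @return a \code{PillarMaterial} object
#' @export
pillarMaterial <- function(youngsModulus = 2e6, poissonRatio = 0.5) {
  new("PillarMaterial", youngsModulus = youngsModulus,
      poissonRatio = poissonRatio)
}

#' Warping-corrected pillar spring model
#'
#' Holds the Euler-Bernoulli bending stiffness of a cylindrical pillar
#' together with the multiplicative correction for shear and elastic
#' warping/tilting of the pillar base in the substrate, and the resulting
#' effective spring constant and effective substrate modulus.
#'
#' @slot geometry the \code{PillarGeometry}
#' @slot material the \code{PillarMaterial}
#' @slot tiltConstant numeric fitted constant in the base-tilt compliance
#' @slot kBend bending-only spring constant (N/m)
#' @slot tTilt dimensionless base-tilt compliance factor
#' @slot corr dimensionless stiffness correction in (0, 1]
#' @slot k corrected spring constant k = kBend * corr (N/m)
#' @slot eEff effective substrate Young's modulus 9 k / (4 pi a) (Pa)
#' @seealso \code{\link{pillarStiffness}}
#' @export
setClass("StiffnessModel",
  representation(geometry = "PillarGeometry", material = "PillarMaterial",
                 tiltConstant = "numeric", kBend = "numeric",
                 tTilt = "numeric", corr = "numeric", k = "numeric",
                 eEff = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@kBend <= 0) msg <- c(msg, "kBend must be positive")
    if (object@corr <= 0 || object@corr > 1 + 1e-12)
      msg <- c(msg, "corr must lie in (0, 1]")
    if (abs(object@k - object@kBend * object@corr) >
        1e-9 * object@kBend)
      msg <- c(msg, "k must equal kBend * corr")
    if (object@eEff <= 0) msg <- c(msg, "eEff must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Ideal pillar lattice fitted to reference centroids
#'
#' An ideal 2D Bravais lattice (origin plus two basis vectors) describing
#' where undeflected pillar tops sit.  Fitted by least squares to reference
#' pillars outside the cell; deviations of pillars under the cell from this
#' perfect grid are the traction displacements.
#'
#' @slot origin numeric length-2, lattice origin (um)
#' @slot basis 2 x 2 matrix whose columns are the two basis vectors (um)
#' @slot rmsResidual root-mean-square distance of reference centroids to
#'   their nearest lattice node (um)
#' @slot nominalPitch the nominal centre-to-centre pitch (um)
#' @export
setClass("PillarLattice",
  representation(origin = "numeric", basis = "matrix",
                 rmsResidual = "numeric", nominalPitch = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@origin) != 2L)
      msg <- c(msg, "origin must have length 2")
    if (!all(dim(object@basis) == c(2L, 2L)))
      msg <- c(msg, "basis must be a 2 x 2 matrix")
    else {
      if (abs(det(object@basis)) < 1e-12)
        msg <- c(msg, "basis vectors must be linearly independent")
      len <- sqrt(colSums(object@basis^2))
      if (any(abs(len - object@nominalPitch) > 0.2 * object@nominalPitch))
        msg <- c(msg, "basis vector lengths deviate >20% from nominal pitch")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Per-pillar displacement field
#'
#' One row per detected pillar: measured centroid, assigned ideal lattice
#' node, displacement vector and magnitude (um), whether the pillar lies
#' under the cell, and whether its deflection exceeds the noise floor
#' measured from reference pillars outside the cell.
#'
#' @slot pillars data.frame with columns \code{cx, cy, nodeX, nodeY, dx, dy,
#'   magnitude, insideCell, aboveNoise, assigned}
#' @slot noiseFloor displacement magnitude below which deflections are
#'   treated as measurement noise (um)
#' @slot lattice the fitted \code{PillarLattice}
#' @export
setClass("DisplacementField",
  representation(pillars = "data.frame", noiseFloor = "numeric",
                 lattice = "PillarLattice"),
  validity = function(object) {
    need <- c("cx", "cy", "nodeX", "nodeY", "dx", "dy", "magnitude",
              "insideCell", "aboveNoise", "assigned")
    if (!all(need %in% names(object@pillars)))
      return(paste("pillars must contain columns:",
                   paste(need, collapse = ", ")))
    if (object@noiseFloor < 0) return("noiseFloor must be >= 0")
    p <- object@pillars[object@pillars$assigned, , drop = FALSE]
    if (nrow(p) > 0) {
      m <- sqrt((p$cx - p$nodeX)^2 + (p$cy - p$nodeY)^2)
      if (any(abs(m - p$magnitude) > 1e-8))
        return("magnitude must equal |centroid - node|")
      if (!all(p$aboveNoise == (p$magnitude > object@noiseFloor)))
        return("aboveNoise flag inconsistent with noiseFloor")
    }
    TRUE
  })

#' Segmented cell footprint
#'
#' Binary cell mask obtained by thresholding a membrane-stain channel at a
#' fixed offset above the estimated image background.
#'
#' @slot mask logical matrix, TRUE inside the cell
#' @slot pixelSize um per pixel
#' @slot backgroundLevel estimated image background (AU)
#' @slot threshold the applied threshold, backgroundLevel + offset (AU)
#' @export
setClass("CellMask",
  representation(mask = "matrix", pixelSize = "numeric",
                 backgroundLevel = "numeric", threshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
    if (object@threshold < object@backgroundLevel)
      msg <- c(msg, "threshold must be >= backgroundLevel")
    if (is.null(msg)) TRUE else msg
  })

#' Labelled focal-adhesion objects
#'
#' Connected components of the thresholded adhesion-marker channel,
#' restricted to the cell mask and filtered by a minimum area.  Carries a
#' label raster plus a per-focus table of area, centroid, mean channel
#' intensities and minimum distance to the cell edge.
#'
#' @slot labels integer matrix, 0 = background, i = pixels of focus i
#' @slot foci data.frame with one row per focus: \code{id, areaUm2, cx, cy,
#'   meanVinculin, meanFarRed, minEdgeDistance}
#' @slot pixelSize um per pixel
#' @export
setClass("FociSet",
  representation(labels = "matrix", foci = "data.frame",
                 pixelSize = "numeric"),
  validity = function(object) {
    need <- c("id", "areaUm2", "cx", "cy", "meanVinculin", "meanFarRed")
    if (!all(need %in% names(object@foci)))
      return(paste("foci must contain columns:", paste(need, collapse = ", ")))
    if (nrow(object@foci) > 0 && any(object@foci$areaUm2 <= 0))
      return("focus areas must be positive")
    TRUE
  })

#' Thresholded two-channel colocalization result
#'
#' @slot pearson Pearson correlation over qualifying pixels, in [-1, 1]
#' @slot tM1,tM2 thresholded Manders split coefficients, in [0, 1]
#'   (NaN when the respective above-threshold set is empty)
#' @slot percentVolume1,percentVolume2 percentage of each channel's
#'   above-threshold pixels that are above threshold in the other channel
#' @slot t1,t2 the channel thresholds used (AU)
#' @export
setClass("ColocResult",
  representation(pearson = "numeric", tM1 = "numeric", tM2 = "numeric",
                 percentVolume1 = "numeric", percentVolume2 = "numeric",
                 t1 = "numeric", t2 = "numeric"),
  validity = function(object) {
    msg <- NULL
    chk01 <- function(x) is.nan(x) || (x >= -1e-12 && x <= 1 + 1e-12)
    if (!is.nan(object@pearson) &&
        (object@pearson < -1 - 1e-9 || object@pearson > 1 + 1e-9))
      msg <- c(msg, "pearson must lie in [-1, 1]")
    if (!chk01(object@tM1) || !chk01(object@tM2))
      msg <- c(msg, "Manders coefficients must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

## ---- show methods -------------------------------------------------------

setMethod("show", "PillarGeometry", function(object) {
  cat("PillarGeometry: D =", object@diameter, "um, H =", object@height,
      "um, pitch =", object@pitch, "um\n")
})

setMethod("show", "StiffnessModel", function(object) {
  cat("StiffnessModel (warping-corrected pillar spring)\n")
  cat(sprintf("  k_bend = %.4g N/m\n", object@kBend))
  cat(sprintf("  corr   = %.4f  (T_tilt = %.4f)\n", object@corr,
              object@tTilt))
  cat(sprintf("  k      = %.4g N/m\n", object@k))
  cat(sprintf("  E_eff  = %.4g Pa\n", object@eEff))
})

setMethod("show", "PillarLattice", function(object) {
  cat("PillarLattice\n")
  cat(sprintf("  origin: (%.3f, %.3f) um\n", object@origin[1],
              object@origin[2]))
  cat(sprintf("  basis vectors: (%.3f, %.3f), (%.3f, %.3f) um\n",
              object@basis[1, 1], object@basis[2, 1],
              object@basis[1, 2], object@basis[2, 2]))
  cat(sprintf("  rms residual: %.4f um\n", object@rmsResidual))
})

setMethod("show", "DisplacementField", function(object) {
  p <- object@pillars
  cat("DisplacementField:", nrow(p), "pillars,",
      sum(p$insideCell), "under cell,", sum(p$aboveNoise),
      "above noise floor of", signif(object@noiseFloor, 3), "um\n")
})

setMethod("show", "CellMask", function(object) {
  cat(sprintf(
    "CellMask: %d x %d px, area %.1f um^2, threshold %g AU (bg %g AU)\n",
    nrow(object@mask), ncol(object@mask), cellArea(object),
    object@threshold, object@backgroundLevel))
})

setMethod("show", "FociSet", function(object) {
  cat("FociSet:", nrow(object@foci), "foci")
  if (nrow(object@foci) > 0)
    cat(sprintf(", mean area %.2f um^2", mean(object@foci$areaUm2)))
  cat("\n")
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf(
    "ColocResult: r = %.3f, tM1 = %.3f, tM2 = %.3f, %%vol = %.1f / %.1f (t1 = %g, t2 = %g)\n",
    object@pearson, object@tM1, object@tM2, object@percentVolume1,
    object@percentVolume2, object@t1, object@t2))
})
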