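## Focal adhesion detection in TIRF images and the overlap-based turnover
## index for time-lapse label stacks.

#' Segment the cell from a membrane-stain channel
#'
#' Thresholds the membrane channel at a fixed offset above the estimated
#' image background (histogram mode), keeps the largest connected
#' component and fills holes.
#'
#' @param membrane numeric matrix, membrane-stain channel (AU)
#' @param pixelSize um per pixel
#' @param offset threshold offset above background (AU)
#' @param background background level (AU); default: histogram mode
#' @return a \code{\link{CellMask}}
#' @export
segmentCell <- function(membrane, pixelSize, offset = 100,
                        background = NULL) {
  stopifnot(is.matrix(membrane), pixelSize > 0)
  if (is.null(background)) background <- histogramMode(membrane)
  thr <- background + offset
  bin <- membrane > thr
  if (!any(bin)) stop("no cell detected: no pixel exceeds the threshold")
  mask <- largestComponent(bin)
  new("CellMask", mask = mask, pixelSize = pixelSize,
      backgroundLevel = background, threshold = thr)
}

#' Detect focal adhesions as thresholded foci
#'
#' Connected components (8-connectivity) of pixels above the intensity
#' threshold inside the cell mask, kept when their pixel area is at least
#' \code{minArea}.  Mean adhesion-marker and far-red intensities are
#' recorded per focus.
#'
#' @param vinculin adhesion-marker channel, numeric matrix (AU)
#' @param mask a \code{\link{CellMask}} co-registered with the raster
#' @param farRed optional far-red channel for per-focus intensity
#' @param intensityThreshold foci threshold on raw intensities (AU)
#' @param minArea minimum focus area (um^2)
#' @param connectivity 4 or 8 (default 8)
#' @return a \code{\link{FociSet}} (possibly with zero foci)
#' @export
detectFoci <- function(vinculin, mask, farRed = NULL,
                       intensityThreshold = 10000, minArea = 0.5,
                       connectivity = 8L) {
  stopifnot(is(mask, "CellMask"),
            all(dim(vinculin) == dim(mask@mask)))
  px <- mask@pixelSize
  bin <- (vinculin > intensityThreshold) & mask@mask
  lab <- labelComponents(bin, connectivity)
  nlab <- max(lab)
  emptySet <- function() {
    new("FociSet", labels = matrix(0L, nrow(bin), ncol(bin)),
        foci = data.frame(id = integer(), areaUm2 = numeric(),
                          cx = numeric(), cy = numeric(),
                          meanVinculin = numeric(), meanFarRed = numeric(),
                          minEdgeDistance = numeric()),
        pixelSize = px)
  }
  if (nlab == 0L) return(emptySet())
  pxArea <- px^2
  counts <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(counts * pxArea >= minArea)
  if (length(keep) == 0L) return(emptySet())
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  lab2[lab > 0L] <- remap[lab[lab > 0L]]
  idx <- which(lab2 > 0L, arr.ind = TRUE)
  f <- factor(lab2[lab2 > 0L], levels = seq_along(keep))
  xs <- (idx[, 2] - 0.5) * px
  ys <- (idx[, 1] - 0.5) * px
  vv <- vinculin[idx]
  fr <- if (is.null(farRed)) rep(NA_real_, nrow(idx)) else farRed[idx]
  foci <- data.frame(
    id = seq_along(keep),
    areaUm2 = counts[keep] * pxArea,
    cx = as.numeric(tapply(xs, f, mean)),
    cy = as.numeric(tapply(ys, f, mean)),
    meanVinculin = as.numeric(tapply(vv, f, mean)),
    meanFarRed = as.numeric(tapply(fr, f, mean)),
    minEdgeDistance = NA_real_)
  new("FociSet", labels = lab2, foci = foci, pixelSize = px)
}

#' Minimum distance of each focus to the cell edge
#'
#' Computes the Euclidean distance transform of the cell mask (distance of
#' every in-cell pixel to the nearest outside pixel) and records, per
#' focus, the minimum transform value over the focus's pixels.
#'
#' @param fociSet a \code{\link{FociSet}}
#' @param mask the \code{\link{CellMask}} the foci were detected in
#' @return the \code{FociSet} with \code{minEdgeDistance} (um) filled in
#' @export
edgeDistances <- function(fociSet, mask) {
  stopifnot(is(fociSet, "FociSet"), is(mask, "CellMask"),
            all(dim(fociSet@labels) == dim(mask@mask)))
  f <- fociSet@foci
  if (nrow(f) == 0L) return(fociSet)
  dm <- distanceToOutside(mask@mask, mask@pixelSize)
  lab <- fociSet@labels
  idx <- which(lab > 0L)
  mins <- tapply(dm[idx], factor(lab[idx], levels = f$id), min)
  f$minEdgeDistance <- as.numeric(mins)
  fociSet@foci <- f
  fociSet
}

#' Per-image adhesion summary
#'
#' One record per image: cell area, focus count, mean focus area, mean
#' minimum edge distance and mean per-focus channel intensities.  Means are
#' NA (and \code{empty} is TRUE) when no foci were detected.
#'
#' @param fociSet a \code{\link{FociSet}} (edge distances filled in)
#' @param mask the \code{\link{CellMask}}
#' @return named list
#' @export
summarizeAdhesions <- function(fociSet, mask) {
  f <- fociSet@foci
  n <- nrow(f)
  list(cellAreaUm2 = cellArea(mask),
       nFoci = n,
       meanFocusAreaUm2 = if (n) mean(f$areaUm2) else NA_real_,
       meanEdgeDistanceUm = if (n) mean(f$minEdgeDistance) else NA_real_,
       meanVinculin = if (n) mean(f$meanVinculin) else NA_real_,
       meanFarRed = if (n) mean(f$meanFarRed) else NA_real_,
       empty = n == 0L)
}

## size of a maximum one-to-one matching between foci of two label rasters,
## linking foci whose pixel sets intersect in >= 1 pixel
overlapMatching <- function(labA, labB) {
  sel <- labA > 0L & labB > 0L
  if (!any(sel)) return(0L)
  pairs <- unique(cbind(labA[sel], labB[sel]))
  va <- paste0("A", pairs[, 1]); vb <- paste0("B", pairs[, 2])
  g <- igraph::graph_from_edgelist(cbind(va, vb), directed = FALSE)
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "B")
  igraph::max_bipartite_match(g)$matching_size
}

#' Overlap-based focal adhesion turnover index
#'
#' Foci in consecutive frames are linked when their pixel sets overlap by
#' at least one pixel (one-to-one, maximum matching).  Per frame pair,
#' \deqn{index(t) = 1 - \frac{2\,n_{overlap}}{n_{foci}(t) + n_{foci}(t+1)},}
#' so 0 means every focus persists and 1 means complete turnover.
#'
#' @param labelStack list of integer label matrices (one per frame), e.g.
#'   \code{fociLabels} of per-frame \code{\link{detectFoci}} results
#' @return list with \code{series} (data.frame: frame, nA, nB, nOverlap,
#'   index) and \code{meanIndex}; a single frame yields an empty series
#' @export
turnoverIndex <- function(labelStack) {
  stopifnot(is.list(labelStack))
  nf <- length(labelStack)
  if (nf < 2L) {
    return(list(series = data.frame(frame = integer(), nA = integer(),
                                    nB = integer(), nOverlap = integer(),
                                    index = numeric()),
                meanIndex = NA_real_))
  }
  rows <- lapply(seq_len(nf - 1L), function(t) {
    labA <- labelStack[[t]]; labB <- labelStack[[t + 1L]]
    stopifnot(all(dim(labA) == dim(labB)))
    nA <- length(unique(labA[labA > 0L]))
    nB <- length(unique(labB[labB > 0L]))
    nOv <- overlapMatching(labA, labB)
    idx <- if (nA + nB == 0L) NaN else 1 - 2 * nOv / (nA + nB)
    data.frame(frame = t, nA = nA, nB = nB, nOverlap = nOv, index = idx)
  })
  series <- do.call(rbind, rows)
  list(series = series, meanIndex = mean(series$index, na.rm = TRUE))
}
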