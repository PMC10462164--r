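## Thresholded two-channel colocalization statistics: automatic threshold
## selection by correlation regression, thresholded Manders split
## coefficients, Pearson above threshold and percent volume colocalised,
## plus a roundness prefilter for extracting round actin structures.

checkPair <- function(ch1, ch2, roi = NULL) {
  stopifnot(is.matrix(ch1), all(dim(ch1) == dim(ch2)))
  if (!is.null(roi)) {
    stopifnot(all(dim(roi) == dim(ch1)))
    list(a = as.numeric(ch1[roi]), b = as.numeric(ch2[roi]))
  } else {
    list(a = as.numeric(ch1), b = as.numeric(ch2))
  }
}

#' Automatic colocalization thresholds (correlation regression)
#'
#' Fits an orthogonal (major-axis) regression ch2 = a ch1 + b, then lowers
#' a threshold pair along the regression line, starting from the intensity
#' maximum, until the Pearson correlation of the pixels below both
#' thresholds is non-positive.  The first such pair is returned; with
#' perfectly correlated channels the scan runs to the intensity minimum.
#'
#' @param ch1,ch2 co-registered intensity matrices (AU)
#' @param roi optional logical region-of-interest mask
#' @return named numeric vector \code{c(t1, t2)}
#' @export
costesThresholds <- function(ch1, ch2, roi = NULL) {
  p <- checkPair(ch1, ch2, roi)
  a <- p$a; b <- p$b
  if (sd(a) == 0 || sd(b) == 0)
    stop("constant channel: regression undefined")
  sxx <- var(a); syy <- var(b); sxy <- cov(a, b)
  slope <- if (abs(sxy) < .Machine$double.eps) {
    stop("zero covariance: regression undefined")
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- mean(b) - slope * mean(a)
  cand <- sort(unique(a), decreasing = TRUE)
  t1 <- min(a); t2 <- slope * t1 + intercept
  for (tc in cand) {
    below <- a < tc & b < (slope * tc + intercept)
    if (sum(below) >= 3 && sd(a[below]) > 0 && sd(b[below]) > 0) {
      r <- cor(a[below], b[below])
      if (r <= 0) {
        t1 <- tc; t2 <- slope * tc + intercept
        break
      }
    }
  }
  c(t1 = t1, t2 = t2)
}

#' Thresholded Manders split coefficients
#'
#' tM1 is the fraction of channel-1 intensity above its threshold that
#' falls on pixels where channel 2 is also above its threshold; tM2 is the
#' symmetric quantity for channel 2.
#'
#' @param ch1,ch2 co-registered intensity matrices (AU)
#' @param t1,t2 channel thresholds (AU)
#' @param roi optional logical region-of-interest mask
#' @param denominator \code{"above-threshold"} (default; the denominator is
#'   the channel's own above-threshold intensity) or \code{"whole-image"}
#' @return named numeric vector \code{c(tM1, tM2)}; NaN when the
#'   respective denominator set is empty
#' @export
mandersSplit <- function(ch1, ch2, t1, t2, roi = NULL,
                         denominator = c("above-threshold", "whole-image")) {
  denominator <- match.arg(denominator)
  p <- checkPair(ch1, ch2, roi)
  a <- p$a; b <- p$b
  co <- a > t1 & b > t2
  d1 <- if (denominator == "above-threshold") sum(a[a > t1]) else sum(a)
  d2 <- if (denominator == "above-threshold") sum(b[b > t2]) else sum(b)
  c(tM1 = if (d1 > 0) sum(a[co]) / d1 else NaN,
    tM2 = if (d2 > 0) sum(b[co]) / d2 else NaN)
}

#' Pearson correlation above threshold
#'
#' Pearson correlation of the two channels over qualifying pixels.  The
#' default excludes only pixels that are zero in both channels; the
#' \code{"above-threshold"} mode restricts to the union of the two
#' above-threshold sets instead.
#'
#' @param ch1,ch2 co-registered intensity matrices (AU)
#' @param t1,t2 channel thresholds (used by the above-threshold mode)
#' @param roi optional logical region-of-interest mask
#' @param pixels \code{"zero-exclusion"} (default) or
#'   \code{"above-threshold"}
#' @return Pearson r, or NaN with fewer than 3 qualifying pixels or zero
#'   variance
#' @export
pearsonAboveThreshold <- function(ch1, ch2, t1 = 0, t2 = 0, roi = NULL,
                                  pixels = c("zero-exclusion",
                                             "above-threshold")) {
  pixels <- match.arg(pixels)
  p <- checkPair(ch1, ch2, roi)
  a <- p$a; b <- p$b
  sel <- if (pixels == "zero-exclusion") !(a == 0 & b == 0)
         else (a > t1 | b > t2)
  a <- a[sel]; b <- b[sel]
  if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) return(NaN)
  cor(a, b)
}

#' Percent volume colocalised
#'
#' Percentage of each channel's above-threshold pixels on which the other
#' channel is also above threshold.
#'
#' @param ch1,ch2 co-registered intensity matrices (AU)
#' @param t1,t2 channel thresholds (AU)
#' @param roi optional logical region-of-interest mask
#' @return named numeric vector \code{c(pct1, pct2)} in percent; NaN when a
#'   channel has no above-threshold pixels
#' @export
percentVolume <- function(ch1, ch2, t1, t2, roi = NULL) {
  p <- checkPair(ch1, ch2, roi)
  a <- p$a; b <- p$b
  co <- a > t1 & b > t2
  n1 <- sum(a > t1); n2 <- sum(b > t2)
  c(pct1 = if (n1 > 0) 100 * sum(co) / n1 else NaN,
    pct2 = if (n2 > 0) 100 * sum(co) / n2 else NaN)
}

#' Full thresholded colocalization analysis of a channel pair
#'
#' Convenience wrapper: chooses thresholds automatically (correlation
#' regression) unless given, then computes Pearson above threshold, the
#' thresholded Manders split coefficients and percent volume colocalised.
#'
#' @param ch1,ch2 co-registered intensity matrices (AU)
#' @param t1,t2 channel thresholds, or NULL for automatic selection
#' @param roi optional logical region-of-interest mask
#' @return a \code{\link{ColocResult}}
#' @export
colocalize <- function(ch1, ch2, t1 = NULL, t2 = NULL, roi = NULL) {
  if (is.null(t1) || is.null(t2)) {
    tt <- costesThresholds(ch1, ch2, roi)
    t1 <- unname(tt[1]); t2 <- unname(tt[2])
  }
  tm <- mandersSplit(ch1, ch2, t1, t2, roi)
  pv <- percentVolume(ch1, ch2, t1, t2, roi)
  r <- pearsonAboveThreshold(ch1, ch2, t1, t2, roi)
  new("ColocResult", pearson = r, tM1 = unname(tm[1]), tM2 = unname(tm[2]),
      percentVolume1 = unname(pv[1]), percentVolume2 = unname(pv[2]),
      t1 = t1, t2 = t2)
}

## crack-length perimeter per label, corrected by pi/4 so a digital disk
## has perimeter ~ pi D (the raw 4-neighbour crack length of a disk is 4 D)
crackPerimeter <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  edges <- integer(max(lab))
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  for (shift in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- pad[2:(nr + 1L) + shift[1], 2:(nc + 1L) + shift[2]]
    sel <- ctr > 0L & nb != ctr
    if (any(sel)) {
      tab <- tabulate(ctr[sel], nbins = max(lab))
      edges <- edges + tab
    }
  }
  edges * pi / 4
}

#' Keep round connected components of a binary mask
#'
#' Filters 8-connected components by circularity 4 pi A / P^2 (perimeter
#' estimated from the boundary crack length with a pi/4 correction so a
#' digital disk scores ~1) and by an area range, e.g. to extract
#' round-shaped actin structures before colocalization within them.
#'
#' @param bin logical or 0/1 matrix
#' @param circularityMin minimum circularity, in (0, 1]
#' @param minArea,maxArea component area range (um^2)
#' @param pixelSize um per pixel
#' @return logical mask keeping only qualifying components
#' @export
roundStructureFilter <- function(bin, circularityMin = 0.8, minArea = 0,
                                 maxArea = Inf, pixelSize = 1) {
  bin <- bin > 0
  lab <- labelComponents(bin, 8L)
  if (max(lab) == 0L) return(matrix(FALSE, nrow(bin), ncol(bin)))
  areaPx <- tabulate(lab[lab > 0L], nbins = max(lab))
  perim <- crackPerimeter(lab)
  circ <- 4 * pi * areaPx / perim^2
  areaUm2 <- areaPx * pixelSize^2
  keep <- which(circ >= circularityMin & areaUm2 >= minArea &
                areaUm2 <= maxArea)
  matrix(lab %in% keep, nrow(bin))
}
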