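## Raster helpers shared by the imaging modules.
##
## Convention: images are numeric matrices indexed [row, col]; the physical
## position of the centre of pixel (r, c) is x = (c - 0.5) * pixelSize,
## y = (r - 0.5) * pixelSize, i.e. x runs along columns and y along rows.

pixelCentres <- function(dim, pixelSize) {
  list(x = (seq_len(dim[2]) - 0.5) * pixelSize,
       y = (seq_len(dim[1]) - 0.5) * pixelSize)
}

## 8-connected component labelling.  EBImage::bwlabel is 4-connected; merge
## labels that touch diagonally so diagonal foci are not split.
labelComponents <- function(bin, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  lab <- matrix(as.integer(lab), nrow = nrow(bin))
  if (connectivity == 4L || max(lab) == 0L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    r0 <- seq_len(nr - 1L)
    c0 <- if (shift[2] > 0) seq_len(nc - 1L) else 2:nc
    a <- lab[r0, c0, drop = FALSE]
    b <- lab[r0 + 1L, c0 + shift[2], drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  g <- igraph::graph_from_edgelist(apply(unique(pairs), 2, as.character),
                                   directed = FALSE)
  comp <- igraph::components(g)
  remap <- seq_len(max(lab))
  remap[as.integer(igraph::V(g)$name)] <-
    max(lab) + comp$membership  # temporary ids, renumbered below
  lab2 <- lab
  lab2[lab > 0L] <- remap[lab[lab > 0L]]
  ## renumber to consecutive 1..n in first-appearance order
  u <- unique(lab2[lab2 > 0L])
  lab2[lab2 > 0L] <- match(lab2[lab2 > 0L], u)
  lab2
}

## Mode of the intensity histogram (integer-rounded); robust background
## estimate for mostly-background fluorescence fields.
histogramMode <- function(img) {
  v <- round(as.numeric(img))
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

## Even-odd-rule point-in-polygon test, vectorised over points.
## poly: matrix with columns x, y (vertices, closed implicitly).
pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Rasterise a polygon (um coordinates) onto a pixel grid.
polygonMask <- function(poly, dim, pixelSize) {
  ctr <- pixelCentres(dim, pixelSize)
  xs <- rep(ctr$x, each = dim[1])
  ys <- rep(ctr$y, times = dim[2])
  matrix(pointsInPolygon(xs, ys, poly), nrow = dim[1])
}

## Binary disk mask centred at (cx, cy) um with radius r um.
diskMask <- function(cx, cy, r, dim, pixelSize) {
  ctr <- pixelCentres(dim, pixelSize)
  outer(ctr$y, ctr$x, function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

## Add an isotropic Gaussian spot (amplitude A, sd sigma um) at (cx, cy) um.
## Rendered on a +-5 sigma window for speed; closed-form centroid = (cx, cy).
addGaussianSpot <- function(img, cx, cy, amplitude, sigma, pixelSize) {
  nr <- nrow(img); nc <- ncol(img)
  half <- 5 * sigma
  c0 <- max(1L, floor((cx - half) / pixelSize) + 1L)
  c1 <- min(nc, ceiling((cx + half) / pixelSize))
  r0 <- max(1L, floor((cy - half) / pixelSize) + 1L)
  r1 <- min(nr, ceiling((cy + half) / pixelSize))
  if (c0 > c1 || r0 > r1) return(img)
  x <- (c0:c1 - 0.5) * pixelSize
  y <- (r0:r1 - 0.5) * pixelSize
  gx <- exp(-(x - cx)^2 / (2 * sigma^2))
  gy <- exp(-(y - cy)^2 / (2 * sigma^2))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amplitude * outer(gy, gx)
  img
}

## Euclidean distance (um) from every foreground pixel of a logical mask to
## the nearest background pixel.  Pixels of an all-foreground mask are Inf.
distanceToOutside <- function(mask, pixelSize) {
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  matrix(as.numeric(dm), nrow = nrow(mask)) * pixelSize
}

## Largest connected component of a binary mask, holes filled.
largestComponent <- function(bin, connectivity = 8L) {
  lab <- labelComponents(bin, connectivity)
  if (max(lab) == 0L) return(matrix(FALSE, nrow(bin), ncol(bin)))
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  filled <- EBImage::fillHull(EBImage::Image((lab == keep) * 1))
  matrix(as.numeric(EBImage::imageData(filled)) > 0, nrow = nrow(bin))
}
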