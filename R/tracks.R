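## Cell migration track statistics for 2D time-lapse and 3D invasion
## assays.  Tracks are tidy tables with columns track_id, frame, t, x, y
## (and optionally condition); the chemoattractant gradient axis is +y.

checkTrackTable <- function(tracks) {
  need <- c("track_id", "frame", "t", "x", "y")
  if (!all(need %in% names(tracks)))
    stop("track table must contain columns: ", paste(need, collapse = ", "))
  invisible(tracks)
}

#' Accumulated distance of a track
#'
#' Total path length: the sum of Euclidean step lengths between
#' consecutive samples, from the first to the last timepoint.
#'
#' @param x,y positional samples (um), in frame order
#' @return accumulated distance (um)
#' @examples
#' accumulatedDistance(c(0, 3), c(0, 4))  # 5
#' @export
accumulatedDistance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Motility metrics for a single track
#'
#' Net displacement is last minus first position; its x component is the
#' lateral displacement and its y component the vertical (gradient-
#' parallel) displacement.  Straightness is net over accumulated path
#' length; speed is accumulated distance over elapsed time; the parallel
#' forward motion index (FMI) is the signed ratio of vertical displacement
#' to accumulated distance.  Stationary tracks (zero accumulated distance)
#' get straightness = FMI = 0 so cohort summaries stay computable.
#'
#' @param track data.frame with columns \code{frame, t, x, y} for one track
#' @param gradientAxis either \code{"+y"} (default) or \code{"-y"}; flips
#'   the sign of the FMI and vertical displacement
#' @return one-row data.frame of metrics
#' @examples
#' trackMetrics(data.frame(frame = 0:1, t = c(0, 100),
#'                         x = c(0, 3), y = c(0, 4)))
#' @export
trackMetrics <- function(track, gradientAxis = c("+y", "-y")) {
  gradientAxis <- match.arg(gradientAxis)
  sgn <- if (gradientAxis == "+y") 1 else -1
  stopifnot(nrow(track) >= 2, !is.unsorted(track$frame, strictly = TRUE))
  acc <- accumulatedDistance(track$x, track$y)
  lateral <- track$x[nrow(track)] - track$x[1]
  vertical <- sgn * (track$y[nrow(track)] - track$y[1])
  net <- sqrt(lateral^2 + vertical^2)
  elapsed <- track$t[nrow(track)] - track$t[1]
  data.frame(
    nTimepoints = nrow(track),
    accumulatedDistance = acc,
    netDisplacement = net,
    lateralDisplacement = lateral,
    verticalDisplacement = vertical,
    straightness = if (acc > 0) net / acc else 0,
    speed = if (elapsed > 0) acc / elapsed else NA_real_,
    parallelFmi = if (acc > 0) vertical / acc else 0)
}

#' Metrics for every track in a table
#'
#' @param tracks tidy track table (\code{track_id, frame, t, x, y}, and
#'   optionally \code{condition})
#' @param gradientAxis passed to \code{\link{trackMetrics}}
#' @return data.frame, one row per track, with \code{track_id} (and
#'   \code{condition} when present) prepended
#' @export
allTrackMetrics <- function(tracks, gradientAxis = "+y") {
  checkTrackTable(tracks)
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) return(NULL)
    m <- trackMetrics(tr, gradientAxis)
    m <- cbind(data.frame(track_id = id), m)
    if ("condition" %in% names(tr)) m$condition <- tr$condition[1]
    m
  })
  do.call(rbind, rows)
}

#' Track filter for the 3D invasion assay
#'
#' Discards tracks shorter than 3 timepoints.
#'
#' @param tracks tidy track table
#' @return the filtered table
#' @export
filterTracks3D <- function(tracks) {
  checkTrackTable(tracks)
  len <- table(tracks$track_id)
  keep <- names(len)[len >= 3]
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

#' Track filters for the 2D migration assay
#'
#' Keeps tracks with at least 5 timepoints whose first frame index is
#' below 5 (i.e. cells present from near the start of the movie).
#'
#' @param tracks tidy track table
#' @return the filtered table
#' @export
filterTracks2D <- function(tracks) {
  checkTrackTable(tracks)
  ids <- unique(tracks$track_id)
  keep <- vapply(ids, function(id) {
    fr <- tracks$frame[tracks$track_id == id]
    length(fr) >= 5 && min(fr) < 5
  }, logical(1))
  tracks[tracks$track_id %in% ids[keep], , drop = FALSE]
}

#' Exclude cells with close neighbours at the selection frame
#'
#' A cell is eligible for tracking only if no other cell lies strictly
#' within \code{radius} of it at the selection frame.
#'
#' @param positions data.frame with columns \code{cell_id, x, y} (um)
#' @param radius exclusion radius (um)
#' @return vector of eligible cell ids
#' @export
proximityExclusion <- function(positions, radius = 35) {
  stopifnot(all(c("cell_id", "x", "y") %in% names(positions)))
  n <- nrow(positions)
  if (n <= 1L) return(positions$cell_id)
  d <- as.matrix(dist(positions[, c("x", "y")]))
  diag(d) <- Inf
  positions$cell_id[apply(d, 1, min) >= radius]
}

#' Per-condition summary of track metrics
#'
#' Means and sample standard deviations (n - 1 denominator) of every
#' metric, per condition.
#'
#' @param metrics per-track metric table from \code{\link{allTrackMetrics}};
#'   a \code{condition} column groups tracks (a single pseudo-condition is
#'   used when absent)
#' @return data.frame with one row per condition x metric: condition,
#'   metric, n, mean, sd (sd is NA for a single track)
#' @export
groupSummary <- function(metrics) {
  if (!"condition" %in% names(metrics)) metrics$condition <- "all"
  cols <- c("nTimepoints", "accumulatedDistance", "netDisplacement",
            "lateralDisplacement", "verticalDisplacement", "straightness",
            "speed", "parallelFmi")
  out <- list()
  for (cond in unique(metrics$condition)) {
    m <- metrics[metrics$condition == cond, , drop = FALSE]
    for (col in cols) {
      v <- m[[col]]
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, metric = col, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else NA_real_)
    }
  }
  do.call(rbind, out)
}
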