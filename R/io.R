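## Readers and writers for the formats the pipelines consume: 16-bit TIFF
## rasters, CSV track/ground-truth tables and YAML scene descriptions.

#' Write an intensity raster as a 16-bit TIFF
#'
#' Intensities are stored as 16-bit samples; values are clipped to
#' [0, 65535] and rounded.  Multi-channel arrays (rows x cols x channels)
#' are written as multi-sample TIFFs.
#'
#' @param img numeric matrix or rows x cols x channels array (AU)
#' @param path output file
#' @return invisibly, the path
#' @export
writeIntensityTiff <- function(img, path) {
  scaled <- pmin(pmax(round(img), 0), 65535) / 65535
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an intensity TIFF written by \code{\link{writeIntensityTiff}}
#'
#' @param path TIFF file
#' @return numeric matrix or array with intensities in AU
#' @export
readIntensityTiff <- function(path) {
  img <- tiff::readTIFF(path)
  round(img * 65535)
}

#' Write a tidy table as CSV
#'
#' @param x data.frame (track table, ground-truth table, per-focus table)
#' @param path output file
#' @return invisibly, the path
#' @export
writeTable <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy CSV table
#'
#' @param path CSV file
#' @return data.frame
#' @export
readTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a scene description as YAML
#'
#' Serialises the scalar parameters of a generator scene (rasters and
#' functions are omitted) so a scene can be archived next to its outputs.
#'
#' @param scene a \code{pillarScene}, \code{faScene}, \code{walkModel} or
#'   \code{omicsDesign}
#' @param path output file
#' @return invisibly, the path
#' @export
writeSceneYaml <- function(scene, path) {
  keep <- Filter(function(x) is.numeric(x) || is.character(x),
                 unclass(scene))
  keep <- keep[vapply(keep, function(x) length(x) <= 10, logical(1))]
  yaml::write_yaml(c(list(kind = class(scene)[1]), keep), path)
  invisible(path)
}
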