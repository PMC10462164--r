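## Accessor generics: slot access stays internal to the package.

#' Per-pillar table of a displacement field
#' @param object a \code{DisplacementField}
#' @return data.frame with one row per pillar
#' @export
setGeneric("pillars", function(object) standardGeneric("pillars"))

#' @rdname pillars
#' @export
setMethod("pillars", "DisplacementField", function(object) object@pillars)

#' Noise floor of a displacement field (um)
#' @param object a \code{DisplacementField}
#' @export
setGeneric("noiseFloor", function(object) standardGeneric("noiseFloor"))

#' @rdname noiseFloor
#' @export
setMethod("noiseFloor", "DisplacementField", function(object)
  object@noiseFloor)

#' Per-focus table of a FociSet
#' @param object a \code{FociSet}
#' @return data.frame with one row per focus
#' @export
setGeneric("foci", function(object) standardGeneric("foci"))

#' @rdname foci
#' @export
setMethod("foci", "FociSet", function(object) object@foci)

#' Label raster of a FociSet
#' @param object a \code{FociSet}
#' @return integer matrix (0 background, i = focus i)
#' @export
setGeneric("fociLabels", function(object) standardGeneric("fociLabels"))

#' @rdname fociLabels
#' @export
setMethod("fociLabels", "FociSet", function(object) object@labels)

#' Binary raster of a cell mask
#' @param object a \code{CellMask}
#' @return logical matrix
#' @export
setGeneric("maskRaster", function(object) standardGeneric("maskRaster"))

#' @rdname maskRaster
#' @export
setMethod("maskRaster", "CellMask", function(object) object@mask)

#' Cell area of a mask (um^2)
#' @param object a \code{CellMask}
#' @export
setGeneric("cellArea", function(object) standardGeneric("cellArea"))

#' @rdname cellArea
#' @export
setMethod("cellArea", "CellMask", function(object)
  sum(object@mask) * object@pixelSize^2)

#' Corrected pillar spring constant k (N/m)
#' @param object a \code{StiffnessModel}
#' @export
setGeneric("springConstant", function(object)
  standardGeneric("springConstant"))

#' @rdname springConstant
#' @export
setMethod("springConstant", "StiffnessModel", function(object) object@k)

#' Bending-only pillar spring constant (N/m)
#' @param object a \code{StiffnessModel}
#' @export
setGeneric("bendingStiffness", function(object)
  standardGeneric("bendingStiffness"))

#' @rdname bendingStiffness
#' @export
setMethod("bendingStiffness", "StiffnessModel", function(object)
  object@kBend)

#' Effective substrate Young's modulus (Pa)
#' @param object a \code{StiffnessModel}
#' @export
setGeneric("effectiveModulus", function(object)
  standardGeneric("effectiveModulus"))

#' @rdname effectiveModulus
#' @export
setMethod("effectiveModulus", "StiffnessModel", function(object)
  object@eEff)

#' Convert a ColocResult to a named list
#' @param x a \code{ColocResult}
#' @param ... unused
#' @return named list of the colocalization statistics
#' @export
setMethod("as.list", "ColocResult", function(x, ...) {
  list(pearson = x@pearson, tM1 = x@tM1, tM2 = x@tM2,
       percentVolume1 = x@percentVolume1, percentVolume2 = x@percentVolume2,
       t1 = x@t1, t2 = x@t2)
})
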