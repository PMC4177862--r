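# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname maskPixels
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' Accessors for ccmorph objects
#'
#' `maskPixels()` returns the binary pixel matrix; `pixelSpacing()` the
#' `c(row_mm, col_mm)` spacing; `subjectID()` the subject identifier;
#' `baseLength()`/`rectHeight()`/`rectCorners()`/`rectMode()` the bounding
#' rectangle geometry; `labelMatrix()` and `regionProportions()` the
#' subdivision labelling; `displacements()` the deformation array;
#' `templateImage()` and `templateFields()` the template parts.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name maskPixels
#' @aliases pixelSpacing subjectID baseLength rectHeight rectCorners rectMode
#'   labelMatrix regionProportions displacements templateImage templateFields
NULL

#' @rdname maskPixels
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname maskPixels
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname maskPixels
#' @export
setGeneric("baseLength", function(x) standardGeneric("baseLength"))
#' @rdname maskPixels
#' @export
setGeneric("rectHeight", function(x) standardGeneric("rectHeight"))
#' @rdname maskPixels
#' @export
setGeneric("rectCorners", function(x) standardGeneric("rectCorners"))
#' @rdname maskPixels
#' @export
setGeneric("rectMode", function(x) standardGeneric("rectMode"))
#' @rdname maskPixels
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname maskPixels
#' @export
setGeneric("regionProportions", function(x) standardGeneric("regionProportions"))
#' @rdname maskPixels
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))
#' @rdname maskPixels
#' @export
setGeneric("templateImage", function(x) standardGeneric("templateImage"))
#' @rdname maskPixels
#' @export
setGeneric("templateFields", function(x) standardGeneric("templateFields"))

setMethod("maskPixels", "MidsagittalMask", function(x) x@pixels)
setMethod("pixelSpacing", "MidsagittalMask", function(x) x@spacing)
setMethod("subjectID", "MidsagittalMask", function(x) x@subjectID)

setMethod("baseLength", "BoundingRect", function(x) x@baseMM)
setMethod("rectHeight", "BoundingRect", function(x) x@heightMM)
setMethod("rectCorners", "BoundingRect", function(x) x@corners)
setMethod("rectMode", "BoundingRect", function(x) x@mode)

setMethod("labelMatrix", "SubregionLabelMap", function(x) x@labels)
setMethod("regionProportions", "SubregionLabelMap", function(x) x@proportions)
setMethod("pixelSpacing", "SubregionLabelMap", function(x) x@spacing)

setMethod("displacements", "DeformationField", function(x) x@displacements)
setMethod("pixelSpacing", "DeformationField", function(x) x@spacing)
setMethod("subjectID", "DeformationField", function(x) x@subjectID)

setMethod("templateImage", "CCTemplate", function(x) x@image)
setMethod("templateFields", "CCTemplate", function(x) x@fields)
setMethod("pixelSpacing", "CCTemplate", function(x) x@spacing)
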