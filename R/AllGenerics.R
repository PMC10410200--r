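#' @import methods
NULL

#' System (template) labels
#'
#' Accessor for the molecular system labels carried by template sets,
#' per-system time series and enriched FC maps.
#'
#' @param x A \code{TemplateSet}, \code{SystemTimeSeries} or
#'   \code{EnrichedFCMaps} object.
#' @return Character vector of system labels.
#' @export
setGeneric("systemNames", function(x) standardGeneric("systemNames"))

#' Number of molecular systems
#'
#' @param x A \code{TemplateSet}, \code{SystemTimeSeries} or
#'   \code{EnrichedFCMaps} object.
#' @return Integer scalar.
#' @export
setGeneric("nSystems", function(x) standardGeneric("nSystems"))

#' Spatial grid dimensions
#'
#' @param x An object with a 3-D spatial grid.
#' @return Integer vector of length 3.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Voxel-to-world affine
#'
#' @param x An object with a 3-D spatial grid.
#' @return A 4x4 affine matrix mapping 0-based voxel indices to mm.
#' @export
setGeneric("affineMat", function(x) standardGeneric("affineMat"))

#' Number of true voxels in a mask
#'
#' @param x A \code{VolumeMask}.
#' @return Integer scalar.
#' @export
setGeneric("maskCount", function(x) standardGeneric("maskCount"))
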