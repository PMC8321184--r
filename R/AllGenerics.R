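#' @export
setGeneric("forwardProject", function(vol, geometry, ...)
  standardGeneric("forwardProject"))

#' @export
setGeneric("backProject", function(proj, ...) standardGeneric("backProject"))

#' @export
setGeneric("fdkWeightedBackproject", function(proj, ...)
  standardGeneric("fdkWeightedBackproject"))

#' @export
setGeneric("fdk", function(proj, filter, ...) standardGeneric("fdk"))

#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setGeneric("binCoefficients", function(x) standardGeneric("binCoefficients"))

#' @export
setGeneric("taps", function(x) standardGeneric("taps"))

#' @export
setGeneric("nHidden", function(x) standardGeneric("nHidden"))
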