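#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Maximum intensity projection along z
#'
#' @param x an \code{ImageStack}.
#' @param channel channel name or index; \code{NULL} projects all channels.
#' @return a 2D matrix (one channel) or 3D array (x, y, channel).
#' @export
setGeneric("maxProject", function(x, channel = NULL) standardGeneric("maxProject"))

#' @export
setGeneric("piValue", function(x) standardGeneric("piValue"))

#' @export
setGeneric("groundTruthTable", function(x, ...) standardGeneric("groundTruthTable"))
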