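#' Construct an ImageStack
#'
#' @param voxels 4D numeric array \code{(x, y, z, channel)}; a 3D array is
#'   promoted to a single channel.
#' @param voxelSize \code{(dx, dy, dz)} spacing in micrometres.
#' @param channelNames one label per channel.
#' @param timestamp optional acquisition time, seconds.
#' @return an \code{ImageStack}.
#' @examples
#' st <- ImageStack(array(1, c(8, 8, 4, 1)), c(0.1, 0.1, 0.35), "F-actin")
#' voxelSize(st)
#' @export
ImageStack <- function(voxels, voxelSize, channelNames = NULL,
                       timestamp = NULL) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(voxels)[4]))
  new("ImageStack", voxels = voxels, voxelSize = as.numeric(voxelSize),
      channelNames = as.character(channelNames),
      timestamp = if (is.null(timestamp)) NULL else as.numeric(timestamp))
}

#' @rdname voxelSize
#' @param x an \code{ImageStack} or \code{TimeLapse}.
#' @export
setMethod("voxelSize", "ImageStack", function(x) {
  v <- x@voxelSize
  names(v) <- c("dx", "dy", "dz")
  v
})

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "TimeLapse", function(x) {
  v <- x@voxelSize
  names(v) <- c("dx", "dy")
  v
})

#' @rdname channelNames
#' @param x an \code{ImageStack} or \code{TimeLapse}.
#' @export
setMethod("channelNames", "ImageStack", function(x) x@channelNames)

#' @rdname channelNames
#' @export
setMethod("channelNames", "TimeLapse", function(x) x@channelNames)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat("ImageStack:", d[1], "x", d[2], "x", d[3], "voxels,",
      d[4], "channel(s)\n")
  cat("  voxel size (um):", paste(signif(object@voxelSize, 3),
                                  collapse = " x "), "\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "TimeLapse", function(object) {
  d <- dim(object@frames)
  cat("TimeLapse:", d[4], "frames of", d[1], "x", d[2], "px,",
      d[3], "channel(s)\n")
  cat("  t = ", min(object@timestamps), "..", max(object@timestamps),
      " s\n", sep = "")
})

# Resolve a channel name or index to an index, with a clear error.
channelIndex <- function(stack, channel) {
  if (is.numeric(channel)) {
    ci <- as.integer(channel)
    if (ci < 1L || ci > length(stack@channelNames))
      stop("unknown channel index ", channel)
    return(ci)
  }
  ci <- match(channel, stack@channelNames)
  if (is.na(ci))
    stop("unknown channel '", channel, "'; have: ",
         paste(stack@channelNames, collapse = ", "))
  ci
}

# One channel as a 3D (x, y, z) array (z kept even when singleton).
channelVoxels <- function(stack, channel) {
  ci <- channelIndex(stack, channel)
  array(stack@voxels[, , , ci, drop = FALSE], dim(stack@voxels)[1:3])
}

#' @rdname maxProject
#' @export
setMethod("maxProject", "ImageStack", function(x, channel = NULL) {
  if (!is.null(channel)) {
    v <- channelVoxels(x, channel)
    return(apply(v, c(1, 2), max))
  }
  d <- dim(x@voxels)
  out <- array(0, c(d[1], d[2], d[4]))
  for (ci in seq_len(d[4]))
    out[, , ci] <- apply(x@voxels[, , , ci, drop = FALSE][, , , 1],
                         c(1, 2), max)
  dimnames(out) <- list(NULL, NULL, x@channelNames)
  out
})

#' Flatten a stack to its maximum intensity projection
#'
#' Returns a single-z \code{ImageStack} whose one plane holds the MIP of
#' every channel, so that all volumetric operations (segmentation,
#' centre-of-mass, polarity) can be run unchanged on the projection —
#' this is how end-point synapse measurements are made by default.
#'
#' @param stack an \code{ImageStack}.
#' @return an \code{ImageStack} with one z-section.
#' @export
mipStack <- function(stack) {
  m <- maxProject(stack)
  d <- dim(m)
  ImageStack(array(m, c(d[1], d[2], 1L, d[3])), stack@voxelSize,
             stack@channelNames, stack@timestamp)
}
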