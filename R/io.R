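#' Write an ImageStack to multi-plane TIFF with a YAML sidecar
#'
#' Planes are written z-fastest within channel as 16-bit samples; physical
#' voxel size, channel order and the intensity scale go to a sidecar
#' \code{<path>.yaml} so the round trip is self-describing. Integer
#' intensities up to 65535 round-trip losslessly.
#'
#' @param stack an \code{ImageStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  v <- stack@voxels
  d <- dim(v)
  scale <- max(65535, max(v))
  planes <- vector("list", d[3] * d[4])
  k <- 0L
  for (ci in seq_len(d[4])) for (zi in seq_len(d[3])) {
    k <- k + 1L
    # TIFF rasters are row-major (y, x); transpose from internal (x, y)
    planes[[k]] <- t(v[, , zi, ci]) / scale
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- list(
    voxel_size_um = as.numeric(stack@voxelSize),
    channel_names = as.character(stack@channelNames),
    n_z = d[3], n_channels = d[4],
    intensity_scale = scale,
    timestamp_s = if (is.null(stack@timestamp)) NULL else stack@timestamp
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an ImageStack from TIFF
#'
#' Reads a multi-plane TIFF written by \code{\link{writeStack}} (or any
#' plain TIFF plus explicit geometry). Voxel size comes from the YAML
#' sidecar; without a sidecar, \code{voxelSize} (and \code{nz}) must be
#' given or an error is raised — physical spacing is required for every
#' downstream distance computation.
#'
#' @param path TIFF path.
#' @param voxelSize optional \code{(dx, dy, dz)} override, um.
#' @param channelNames optional channel-name override.
#' @param nz number of z-sections (needed only without a sidecar).
#' @return an \code{ImageStack}.
#' @export
readStack <- function(path, voxelSize = NULL, channelNames = NULL,
                      nz = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  if (is.null(voxelSize)) voxelSize <- meta$voxel_size_um
  if (is.null(voxelSize))
    stop("voxel size unknown: no sidecar metadata and no override")
  planes <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (is.null(nz)) nz <- if (!is.null(meta)) meta$n_z else length(planes)
  nc <- length(planes) / nz
  if (nc != round(nc))
    stop("axis-order ambiguity: ", length(planes),
         " planes do not factor into ", nz, " z-sections")
  nc <- as.integer(nc)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  d2 <- dim(planes[[1]])
  # tiff reads row-major (y, x); transpose to the internal (x, y) order
  v <- array(0, c(d2[2], d2[1], nz, nc))
  k <- 0L
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    k <- k + 1L
    # recover the exact 16-bit sample before rescaling so that integer
    # intensities round-trip bit-identically
    v[, , zi, ci] <- round(t(planes[[k]]) * 65535) * (scale / 65535)
  }
  if (is.null(channelNames)) channelNames <- meta$channel_names
  ts <- meta$timestamp_s
  ImageStack(v, voxelSize, channelNames, ts)
}

#' Construct a TimeLapse
#'
#' @param frames 4D numeric array \code{(x, y, channel, frame)}.
#' @param timestamps strictly increasing frame times, seconds.
#' @param pixelSize \code{(dx, dy)} in micrometres.
#' @param channelNames one label per channel.
#' @return a \code{TimeLapse}.
#' @export
TimeLapse <- function(frames, timestamps, pixelSize = c(0.1, 0.1),
                      channelNames = NULL) {
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(frames)[3]))
  new("TimeLapse", frames = frames, timestamps = as.numeric(timestamps),
      voxelSize = as.numeric(pixelSize),
      channelNames = as.character(channelNames))
}

# One frame of one channel as an (x, y) matrix.
frameChannel <- function(tl, frame, channel) {
  ci <- if (is.numeric(channel)) as.integer(channel)
        else match(channel, tl@channelNames)
  if (is.na(ci) || ci < 1L || ci > dim(tl@frames)[3])
    stop("unknown channel '", channel, "'")
  tl@frames[, , ci, frame]
}
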