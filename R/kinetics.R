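#' Construct an AccumulationKinetics
#'
#' @param onset s after movie start at which IS enrichment begins.
#' @param duration s the enrichment lasts.
#' @param fold reporter enrichment inside the IS ROI during the plateau
#'   (1 = none).
#' @return an \code{AccumulationKinetics}.
#' @export
AccumulationKinetics <- function(onset = 120, duration = 378, fold = 3) {
  new("AccumulationKinetics", onset = onset, duration = duration,
      fold = fold)
}

#' A floating ROI track
#'
#' @param rois list of per-frame geometries: discs
#'   \code{list(center = c(x, y), radius = r)} or polygons
#'   \code{list(poly = matrix)}, in 0-based pixel coordinates.
#' @param label "cell", "IS", ...
#' @return a \code{RoiTrack}.
#' @export
RoiTrack <- function(rois, label = "ROI") {
  new("RoiTrack", rois = rois, label = label)
}

#' A static ROI replicated over all frames
#'
#' @param center,radius disc geometry in 0-based pixel coordinates.
#' @param nFrames number of frames.
#' @param label track label.
#' @return a \code{RoiTrack}.
#' @export
staticRoiTrack <- function(center, radius, nFrames, label = "ROI") {
  RoiTrack(rep(list(list(center = center, radius = radius)), nFrames),
           label)
}

roiPixelMask <- function(roi, nx, ny) {
  if (!is.null(roi$poly)) return(polygonMask(roi$poly, nx, ny))
  px <- rep(seq_len(nx) - 1, times = ny)
  py <- rep(seq_len(ny) - 1, each = nx)
  matrix((px - roi$center[1])^2 + (py - roi$center[2])^2 <= roi$radius^2,
         nx, ny)
}

#' Per-frame mean fluorescence intensity inside a floating ROI
#'
#' @param timelapse a \code{TimeLapse}.
#' @param track a \code{RoiTrack} with one geometry per frame.
#' @param channel channel name or index.
#' @return numeric MFI series, one value per frame.
#' @export
roiMfiSeries <- function(timelapse, track, channel) {
  d <- dim(timelapse@frames)
  if (length(track@rois) != d[4])
    stop("track must cover every frame (", d[4], " frames)")
  vapply(seq_len(d[4]), function(fi) {
    m <- roiPixelMask(track@rois[[fi]], d[1], d[2])
    if (!any(m)) stop("ROI outside frame bounds at frame ", fi)
    mean(frameChannel(timelapse, fi, channel)[m])
  }, numeric(1))
}

#' Duration of reporter accumulation at the immune synapse
#'
#' The per-frame enrichment is the IS-ROI MFI divided by the cell-ROI
#' MFI; its baseline is the median over the first 3 frames. Accumulation
#' is the longest contiguous run of at least \code{minFrames} frames with
#' enrichment exceeding \code{k} times baseline; the duration is the time
#' spanned between the midpoints of the boundary frame intervals, and 0
#' when no run crosses the threshold. The rule is intensity-scale
#' invariant (any common gain cancels in the ratio).
#'
#' @param isSeries,cellSeries aligned per-frame MFI series.
#' @param timestamps frame times, s.
#' @param k enrichment threshold multiplier (> 1).
#' @param minFrames minimum run length in frames.
#' @return an \code{\linkS4class{AccumulationResult}}.
#' @export
accumulationDuration <- function(isSeries, cellSeries, timestamps,
                                 k = 1.5, minFrames = 2L) {
  n <- length(isSeries)
  if (length(cellSeries) != n || length(timestamps) != n)
    stop("series and timestamps must be aligned")
  if (k <= 1) stop("k must be > 1")
  if (n < minFrames + 3) stop("too short to score")
  ratio <- isSeries / cellSeries
  baseline <- stats::median(ratio[1:3])
  above <- ratio > k * baseline
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= minFrames)
  mid <- function(i, j) (timestamps[i] + timestamps[j]) / 2
  dt <- if (n > 1) stats::median(diff(timestamps)) else 0
  if (length(runs) == 0L) {
    res <- new("AccumulationResult", onsetTime = timestamps[1],
               offsetTime = timestamps[1], duration = 0,
               peakEnrichment = max(ratio), enrichmentSeries = ratio,
               timestamps = timestamps)
    return(res)
  }
  best <- runs[which.max(r$lengths[runs])]
  i <- starts[best]; j <- ends[best]
  onset <- if (i > 1) mid(i - 1, i) else timestamps[1] - dt / 2
  offset <- if (j < n) mid(j, j + 1) else timestamps[n] + dt / 2
  new("AccumulationResult", onsetTime = onset, offsetTime = offset,
      duration = offset - onset, peakEnrichment = max(ratio),
      enrichmentSeries = ratio, timestamps = timestamps)
}

setMethod("show", "AccumulationResult", function(object) {
  cat(sprintf(
    "AccumulationResult: duration %.0f s (onset %.0f s, offset %.0f s), peak enrichment %.2f\n",
    object@duration, object@onsetTime, object@offsetTime,
    object@peakEnrichment))
})
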