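# Costes automatic threshold pair: regress B on A, walk the A threshold
# down until the correlation of the sub-threshold pixels is <= 0.
costesThresholds <- function(a, b, steps = 100L) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(c(min(a), min(b)))
  fit <- stats::lm.fit(cbind(1, a), b)
  slope <- fit$coefficients[2]
  inter <- fit$coefficients[1]
  for (tA in seq(max(a), min(a), length.out = steps)) {
    tB <- inter + slope * tA
    below <- a < tA & b < tB
    if (sum(below) > 2 &&
        stats::sd(a[below]) > 0 && stats::sd(b[below]) > 0 &&
        stats::cor(a[below], b[below]) <= 0)
      return(c(unname(tA), unname(tB)))
  }
  c(min(a), min(b))
}

#' Pixel-intensity colocalization metrics
#'
#' Pearson correlation (computed over all analysis-region pixels, without
#' thresholding) and Manders split coefficients M1 (fraction of channel-A
#' intensity on B-positive pixels) and M2 (symmetric counterpart), plus
#' the mask of jointly supra-threshold pixels. Intensity recoding for
#' display (e.g. remapping emission colours to RGB) never changes these
#' metrics.
#'
#' @param imgA,imgB 2D numeric matrices of identical shape.
#' @param regionMask logical matrix restricting the analysis
#'   (\code{NULL} = whole image).
#' @param thresholdMethod \code{"otsu"} (default), \code{"costes"} or
#'   \code{"manual"}.
#' @param thresholds length-2 \code{(tA, tB)} when manual.
#' @return a \code{\linkS4class{ColocResult}}.
#' @examples
#' a <- matrix(runif(64), 8)
#' colocMetrics(a, a)   # Pearson 1, M1 = M2 = 1
#' @export
colocMetrics <- function(imgA, imgB, regionMask = NULL,
                         thresholdMethod = c("otsu", "costes", "manual"),
                         thresholds = NULL) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (!all(dim(imgA) == dim(imgB))) stop("images must share shape")
  if (is.null(regionMask)) regionMask <- matrix(TRUE, nrow(imgA), ncol(imgA))
  if (!any(regionMask)) stop("empty analysis region")
  a <- imgA[regionMask]
  b <- imgB[regionMask]
  pearson <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    structure(NA_real_, reason = "zero variance: Pearson undefined")
  } else stats::cor(a, b)
  th <- switch(thresholdMethod,
    otsu = c(otsuThreshold(a), otsuThreshold(b)),
    costes = costesThresholds(a, b),
    manual = {
      if (length(thresholds) != 2) stop("manual thresholds (tA, tB) required")
      as.numeric(thresholds)
    })
  m1 <- if (sum(a) > 0) sum(a[b > th[2]]) / sum(a) else NA_real_
  m2 <- if (sum(b) > 0) sum(b[a > th[1]]) / sum(b) else NA_real_
  mask <- regionMask & imgA > th[1] & imgB > th[2]
  new("ColocResult", pearson = pearson, m1 = m1, m2 = m2,
      colocMask = mask, thresholds = c(tA = th[1], tB = th[2]),
      thresholdMethod = thresholdMethod)
}

setMethod("show", "ColocResult", function(object) {
  cat(sprintf(
    "ColocResult: Pearson = %.3f, M1 = %.3f, M2 = %.3f (%s thresholds %.3g / %.3g)\n",
    object@pearson, object@m1, object@m2, object@thresholdMethod,
    object@thresholds[1], object@thresholds[2]))
})

#' Colocalization at the en-face synaptic interface
#'
#' Reconstructs both channels en face at the synapse and computes
#' \code{\link{colocMetrics}} there; also builds a presentation overlay in
#' which channel A is recoded red, channel B green, and jointly
#' supra-threshold (colocalization) pixels white. The recoding is
#' cosmetic — metrics are computed on the raw resampled intensities.
#'
#' @param stack an \code{ImageStack}.
#' @param channelA,channelB channel names.
#' @param synapsePoint,axis interface position and axis (um), e.g. from a
#'   \code{ConjugateSegmentation}.
#' @param halfSize,slabUm forwarded to \code{\link{enfaceReconstruct}}.
#' @param ... forwarded to \code{\link{colocMetrics}}.
#' @return list: \code{result} (\code{ColocResult}), \code{overlay}
#'   (na x na x 3 RGB array in [0,1]), \code{enfaceA}, \code{enfaceB}.
#' @export
interfaceColocalization <- function(stack, channelA, channelB,
                                    synapsePoint, axis, halfSize = 5,
                                    slabUm = 1, ...) {
  efA <- enfaceReconstruct(stack, channelA, synapsePoint, axis,
                           halfSize = halfSize, slabUm = slabUm)
  efB <- enfaceReconstruct(stack, channelB, synapsePoint, axis,
                           halfSize = halfSize, slabUm = slabUm)
  res <- colocMetrics(efA, efB, ...)
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  ov <- array(0, c(dim(efA), 3))
  ov[, , 1] <- norm(efA)
  ov[, , 2] <- norm(efB)
  white <- res@colocMask
  for (k in 1:3) {
    plane <- ov[, , k]
    plane[white] <- 1
    ov[, , k] <- plane
  }
  list(result = res, overlay = ov, enfaceA = efA, enfaceB = efB)
}

# Bilinear sampling of a 2D matrix at fractional 0-based pixel coords.
bilinearSample <- function(img, q) {
  trilinearSample(array(img, c(dim(img), 1L)), cbind(q, 0))
}

#' Mean fluorescence intensity profile along a line
#'
#' Samples band-averaged intensity at unit-pixel steps along a segment;
#' at each step the intensity is averaged over \code{width} samples
#' spaced one pixel apart along the perpendicular.
#'
#' @param image 2D matrix or 3D (x, y, channel) array.
#' @param lineStart,lineEnd endpoints in 0-based pixel coordinates
#'   \code{(x, y)}, inside the image.
#' @param width averaging band width in pixels (odd).
#' @param pixelSize um per pixel for the position axis.
#' @param channelNames labels (multi-channel input).
#' @return an \code{\linkS4class{IntensityProfile}}.
#' @export
mfiProfile <- function(image, lineStart, lineEnd, width = 1L,
                       pixelSize = 1, channelNames = NULL) {
  d <- dim(image)
  if (length(d) == 2L) {
    image <- array(image, c(d, 1L))
    d <- dim(image)
  }
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(d[3]))
  v <- lineEnd - lineStart
  len <- sqrt(sum(v^2))
  if (len <= 0) stop("zero-length line")
  inb <- function(p) all(p >= 0) && p[1] <= d[1] - 1 && p[2] <= d[2] - 1
  if (!inb(lineStart) || !inb(lineEnd)) stop("endpoints outside image")
  u <- v / len
  perp <- c(-u[2], u[1])
  ts <- seq(0, len, by = 1)
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(width, 1))
  vals <- matrix(0, length(ts), d[3])
  for (ci in seq_len(d[3])) {
    acc <- numeric(length(ts))
    for (o in offs) {
      px <- lineStart[1] + ts * u[1] + o * perp[1]
      py <- lineStart[2] + ts * u[2] + o * perp[2]
      acc <- acc + bilinearSample(image[, , ci], cbind(px, py))
    }
    vals[, ci] <- acc / length(offs)
  }
  new("IntensityProfile", positions = ts * pixelSize, values = vals,
      channelNames = channelNames)
}
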