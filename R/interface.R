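# Vectorized trilinear sampling of a 3D array at fractional 0-based voxel
# indices q (n x 3); points outside the grid sample 0.
trilinearSample <- function(img, q) {
  n <- dim(img)
  out <- numeric(nrow(q))
  ok <- q[, 1] >= 0 & q[, 1] <= n[1] - 1 &
        q[, 2] >= 0 & q[, 2] <= n[2] - 1 &
        q[, 3] >= 0 & q[, 3] <= n[3] - 1
  if (!any(ok)) return(out)
  q <- q[ok, , drop = FALSE]
  f0 <- pmin(floor(q), rep(n - 1, each = nrow(q)) - 1)
  f0 <- pmax(f0, 0)
  f1 <- sweep(f0 + 1, 2, n - 1, pmin)  # upper corner clamped to the grid
  fr <- q - f0
  acc <- numeric(nrow(q))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (if (cx == 1) fr[, 1] else 1 - fr[, 1]) *
          (if (cy == 1) fr[, 2] else 1 - fr[, 2]) *
          (if (cz == 1) fr[, 3] else 1 - fr[, 3])
    ix <- if (cx == 1) f1[, 1] else f0[, 1]
    iy <- if (cy == 1) f1[, 2] else f0[, 2]
    iz <- if (cz == 1) f1[, 3] else f0[, 3]
    acc <- acc + wt * img[ix + n[1] * (iy + n[2] * iz) + 1]
  }
  out[ok] <- acc
  out
}

# Nearest-neighbour variant.
nearestSample <- function(img, q) {
  n <- dim(img)
  r <- round(q)
  ok <- r[, 1] >= 0 & r[, 1] <= n[1] - 1 &
        r[, 2] >= 0 & r[, 2] <= n[2] - 1 &
        r[, 3] >= 0 & r[, 3] <= n[3] - 1
  out <- numeric(nrow(q))
  ii <- r[ok, 1] + n[1] * (r[ok, 2] + n[2] * r[ok, 3]) + 1
  out[ok] <- img[ii]
  out
}

# Orthonormal basis completing the unit axis u.
axisBasis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- c(u[2] * ref[3] - u[3] * ref[2],
         u[3] * ref[1] - u[1] * ref[3],
         u[1] * ref[2] - u[2] * ref[1])
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(v = v, w = w)
}

#' En-face reconstruction of the synaptic interface
#'
#' Resamples a channel onto the plane orthogonal to the cell-to-synapse
#' axis through the synapse point — the "90 degree turn" that converts a
#' side-on z-stack into a head-on view of the interface. Output pixels are
#' isotropic with size equal to the lateral spacing dx (z is implicitly
#' rescaled by dz/dx). Because the physical interface has thickness
#' (cortical layer plus PSF), a thin slab centred on the plane is
#' max-projected rather than sampling a zero-thickness section; set
#' \code{slabUm = 0} for a pure plane.
#'
#' @param stack an \code{ImageStack}.
#' @param channel channel name or index.
#' @param synapsePoint interface point (x, y, z), um.
#' @param axis direction of the cell-centroid-to-synapse axis (need not be
#'   normalized).
#' @param halfSize half-width of the square output window, um.
#' @param slabUm slab depth aggregated along the axis, um.
#' @param sampling \code{"trilinear"} (default) or \code{"nearest"}.
#' @param aggregate how slab samples combine: \code{"mean"} (default;
#'   robust to noise fringes) or \code{"max"}.
#' @return 2D matrix, \code{attr "pixelSize"} = dx in um.
#' @export
enfaceReconstruct <- function(stack, channel, synapsePoint, axis,
                              halfSize = 5, slabUm = 1,
                              sampling = c("trilinear", "nearest"),
                              aggregate = c("mean", "max")) {
  sampling <- match.arg(sampling)
  aggregate <- match.arg(aggregate)
  img <- channelVoxels(stack, channel)
  vs <- unname(voxelSize(stack))
  u <- axis / sqrt(sum(axis^2))
  b <- axisBasis(u)
  dx <- vs[1]
  g <- seq(-halfSize, halfSize, by = dx)
  offs <- if (slabUm > 0) seq(-slabUm / 2, slabUm / 2, by = dx) else 0
  na <- length(g)
  A <- matrix(rep(g, times = na), ncol = 1)        # v-coordinate, fast axis
  B <- matrix(rep(g, each = na), ncol = 1)         # w-coordinate
  sampler <- if (sampling == "trilinear") trilinearSample else nearestSample
  out <- matrix(0, na, na)
  for (s in offs) {
    px <- synapsePoint[1] + A * b$v[1] + B * b$w[1] + s * u[1]
    py <- synapsePoint[2] + A * b$v[2] + B * b$w[2] + s * u[2]
    pz <- synapsePoint[3] + A * b$v[3] + B * b$w[3] + s * u[3]
    q <- cbind(px / vs[1], py / vs[2], pz / vs[3])
    plane <- matrix(sampler(img, q), na, na)
    out <- if (aggregate == "max") pmax(out, plane) else out + plane
  }
  if (aggregate == "mean") out <- out / length(offs)
  attr(out, "pixelSize") <- dx
  out
}

# Components of a 2D mask no smaller than `frac` of the largest one.
keepLargeComponents <- function(mask, frac) {
  lab <- label3d(mask)[, , 1]
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= frac * max(sizes))
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# 2D helpers on (x, y) matrices via the 3D mask machinery.
dilate2d <- function(mask, r) {
  m <- array(mask, c(dim(mask), 1L))
  dilateBox(m, c(r, r, 0L))[, , 1]
}

#' F-actin clearance ratio of an en-face interface image
#'
#' The synapse interface (IS) area is the filled convex region enclosing
#' supra-threshold F-actin; the F-actin-low central region is the largest
#' connected sub-threshold component interior to that region (components
#' touching the interface boundary are peripheral background and do not
#' count). The clearance ratio F-actin-low area / IS area is independent
#' of cell and synapse size, and — with the relative (Otsu) threshold —
#' of uniform intensity rescaling.
#'
#' @param enfaceFactin 2D en-face F-actin image (from
#'   \code{\link{enfaceReconstruct}}).
#' @param pixelSize isotropic pixel size in um (defaults to the image's
#'   \code{pixelSize} attribute).
#' @param thresholdMethod \code{"midlevel"} (default), \code{"otsu"} or
#'   \code{"manual"}. \code{"midlevel"} first outlines the interface with
#'   a foreground Otsu pass, then re-thresholds at the midpoint of the
#'   dim and bright intensity modes inside that outline — the midpoint of
#'   a blurred edge crosses at the true edge position, so areas are
#'   unbiased; \code{"otsu"} is the single-pass default threshold.
#' @param threshold absolute intensity threshold when manual.
#' @param interiorMargin pixels a low component must keep clear of the
#'   interface boundary to count as interior.
#' @return an \code{\linkS4class{InterfaceResult}}.
#' @export
clearanceRatio <- function(enfaceFactin, pixelSize = NULL,
                           thresholdMethod = c("midlevel", "otsu", "manual"),
                           threshold = NULL, interiorMargin = 2L) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (is.null(pixelSize)) pixelSize <- attr(enfaceFactin, "pixelSize")
  if (is.null(pixelSize)) stop("pixelSize unknown")
  img <- as.matrix(enfaceFactin)
  if (max(img) <= 0) stop("no IS detected: image has no signal")
  # Otsu on the foreground histogram: the sea of empty pixels outside
  # the cell would otherwise drag the threshold far below the
  # ring/clearance mid-level and bias both edges outward.
  fgOtsu <- function(x) {
    fg <- x[x > 0.05 * max(x)]
    t1 <- otsuThreshold(fg)
    if (any(x > t1)) t1 else otsuThreshold(x)
  }
  th <- switch(thresholdMethod,
    manual = {
      if (is.null(threshold)) stop("manual threshold not given")
      threshold
    },
    otsu = fgOtsu(img),
    midlevel = {
      t0 <- fgOtsu(img)
      s0 <- img > t0
      core0 <- keepLargeComponents(s0, 0.05)
      pts0 <- which(core0, arr.ind = TRUE) - 1
      h0 <- polygonMask(pts0[grDevices::chull(pts0[, 1], pts0[, 2]), ,
                             drop = FALSE], nrow(img), ncol(img)) | core0
      lowPx <- img[h0 & img <= t0]
      brightPx <- img[h0 & img > t0]
      if (length(lowPx) == 0) t0
      else (stats::quantile(lowPx, 0.1, names = FALSE) +
              stats::quantile(brightPx, 0.95, names = FALSE)) / 2
    })
  supra <- img > th
  if (!any(supra)) stop("no IS detected: no supra-threshold pixels")
  # the interface is the union of substantial supra-threshold structures
  # (arcs of a broken ring included); detached glints below 5% of the
  # largest structure (noise, out-of-plane cortex) do not widen the
  # outline
  core <- keepLargeComponents(supra, 0.05)
  pts <- which(core, arr.ind = TRUE) - 1
  hullIdx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- polygonMask(pts[hullIdx, , drop = FALSE],
                      nrow(img), ncol(img)) | core
  # pixel-centre counting overstates the area enclosed by an outline by
  # about half the boundary band; correct as in stereological counting
  hullBoundary <- hull & dilate2d(!hull, 1L)
  isArea <- (sum(hull) - 0.5 * sum(hullBoundary)) * pixelSize^2
  # interior = hull eroded by the margin: sub-threshold components there
  # are central clearance; thin peripheral slivers along the outline
  # (background between the outline and the actin rim) are excluded
  interior <- !dilate2d(!hull, interiorMargin)
  low <- interior & !supra
  lowMask <- matrix(FALSE, nrow(img), ncol(img))
  factinLowArea <- 0
  lab <- label3d(low)
  if (max(lab) > 0L) {
    lab <- lab[, , 1]
    sizes <- tabulate(lab[lab > 0L])
    best <- which.max(sizes)
    lowMask <- lab == best
    factinLowArea <- sizes[best] * pixelSize^2
  }
  new("InterfaceResult", enface = img, pixelSize = pixelSize,
      isArea = isArea, factinLowArea = factinLowArea,
      clearanceRatio = if (isArea > 0) factinLowArea / isArea else 0,
      threshold = th, thresholdMethod = thresholdMethod,
      isMask = hull, lowMask = lowMask)
}

setMethod("show", "InterfaceResult", function(object) {
  cat(sprintf(
    "InterfaceResult: IS area %.2f um^2, F-actin-low %.2f um^2, ratio %.3f (%s threshold %.3g)\n",
    object@isArea, object@factinLowArea, object@clearanceRatio,
    object@thresholdMethod, object@threshold))
})

#' Quantify F-actin clearance at the synapse of a conjugate stack
#'
#' Convenience pipeline: segments the conjugate (unless a segmentation is
#' supplied), reconstructs the en-face F-actin view along the
#' cell-centroid-to-synapse axis, and measures the clearance ratio.
#'
#' @param stack an \code{ImageStack}.
#' @param seg optional \code{ConjugateSegmentation}.
#' @param factinChannel channel name.
#' @param halfSize,slabUm forwarded to \code{\link{enfaceReconstruct}}; the
#'   default slab is kept thin so the interface plate is sampled without
#'   admixing cortex curving away behind the contact.
#' @param ... forwarded to \code{\link{clearanceRatio}}.
#' @return an \code{InterfaceResult}.
#' @export
interfaceQuantify <- function(stack, seg = NULL, factinChannel = "F-actin",
                              halfSize = 5, slabUm = 0.4, ...) {
  if (is.null(seg)) seg <- segmentConjugate(stack)
  axis <- seg@synapsePoint - seg@cellCentroid
  ef <- enfaceReconstruct(stack, factinChannel, seg@synapsePoint, axis,
                          halfSize = halfSize, slabUm = slabUm)
  clearanceRatio(ef, ...)
}
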