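# Shift a logical 3D mask by whole voxels, zero-padding at the edges.
shiftMask <- function(mask, d) {
  n <- dim(mask)
  out <- array(FALSE, n)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= 0) {
      src[[a]] <- seq_len(n[a] - d[a])
      dst[[a]] <- src[[a]] + d[a]
    } else {
      src[[a]] <- seq_len(n[a] + d[a]) - d[a]
      dst[[a]] <- seq_len(n[a] + d[a])
    }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    mask[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary dilation by an axis-aligned box of voxel radii r = (rx, ry, rz).
dilateBox <- function(mask, r) {
  for (a in 1:3) {
    if (r[a] <= 0 || dim(mask)[a] == 1L) next
    acc <- mask
    for (s in seq_len(r[a])) {
      d <- c(0L, 0L, 0L); d[a] <- s
      acc <- acc | shiftMask(mask, d) | shiftMask(mask, -d)
    }
    mask <- acc
  }
  mask
}

# Boundary voxels: mask voxels with a 6-neighbour outside the mask (or on
# the grid edge).
maskBoundary <- function(mask) {
  inner <- mask
  n <- dim(mask)
  for (a in 1:3) {
    if (n[a] == 1L) next
    d <- c(0L, 0L, 0L); d[a] <- 1L
    inner <- inner & shiftMask(mask, d) & shiftMask(mask, -d)
  }
  mask & !inner
}

# Morphological closing (3D box) followed by slice-wise hole filling
# (EBImage::fillHull). Closing bridges thin dark seams; filling turns a
# cortical ring into a solid body, so a membrane-biased stain still
# yields a volumetric cell mask.
closeMask <- function(mask, r = c(2L, 2L, 1L)) {
  n <- dim(mask)
  dil <- dilateBox(mask, r)
  closed <- !dilateBox(!dil, r)
  filled <- EBImage::fillHull(EBImage::Image(closed * 1, dim = n))
  array(as.array(filled) > 0.5, n)
}

#' Segment the T cell and the APC in a conjugate stack
#'
#' The APC is the largest connected component above an Otsu threshold in
#' the APC (CMAC) channel; the T-cell body is the largest component above
#' threshold in the cell channel after subtracting the APC mask. Both
#' masks are morphologically closed and kept disjoint. Manual thresholds
#' may replace the automatic ones.
#'
#' @param stack an \code{ImageStack}.
#' @param apcChannel,cellChannel channel names. The F-actin channel is the
#'   default T-cell body channel.
#' @param apcThreshold,cellThreshold optional manual absolute thresholds;
#'   \code{NULL} means Otsu.
#' @return list with logical arrays \code{tCellMask} and \code{apcMask}.
#' @export
segmentCells <- function(stack, apcChannel = "APC",
                         cellChannel = "F-actin",
                         apcThreshold = NULL, cellThreshold = NULL) {
  aimg <- channelVoxels(stack, apcChannel)
  cimg <- channelVoxels(stack, cellChannel)
  ta <- if (is.null(apcThreshold)) otsuThreshold(aimg) else apcThreshold
  # the cell channel is typically trimodal (background / cytosol /
  # cortex); the lower three-class Otsu level keeps the cytosol in the
  # body mask
  tc <- if (is.null(cellThreshold)) otsu3Lower(cimg) else cellThreshold
  apc <- largestComponent(closeMask(aimg > ta))
  if (is.null(apc)) stop("cell not found: no APC signal above threshold")
  tcell <- largestComponent(closeMask(cimg > tc) & !apc)
  if (is.null(tcell)) stop("cell not found: no cell signal above threshold")
  list(tCellMask = tcell, apcMask = apc)
}

#' Locate the synapse contact point between two cell masks
#'
#' The contact set on each side is the set of boundary voxels of one mask
#' within a small dilation radius (default 2 voxels laterally, 1 axially —
#' PSF-scale tolerance) of the other mask; the synapse point is the
#' midpoint of the two contact-set centroids, in physical micrometres.
#' Using both sides cancels the inward bias either single boundary
#' carries.
#'
#' @param tCellMask,apcMask disjoint logical voxel masks on one grid.
#' @param voxelSize \code{(dx, dy, dz)} in um.
#' @param dilation voxel radii \code{(rx, ry, rz)} of the contact search.
#' @return synapse point \code{(x, y, z)} in um.
#' @export
detectSynapsePoint <- function(tCellMask, apcMask, voxelSize,
                               dilation = c(2L, 2L, 1L)) {
  if (any(tCellMask & apcMask)) stop("masks must be disjoint")
  contactT <- maskBoundary(tCellMask) & dilateBox(apcMask, dilation)
  contactA <- maskBoundary(apcMask) & dilateBox(tCellMask, dilation)
  if (!any(contactT) || !any(contactA))
    stop("no contact between the cell masks")
  (maskCentroid(contactT, voxelSize) + maskCentroid(contactA, voxelSize)) / 2
}

#' Intensity-weighted centre of mass of a channel
#'
#' Background (the channel median outside the mask) is subtracted before
#' weighting; positions are voxel centres in physical micrometres.
#'
#' @param stack an \code{ImageStack}.
#' @param channel channel name or index.
#' @param mask logical voxel mask restricting the computation
#'   (\code{NULL} = whole stack, background 0).
#' @return centre of mass \code{(x, y, z)} in um.
#' @export
centerOfMass <- function(stack, channel, mask = NULL) {
  img <- channelVoxels(stack, channel)
  if (is.null(mask)) {
    bg <- 0
    mask <- array(TRUE, dim(img))
  } else {
    if (!any(mask)) stop("empty mask")
    bg <- stats::median(img[!mask])
  }
  w <- pmax(img - bg, 0)
  w[!mask] <- 0
  tot <- sum(w)
  if (tot <= 0) stop("empty signal: no weighted mass in mask")
  sel <- mask & w > 0
  idx <- which(sel, arr.ind = TRUE)
  ww <- w[sel]
  com <- colSums((idx - 1) * ww) / tot
  unname(com * voxelSize(stack))
}

# Brightest supra-threshold component of a channel within a mask:
# ranked by peak intensity, then volume, then lowest linear index.
brightestComponent <- function(img, within, threshold) {
  cand <- img > threshold & within
  lab <- label3d(cand)
  k <- max(lab)
  if (k == 0L) return(NULL)
  peak <- vol <- first <- numeric(k)
  for (i in seq_len(k)) {
    sel <- which(lab == i)
    peak[i] <- max(img[sel])
    vol[i] <- length(sel)
    first[i] <- sel[1]
  }
  ord <- order(-peak, -vol, first)
  array(lab == ord[1], dim(lab))
}

#' Full landmark segmentation of one T-cell/APC conjugate
#'
#' Runs \code{\link{segmentCells}}, \code{\link{detectSynapsePoint}} and
#' \code{\link{centerOfMass}} to produce every landmark the polarization
#' index needs: the cell geometric centre (binary-mask centroid), the
#' synapse point, and the MTOC and MVB centres of mass. The MTOC is the
#' centre of the brightest supra-threshold component (single-punctum
#' assumption; doublets resolved by peak intensity, then volume); the MVB
#' centre is the intensity-weighted centre of all supra-threshold MVB
#' signal inside the (dilated) T-cell mask.
#'
#' @param stack an \code{ImageStack}.
#' @param apcChannel,cellChannel,mtocChannel,mvbChannel channel names.
#' @param dilation voxel radii used both for the synapse contact search
#'   and for the organelle containment region.
#' @param ... thresholds forwarded to \code{\link{segmentCells}}.
#' @return a \code{\linkS4class{ConjugateSegmentation}}.
#' @export
segmentConjugate <- function(stack, apcChannel = "APC",
                             cellChannel = "F-actin",
                             mtocChannel = "MTOC", mvbChannel = "MVB",
                             dilation = c(2L, 2L, 1L), ...) {
  masks <- segmentCells(stack, apcChannel, cellChannel, ...)
  vs <- voxelSize(stack)[c("dx", "dy", "dz")]
  syn <- detectSynapsePoint(masks$tCellMask, masks$apcMask, vs, dilation)
  home <- dilateBox(masks$tCellMask, dilation)
  mimg <- channelVoxels(stack, mtocChannel)
  mcomp <- brightestComponent(mimg, home, otsuThreshold(mimg))
  if (is.null(mcomp)) stop("empty signal: no MTOC above threshold")
  mtoc <- centerOfMass(stack, mtocChannel, mcomp)
  vimg <- channelVoxels(stack, mvbChannel)
  mvbMask <- vimg > otsuThreshold(vimg) & home
  if (!any(mvbMask)) stop("empty signal: no MVB above threshold")
  mvb <- centerOfMass(stack, mvbChannel, mvbMask)
  new("ConjugateSegmentation",
      tCellMask = masks$tCellMask, apcMask = masks$apcMask,
      mvbMask = mvbMask,
      cellCentroid = maskCentroid(masks$tCellMask, vs),
      synapsePoint = syn, mtocCenter = mtoc, mvbCenter = mvb)
}

setMethod("show", "ConjugateSegmentation", function(object) {
  cat("ConjugateSegmentation\n")
  cat("  cell centroid (um):",
      paste(signif(object@cellCentroid, 4), collapse = ", "), "\n")
  cat("  synapse point (um):",
      paste(signif(object@synapsePoint, 4), collapse = ", "), "\n")
  cat("  MTOC (um):", paste(signif(object@mtocCenter, 4), collapse = ", "),
      " MVB (um):", paste(signif(object@mvbCenter, 4), collapse = ", "), "\n")
})
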