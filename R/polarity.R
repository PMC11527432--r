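#' Signed organelle polarization index
#'
#' The polarization index (PI) measures how far an organelle's centre of
#' mass has moved toward the synapse, normalized by cell size and shape.
#' With the cell geometric centre as origin, the organelle centre is
#' projected onto the axis running from the cell centre to the synapse
#' contact; the PI is that signed projection divided by the cell-centre to
#' synapse distance. +1 is fully polarized (organelle at the synapse), -1
#' fully anti-polarized; projections pointing away from the synapse are
#' negative. Values outside [-1, 1] are possible only when a landmark is
#' wrong, so they are reported unclamped and flagged.
#'
#' @param cellCentroid cell geometric centre (x, y, z), um.
#' @param massCenter organelle centre of mass (x, y, z), um.
#' @param synapsePoint synapse contact point (x, y, z), um.
#' @param organelle label stored in the result ("MTOC", "MVB", ...).
#' @param mode mode label recorded in the result.
#' @return a \code{\linkS4class{PolarityResult}}.
#' @examples
#' piValue(polarizationIndex(c(0, 0, 0), c(10, 0, 0), c(10, 0, 0)))  # +1
#' piValue(polarizationIndex(c(0, 0, 0), c(-10, 0, 0), c(10, 0, 0))) # -1
#' piValue(polarizationIndex(c(0, 0, 0), c(5, 5, 0), c(10, 0, 0)))   # 0.5
#' @export
polarizationIndex <- function(cellCentroid, massCenter, synapsePoint,
                              organelle = "organelle", mode = "points") {
  cellCentroid <- stopIfNot3(cellCentroid, "cellCentroid")
  massCenter <- stopIfNot3(massCenter, "massCenter")
  synapsePoint <- stopIfNot3(synapsePoint, "synapsePoint")
  axisVec <- synapsePoint - cellCentroid
  C <- sqrt(sum(axisVec^2))
  if (C <= 0) stop("degenerate axis: synapse point equals cell centroid")
  u <- axisVec / C
  proj <- sum((massCenter - cellCentroid) * u)
  pi <- proj / C
  new("PolarityResult", organelle = organelle, distanceAB = proj,
      distanceC = C, pi = pi, axis = u, mode = mode,
      flagged = abs(pi) > 1 + 1e-6)
}

#' @rdname piValue
#' @param x a \code{PolarityResult}.
#' @export
setMethod("piValue", "PolarityResult", function(x) x@pi)

setMethod("show", "PolarityResult", function(object) {
  cat(sprintf("PolarityResult [%s, %s]: PI = %.3f (A/B = %.2f um, C = %.2f um)%s\n",
              object@organelle, object@mode, object@pi,
              object@distanceAB, object@distanceC,
              if (object@flagged) "  ** |PI| > 1, check landmarks **" else ""))
})

#' Polarization indices of MTOC and MVB from a stack
#'
#' In \code{"MIP-2D"} mode (the measurement default) the stack is first
#' flattened to its maximum intensity projection and every landmark (cell
#' centroid, synapse point, organelle centres of mass) is recomputed on the
#' projection, so the PI is a 2D quantity; in \code{"full-3D"} mode the
#' volumetric landmarks of \code{seg} are used directly.
#'
#' @param stack an \code{ImageStack}.
#' @param seg a \code{ConjugateSegmentation} for the same stack (used
#'   directly in 3D mode; recomputed on the MIP in 2D mode).
#' @param mode \code{"MIP-2D"} or \code{"full-3D"}.
#' @param mtocChannel,mvbChannel,apcChannel,cellChannel channel names used
#'   when re-segmenting the projection.
#' @return list with elements \code{mtoc} and \code{mvb}, both
#'   \code{PolarityResult}.
#' @export
polarityFromStack <- function(stack, seg = NULL,
                              mode = c("MIP-2D", "full-3D"),
                              mtocChannel = "MTOC", mvbChannel = "MVB",
                              apcChannel = "APC", cellChannel = "F-actin") {
  mode <- match.arg(mode)
  if (mode == "MIP-2D") {
    flat <- mipStack(stack)
    seg <- segmentConjugate(flat, apcChannel = apcChannel,
                            cellChannel = cellChannel,
                            mtocChannel = mtocChannel,
                            mvbChannel = mvbChannel)
  } else if (is.null(seg)) {
    seg <- segmentConjugate(stack, apcChannel = apcChannel,
                            cellChannel = cellChannel,
                            mtocChannel = mtocChannel,
                            mvbChannel = mvbChannel)
  }
  list(
    mtoc = polarizationIndex(seg@cellCentroid, seg@mtocCenter,
                             seg@synapsePoint, "MTOC", mode),
    mvb = polarizationIndex(seg@cellCentroid, seg@mvbCenter,
                            seg@synapsePoint, "MVB", mode)
  )
}

#' MVB-MTOC polarization coupling across cells
#'
#' Per-cell coupling of MVB and MTOC polarization: the Pearson correlation
#' of paired per-cell PIs, plus the mean and SD of the physical distance
#' between the two organelle centres of mass.
#'
#' @param piMvb,piMtoc paired per-cell polarization indices (>= 3 cells).
#' @param mvbCenters,mtocCenters optional matrices (cell x 3) of centres
#'   in um for the distance summary.
#' @return list: \code{pearson_r} (NA with a reason attribute when a
#'   variable is constant), \code{n}, and when centres are given
#'   \code{center_distance_mean_um} / \code{center_distance_sd_um}.
#' @export
mvbMtocCoupling <- function(piMvb, piMtoc, mvbCenters = NULL,
                            mtocCenters = NULL) {
  if (length(piMvb) != length(piMtoc))
    stop("piMvb and piMtoc must be paired")
  n <- length(piMvb)
  if (n < 3) stop("need >= 3 cells")
  r <- if (stats::sd(piMvb) == 0 || stats::sd(piMtoc) == 0) {
    structure(NA_real_, reason = "zero variance: correlation undefined")
  } else stats::cor(piMvb, piMtoc)
  out <- list(pearson_r = r, n = n)
  if (!is.null(mvbCenters) && !is.null(mtocCenters)) {
    d <- sqrt(rowSums((mvbCenters - mtocCenters)^2))
    out$center_distance_mean_um <- mean(d)
    out$center_distance_sd_um <- stats::sd(d)
  }
  out
}
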