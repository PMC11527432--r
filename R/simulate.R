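#' Scene parameters for the conjugate simulator
#'
#' Defaults describe a Jurkat-sized T cell (radius 5 um) conjugated with a
#' slightly larger Raji APC (radius 6 um), imaged at 0.1 um lateral / 0.35
#' um axial spacing (35 z-sections over ~12 um), with the MTOC and MVB
#' cloud placed 4 um toward the synapse (a polarized end-point conjugate),
#' 40% of the contact-disc area F-actin-depleted, and peak SNR 20.
#'
#' @param tCellCenter,tCellRadius,apcCenter,apcRadius sphere geometry, um.
#' @param mtocTrue true MTOC position, um.
#' @param mvbCount,mvbSpread,mvbCenterTrue MVB puncta count, scatter SD and
#'   true centre.
#' @param actinShellThickness cortical F-actin layer thickness, um.
#' @param clearanceFractionTrue fraction of contact-disc area depleted.
#' @param snr peak signal to total noise; \code{Inf} disables noise.
#' @param psfSigma Gaussian PSF sigmas (x, y, z), um.
#' @param voxelSize grid spacing (dx, dy, dz), um.
#' @param seed integer RNG seed.
#' @return a validated \code{\linkS4class{SceneParams}}.
#' @export
SceneParams <- function(tCellCenter = c(6, 9, 6.125), tCellRadius = 5,
                        apcCenter = c(16, 9, 6.125), apcRadius = 6,
                        mtocTrue = tCellCenter + c(4, 0, 0),
                        mvbCount = 12L, mvbSpread = 1.5,
                        mvbCenterTrue = mtocTrue,
                        actinShellThickness = 0.6,
                        clearanceFractionTrue = 0.4,
                        snr = 20, psfSigma = c(0.15, 0.15, 0.3),
                        voxelSize = c(0.1, 0.1, 0.35),
                        seed = 1L) {
  new("SceneParams",
      tCellCenter = as.numeric(tCellCenter), tCellRadius = tCellRadius,
      apcCenter = as.numeric(apcCenter), apcRadius = apcRadius,
      mtocTrue = as.numeric(mtocTrue), mvbCount = as.integer(mvbCount),
      mvbSpread = mvbSpread, mvbCenterTrue = as.numeric(mvbCenterTrue),
      actinShellThickness = actinShellThickness,
      clearanceFractionTrue = clearanceFractionTrue,
      snr = snr, psfSigma = as.numeric(psfSigma),
      voxelSize = as.numeric(voxelSize), seed = as.integer(seed))
}

# Analytic geometry of the two-sphere conjugate, in world coordinates.
# The contact plane is the radical plane of the two spheres; the T-cell
# body is its sphere truncated at that plane, and the true cell centroid
# is the closed-form centroid of a sphere minus a spherical cap.
sceneGeometry <- function(params) {
  tc <- params@tCellCenter; ac <- params@apcCenter
  R1 <- params@tCellRadius; R2 <- params@apcRadius
  D <- sqrt(sum((ac - tc)^2))
  if (D > R1 + R2 + 1e-9) stop("no contact: cells are disjoint")
  if (D <= 0) stop("degenerate geometry: coincident cell centres")
  u <- (ac - tc) / D
  d1 <- (D^2 + R1^2 - R2^2) / (2 * D)
  discRadius <- if (d1 < R1) sqrt(R1^2 - d1^2) else 0
  synapsePoint <- tc + d1 * u
  V <- 4 / 3 * pi * R1^3
  if (d1 < R1) {
    h <- R1 - d1
    Vcap <- pi * h^2 * (3 * R1 - h) / 3
    offset <- -(pi / 4) * (R1^2 - d1^2)^2 / (V - Vcap)
  } else offset <- 0
  list(u = u, d1 = d1, discRadius = discRadius,
       synapsePoint = synapsePoint,
       cellCentroidTrue = tc + offset * u,
       contactDistApc = D - d1)
}

# Distance-squared field to a point, on the (xs, ys, zs) grid, um^2.
distSqField <- function(xs, ys, zs, p) {
  outer(outer((xs - p[1])^2, (ys - p[2])^2, "+"), (zs - p[3])^2, "+")
}

# Signed projection field (p - origin) . u on the grid.
projField <- function(xs, ys, zs, origin, u) {
  outer(outer((xs - origin[1]) * u[1], (ys - origin[2]) * u[2], "+"),
        (zs - origin[3]) * u[3], "+")
}

# Apply the imaging model: anisotropic Gaussian PSF then Poisson counts
# at peak level P = 1.25 * snr^2 plus Gaussian read noise of SD 0.5*sqrt(P)
# (so snr = peak / sigma_total). Counts are integers; noiseless channels
# are left continuous on a 0..1000 scale.
imageChannel <- function(ideal, params) {
  sVox <- params@psfSigma / params@voxelSize
  if (any(sVox > 0)) ideal <- gaussBlur3d(ideal, sVox)
  mx <- max(ideal)
  if (mx <= 0) return(ideal)
  if (!is.finite(params@snr)) return(ideal / mx * 1000)
  P <- 1.25 * params@snr^2
  lam <- ideal / mx * P
  counts <- stats::rpois(length(lam), lam) +
    stats::rnorm(length(lam), 0, 0.5 * sqrt(P))
  array(pmax(0, round(counts)), dim = dim(ideal))
}

#' Simulate a two-cell conjugate z-stack with known ground truth
#'
#' Forward model of a T-cell/APC conjugate: both cells are spheres
#' truncated at their contact plane (the contact disc is their
#' intersection). Five channels are rendered — APC volume (CMAC), a
#' point-like MTOC, a cloud of MVB puncta, a cortical F-actin layer
#' covering the whole T-cell boundary (including the flat contact face)
#' over a dimmer cytosolic fill, with a circular F-actin-depleted zone
#' concentric with the contact disc covering
#' \code{clearanceFractionTrue} of its area, and a diffuse cytosolic
#' reporter. Each channel is blurred with the anisotropic Gaussian PSF and
#' degraded with Poisson + Gaussian read noise scaled to \code{snr}. The
#' render is bit-identical for identical parameters and seed.
#'
#' Ground-truth landmark coordinates are reported in the stack's frame
#' (grid origin at voxel (0,0,0)); true PIs are computed with
#' \code{\link{polarizationIndex}} from the analytic centroid of the
#' truncated T-cell body, the contact-disc centre, and the organelle
#' centres (for MVB, the realized puncta centre of mass).
#'
#' @param params a \code{\linkS4class{SceneParams}}.
#' @param margin field margin around the cells, um.
#' @return list with elements \code{stack} (\code{ImageStack}) and
#'   \code{truth} (\code{\linkS4class{GroundTruth}}).
#' @export
simulateConjugate <- function(params, margin = 1) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  geom <- sceneGeometry(params)
  vs <- params@voxelSize
  lo <- pmin(params@tCellCenter - params@tCellRadius,
             params@apcCenter - params@apcRadius) - margin
  hi <- pmax(params@tCellCenter + params@tCellRadius,
             params@apcCenter + params@apcRadius) + margin
  n <- pmax(2L, as.integer(ceiling((hi - lo) / vs)) + 1L)
  toGrid <- function(p) p - lo
  xs <- axisCoords(n[1], vs[1]) + lo[1]
  ys <- axisCoords(n[2], vs[2]) + lo[2]
  zs <- axisCoords(n[3], vs[3]) + lo[3]

  tc <- params@tCellCenter
  R1 <- params@tCellRadius
  d2t <- distSqField(xs, ys, zs, tc)
  d2a <- distSqField(xs, ys, zs, params@apcCenter)
  proj <- projField(xs, ys, zs, tc, geom$u)
  tBody <- d2t <= R1^2 & proj <= geom$d1
  apcBody <- d2a <= params@apcRadius^2 & proj > geom$d1

  thick <- params@actinShellThickness
  distToSurf <- R1 - sqrt(d2t)
  rad2 <- pmax(d2t - proj^2, 0)            # squared distance to the contact axis
  # Cortical layer: spherical shell away from the contact plus a flat
  # plate of radius = contact-disc radius at the interface (where the
  # dSMAC actin ring lies).
  shell <- tBody & distToSurf <= thick & proj <= geom$d1 - thick
  plate <- tBody & (geom$d1 - proj) <= thick & rad2 <= geom$discRadius^2
  rClear <- sqrt(params@clearanceFractionTrue) * geom$discRadius
  # The depletion column reaches into the cortex behind the plate, as a
  # secretory cleft does; otherwise axial PSF blur refills a thin hole
  # with cytosolic signal.
  cleared <- tBody & rad2 <= rClear^2 & (geom$d1 - proj) <= thick + 1.2
  factin <- array(0, n)
  factin[tBody] <- 0.1                      # cytosolic phalloidin background
  factin[shell | plate] <- 1
  factin[cleared] <- 0.05

  mtocSig <- exp(-distSqField(xs, ys, zs, params@mtocTrue) / (2 * 0.2^2))

  res <- withSeed(params@seed, {
    pts <- matrix(0, params@mvbCount, 3)
    for (i in seq_len(params@mvbCount)) {
      repeat {
        p <- params@mvbCenterTrue + stats::rnorm(3, 0, params@mvbSpread)
        inT <- sum((p - tc)^2) <= (R1 - 0.3)^2 &&
          sum((p - tc) * geom$u) <= geom$d1 - 0.3
        if (inT) break
      }
      pts[i, ] <- p
    }
    mvbSig <- array(0, n)
    for (i in seq_len(params@mvbCount))
      mvbSig <- mvbSig + exp(-distSqField(xs, ys, zs, pts[i, ]) / (2 * 0.25^2))
    chans <- list(
      APC = imageChannel(apcBody * 1, params),
      MTOC = imageChannel(mtocSig, params),
      MVB = imageChannel(mvbSig, params),
      "F-actin" = imageChannel(factin, params),
      reporter = imageChannel(tBody * 0.4, params)
    )
    list(chans = chans, pts = pts)
  })

  v <- array(0, c(n, 5L))
  for (ci in 1:5) v[, , , ci] <- res$chans[[ci]]
  stack <- ImageStack(v, vs, names(res$chans))

  cellC <- toGrid(geom$cellCentroidTrue)
  syn <- toGrid(geom$synapsePoint)
  mvbCom <- toGrid(colMeans(res$pts))
  truth <- new("GroundTruth", params = params,
    piTrueMtoc = piValue(polarizationIndex(cellC, toGrid(params@mtocTrue), syn)),
    piTrueMvb = piValue(polarizationIndex(cellC, mvbCom, syn)),
    synapsePointTrue = syn, cellCentroidTrue = cellC, mvbComTrue = mvbCom)
  list(stack = stack, truth = truth)
}

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: PI(MTOC) = %.3f, PI(MVB) = %.3f, clearance = %.2f\n",
              object@piTrueMtoc, object@piTrueMvb,
              object@params@clearanceFractionTrue))
  cat("  synapse point (um):",
      paste(signif(object@synapsePointTrue, 4), collapse = ", "), "\n")
})

#' @rdname groundTruthTable
#' @param x a \code{GroundTruth} or a list of them.
#' @param ... unused.
#' @return a data.frame, one row per scene, suitable for CSV export.
#' @export
setMethod("groundTruthTable", "GroundTruth", function(x, ...) {
  data.frame(
    seed = x@params@seed,
    pi_true_mtoc = x@piTrueMtoc,
    pi_true_mvb = x@piTrueMvb,
    clearance_fraction_true = x@params@clearanceFractionTrue,
    synapse_x_um = x@synapsePointTrue[1],
    synapse_y_um = x@synapsePointTrue[2],
    synapse_z_um = x@synapsePointTrue[3]
  )
})

#' @rdname groundTruthTable
#' @export
setMethod("groundTruthTable", "list", function(x, ...) {
  do.call(rbind, lapply(x, groundTruthTable))
})

#' Scene parameters targeting a given true MTOC polarization
#'
#' Places the MTOC (and the MVB cloud centre, offset by \code{mvbJitter})
#' on the cell-centroid-to-synapse axis so that the analytic PI of the
#' rendered scene equals \code{piTarget}.
#'
#' @param piTarget desired true MTOC PI.
#' @param seed RNG seed.
#' @param mvbJitter SD (um) of an isotropic offset of the MVB cloud centre
#'   from the MTOC, drawn deterministically from \code{seed}.
#' @param ... further arguments to \code{\link{SceneParams}}.
#' @return a \code{SceneParams}.
#' @export
sceneAtPI <- function(piTarget, seed = 1L, mvbJitter = 0, ...) {
  base <- SceneParams(seed = as.integer(seed), ...)
  geom <- sceneGeometry(base)
  C <- sqrt(sum((geom$synapsePoint - geom$cellCentroidTrue)^2))
  mtoc <- geom$cellCentroidTrue + piTarget * C * geom$u
  if (sqrt(sum((mtoc - base@tCellCenter)^2)) > base@tCellRadius - 0.25)
    stop("piTarget places the MTOC outside the cell")
  mvbC <- mtoc
  if (mvbJitter > 0) {
    mvbC <- withSeed(seed + 10000L, mtoc + stats::rnorm(3, 0, mvbJitter))
    off <- mvbC - base@tCellCenter
    lim <- base@tCellRadius - 0.3
    if (sqrt(sum(off^2)) > lim)          # keep the cloud centre inside the cell
      mvbC <- base@tCellCenter + off / sqrt(sum(off^2)) * lim
  }
  SceneParams(seed = as.integer(seed), mtocTrue = mtoc,
              mvbCenterTrue = mvbC, ...)
}
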