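#' Simulate a time-lapse of reporter accumulation at a nascent synapse
#'
#' Renders a 2D two-cell conjugate (the equatorial plane of the
#' \code{\link{SceneParams}} geometry) over time. The reporter channel is
#' diffuse in the T-cell cytosol; between \code{onset} and
#' \code{onset + duration} its intensity inside the true IS region (a
#' disc of radius \code{isRadius} around the contact point) is multiplied
#' by \code{fold}, then returns to baseline. Frames carry strictly
#' increasing timestamps; identical parameters and seed give a
#' bit-identical movie.
#'
#' @param params a \code{SceneParams} (geometry, optics, noise, seed).
#' @param kinetics an \code{\linkS4class{AccumulationKinetics}}.
#' @param frameInterval s between frames (> 0).
#' @param totalTime movie length, s.
#' @param isRadius radius of the true IS accumulation disc, um.
#' @param margin field margin, um.
#' @return list: \code{timelapse} (a \code{TimeLapse} with channels APC
#'   and reporter), \code{truth} (true onset/duration/fold, the IS and
#'   cell ROI tracks in pixel coordinates, and \code{durationTrue} — 0
#'   when \code{fold} is 1).
#' @export
simulateTimelapse <- function(params, kinetics, frameInterval = 30,
                              totalTime = 900, isRadius = 1.5,
                              margin = 1) {
  stopifnot(is(params, "SceneParams"), is(kinetics, "AccumulationKinetics"))
  validObject(params); validObject(kinetics)
  if (frameInterval <= 0) stop("frame interval must be > 0")
  geom <- sceneGeometry(params)
  vs <- params@voxelSize
  lo <- pmin(params@tCellCenter - params@tCellRadius,
             params@apcCenter - params@apcRadius) - margin
  hi <- pmax(params@tCellCenter + params@tCellRadius,
             params@apcCenter + params@apcRadius) + margin
  n <- pmax(2L, as.integer(ceiling((hi - lo) / vs)) + 1L)[1:2]
  xs <- axisCoords(n[1], vs[1]) + lo[1]
  ys <- axisCoords(n[2], vs[2]) + lo[2]
  zc <- params@tCellCenter[3]
  # 2D fields in the equatorial plane
  d2t <- outer((xs - params@tCellCenter[1])^2,
               (ys - params@tCellCenter[2])^2, "+")
  d2a <- outer((xs - params@apcCenter[1])^2,
               (ys - params@apcCenter[2])^2, "+")
  u <- geom$u
  proj <- outer((xs - params@tCellCenter[1]) * u[1],
                (ys - params@tCellCenter[2]) * u[2], "+")
  tDisc <- d2t <= params@tCellRadius^2 & proj <= geom$d1
  apcDisc <- d2a <= params@apcRadius^2 & proj > geom$d1
  syn <- geom$synapsePoint
  # the IS ROI disc sits tangent to the contact, wholly inside the T cell,
  # so the programmed fold applies across the whole ROI
  isCenter <- syn - isRadius * u
  d2syn <- outer((xs - isCenter[1])^2, (ys - isCenter[2])^2, "+")
  isMask <- tDisc & d2syn <= isRadius^2
  times <- seq(0, totalTime, by = frameInterval)
  nf <- length(times)
  blur2 <- function(m) {
    gaussBlur3d(array(m, c(dim(m), 1L)),
                c(params@psfSigma[1:2] / vs[1:2], 0))[, , 1]
  }
  apcIdeal <- blur2(apcDisc * 1)
  frames <- array(0, c(n[1], n[2], 2L, nf))
  enriched <- times >= kinetics@onset &
              times < kinetics@onset + kinetics@duration
  withSeed(params@seed, {
    for (fi in seq_len(nf)) {
      rep0 <- tDisc * 0.4
      if (enriched[fi] && kinetics@fold > 1)
        rep0[isMask] <- rep0[isMask] * kinetics@fold
      repIdeal <- blur2(rep0)
      noisy <- function(ideal) {
        mx <- max(ideal)
        if (mx <= 0) return(ideal)
        if (!is.finite(params@snr)) return(ideal / mx * 1000)
        P <- 1.25 * params@snr^2
        lam <- ideal / mx * P
        matrix(pmax(0, round(stats::rpois(length(lam), lam) +
                               stats::rnorm(length(lam), 0, 0.5 * sqrt(P)))),
               nrow(ideal), ncol(ideal))
      }
      frames[, , 1, fi] <- noisy(apcIdeal)
      frames[, , 2, fi] <- noisy(repIdeal)
    }
  })
  tl <- TimeLapse(frames, times, pixelSize = vs[1:2],
                  channelNames = c("APC", "reporter"))
  toPx <- function(p) (p[1:2] - lo[1:2]) / vs[1:2]
  isCenterPx <- toPx(isCenter)
  cellCenterPx <- toPx(params@tCellCenter)
  truth <- list(
    onset = kinetics@onset,
    durationTrue = if (kinetics@fold > 1) kinetics@duration else 0,
    fold = kinetics@fold,
    isTrack = staticRoiTrack(isCenterPx, isRadius / vs[1], nf, "IS"),
    cellTrack = staticRoiTrack(cellCenterPx,
                               0.5 * params@tCellRadius / vs[1], nf,
                               "cell"),
    frameInterval = frameInterval
  )
  list(timelapse = tl, truth = truth)
}
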