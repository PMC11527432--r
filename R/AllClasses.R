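#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ImageStack: a multi-channel 3D fluorescence stack
#'
#' Container for a multi-channel z-stack with physical voxel spacing.
#' Voxels are stored as a 4D array in \code{(x, y, z, channel)} order
#' (column-major, the natural R/EBImage layout). Physical coordinates are
#' always reported as \code{(x, y, z)} in micrometres with
#' \code{coordinate = 0-based voxel index * spacing} and all distance
#' computations are anisotropy-corrected (dz may exceed dx = dy).
#'
#' @slot voxels 4D numeric array \code{(nx, ny, nz, nchannel)}; finite,
#'   non-negative intensities.
#' @slot voxelSize numeric length-3 \code{(dx, dy, dz)} in micrometres.
#' @slot channelNames character, one label per channel.
#' @slot timestamp optional acquisition time in seconds (or NULL).
#' @export
setClass("ImageStack",
  representation(
    voxels = "array",
    voxelSize = "numeric",
    channelNames = "character",
    timestamp = "numericOrNULL"
  )
)

setValidity("ImageStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 4L)
    return("voxels must be a 4D (x, y, z, channel) array")
  if (any(!is.finite(v)) || any(v < 0))
    return("intensities must be finite and >= 0")
  vs <- object@voxelSize
  if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
    return("voxelSize must be three positive numbers (dx, dy, dz) in um")
  if (abs(vs[1] - vs[2]) > 1e-9)
    return("in-plane spacing must be isotropic (dx = dy)")
  if (vs[3] < vs[1] - 1e-9)
    return("axial spacing dz must be >= lateral spacing dx")
  if (length(object@channelNames) != dim(v)[4])
    return("one channel name per channel required")
  if (anyDuplicated(object@channelNames))
    return("channel names must be unique")
  TRUE
})

#' TimeLapse: an ordered multi-channel 2D frame sequence
#'
#' @slot frames 4D numeric array \code{(nx, ny, nchannel, nframe)}.
#' @slot timestamps numeric seconds, strictly increasing, one per frame.
#' @slot voxelSize numeric length-2 \code{(dx, dy)} in micrometres.
#' @slot channelNames character labels.
#' @export
setClass("TimeLapse",
  representation(
    frames = "array",
    timestamps = "numeric",
    voxelSize = "numeric",
    channelNames = "character"
  )
)

setValidity("TimeLapse", function(object) {
  f <- object@frames
  if (length(dim(f)) != 4L)
    return("frames must be a 4D (x, y, channel, frame) array")
  if (any(!is.finite(f)) || any(f < 0))
    return("intensities must be finite and >= 0")
  ts <- object@timestamps
  if (length(ts) != dim(f)[4])
    return("one timestamp per frame required")
  if (length(ts) > 1 && any(diff(ts) <= 0))
    return("timestamps must be strictly increasing")
  if (length(object@channelNames) != dim(f)[3])
    return("one channel name per channel required")
  TRUE
})

#' SceneParams: ground-truth geometry for a simulated conjugate
#'
#' Parameters of the two-cell conjugate forward model: a T cell and an APC
#' rendered as spheres truncated at their contact plane, a point-like MTOC,
#' a cluster of MVB puncta, a cortical F-actin layer with a central
#' clearance at the contact disc, and an imaging model (anisotropic
#' Gaussian PSF, Poisson + Gaussian read noise). All lengths in
#' micrometres.
#'
#' @slot tCellCenter,tCellRadius T-cell sphere centre (x,y,z) and radius.
#' @slot apcCenter,apcRadius APC sphere centre and radius.
#' @slot mtocTrue true MTOC position (inside the T cell).
#' @slot mvbCount,mvbSpread,mvbCenterTrue number of MVB puncta, the SD of
#'   their isotropic scatter, and their true centre.
#' @slot actinShellThickness thickness of the cortical F-actin layer.
#' @slot clearanceFractionTrue fraction in [0,1] of the contact-disc area
#'   rendered F-actin-depleted.
#' @slot snr peak-signal-to-total-noise ratio; \code{Inf} for noiseless.
#' @slot psfSigma Gaussian PSF sigmas (x, y, z); 0 disables blurring.
#' @slot voxelSize grid spacing (dx, dy, dz).
#' @slot seed RNG seed making the render reproducible.
#' @export
setClass("SceneParams",
  representation(
    tCellCenter = "numeric", tCellRadius = "numeric",
    apcCenter = "numeric", apcRadius = "numeric",
    mtocTrue = "numeric",
    mvbCount = "integer", mvbSpread = "numeric", mvbCenterTrue = "numeric",
    actinShellThickness = "numeric",
    clearanceFractionTrue = "numeric",
    snr = "numeric",
    psfSigma = "numeric",
    voxelSize = "numeric",
    seed = "integer"
  )
)

setValidity("SceneParams", function(object) {
  p3 <- function(x) length(x) == 3L && all(is.finite(x))
  if (!p3(object@tCellCenter) || !p3(object@apcCenter) ||
      !p3(object@mtocTrue) || !p3(object@mvbCenterTrue))
    return("centres must be finite (x, y, z) triples in um")
  if (object@tCellRadius <= 0 || object@apcRadius <= 0)
    return("radii must be > 0")
  if (object@mvbSpread <= 0 || object@actinShellThickness <= 0)
    return("mvbSpread and actinShellThickness must be > 0")
  if (object@mvbCount < 1L)
    return("mvbCount must be >= 1")
  f <- object@clearanceFractionTrue
  if (!is.finite(f) || f < 0 || f > 1)
    return("clearanceFractionTrue must lie in [0, 1]")
  if (object@snr <= 0)
    return("snr must be > 0 (may be Inf)")
  if (length(object@psfSigma) != 3L || any(object@psfSigma < 0))
    return("psfSigma must be three non-negative sigmas (um)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive spacings (um)")
  d <- sqrt(sum((object@tCellCenter - object@apcCenter)^2))
  if (d > object@tCellRadius + object@apcRadius + 1e-9)
    return("no contact: cells must overlap or touch")
  if (sqrt(sum((object@mtocTrue - object@tCellCenter)^2)) >
      object@tCellRadius)
    return("mtocTrue must lie inside the T-cell sphere")
  if (sqrt(sum((object@mvbCenterTrue - object@tCellCenter)^2)) >
      object@tCellRadius)
    return("mvbCenterTrue must lie inside the T-cell sphere")
  TRUE
})

#' GroundTruth: the simulator's true geometry and polarization indices
#'
#' @slot params the \code{SceneParams} used.
#' @slot piTrueMtoc,piTrueMvb analytic signed polarization indices computed
#'   with \code{\link{polarizationIndex}} (shared code path) from the true
#'   cell centroid (centroid of the truncated T-cell sphere), the true
#'   synapse point and the organelle centres. The MVB value uses the centre
#'   of mass of the puncta actually rendered.
#' @slot synapsePointTrue centre of the contact disc (x, y, z) in um.
#' @slot cellCentroidTrue analytic centroid of the truncated T-cell body.
#' @slot mvbComTrue centre of mass of the realized MVB puncta.
#' @export
setClass("GroundTruth",
  representation(
    params = "SceneParams",
    piTrueMtoc = "numeric",
    piTrueMvb = "numeric",
    synapsePointTrue = "numeric",
    cellCentroidTrue = "numeric",
    mvbComTrue = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  if (abs(object@piTrueMtoc) > 1 + 1e-6 || abs(object@piTrueMvb) > 1 + 1e-6)
    return("true polarization indices must lie in [-1, 1]")
  TRUE
})

#' ConjugateSegmentation: masks and landmarks for one T-cell/APC pair
#'
#' @slot tCellMask,apcMask disjoint logical voxel masks (x, y, z).
#' @slot mvbMask logical voxel mask of supra-threshold MVB signal.
#' @slot cellCentroid geometric centre of the T-cell mask (um).
#' @slot synapsePoint centroid of the contact interface (um).
#' @slot mtocCenter,mvbCenter intensity-weighted organelle centres (um).
#' @export
setClass("ConjugateSegmentation",
  representation(
    tCellMask = "array", apcMask = "array", mvbMask = "array",
    cellCentroid = "numeric", synapsePoint = "numeric",
    mtocCenter = "numeric", mvbCenter = "numeric"
  )
)

setValidity("ConjugateSegmentation", function(object) {
  if (any(object@tCellMask & object@apcMask))
    return("T-cell and APC masks must be disjoint")
  TRUE
})

#' PolarityResult: the signed polarization index for one organelle
#'
#' @slot organelle label ("MTOC", "MVB" or caller-supplied).
#' @slot distanceAB signed projection of the organelle centre onto the
#'   cell-centroid-to-synapse axis, um (the "A" distance for MVB, "B" for
#'   MTOC; negative when opposite the synapse direction).
#' @slot distanceC distance from cell centroid to synapse point, um.
#' @slot pi signed polarization index \code{distanceAB / distanceC};
#'   +1 fully polarized, -1 fully anti-polarized. Not clamped: values
#'   outside [-1, 1] are flagged, not hidden.
#' @slot axis unit vector of the cell-centroid-to-synapse axis.
#' @slot mode "MIP-2D" (landmarks on the maximum intensity projection,
#'   the measurement default) or "full-3D".
#' @slot flagged TRUE when |pi| > 1 (landmark quality flag).
#' @export
setClass("PolarityResult",
  representation(
    organelle = "character",
    distanceAB = "numeric",
    distanceC = "numeric",
    pi = "numeric",
    axis = "numeric",
    mode = "character",
    flagged = "logical"
  )
)

#' InterfaceResult: en-face synapse view and the F-actin clearance ratio
#'
#' @slot enface 2D (or 2D multi-channel) en-face image, isotropic pixels.
#' @slot pixelSize en-face pixel size, um.
#' @slot isArea total synapse interface area, um^2 (convex region
#'   enclosing supra-threshold F-actin).
#' @slot factinLowArea area of the largest F-actin-low component interior
#'   to the interface, um^2.
#' @slot clearanceRatio \code{factinLowArea / isArea} in [0, 1].
#' @slot threshold intensity threshold applied to the F-actin channel.
#' @slot thresholdMethod "otsu" or "manual".
#' @slot isMask,lowMask pixel masks of the interface and the low region.
#' @export
setClass("InterfaceResult",
  representation(
    enface = "array",
    pixelSize = "numeric",
    isArea = "numeric",
    factinLowArea = "numeric",
    clearanceRatio = "numeric",
    threshold = "numeric",
    thresholdMethod = "character",
    isMask = "matrix",
    lowMask = "matrix"
  )
)

setValidity("InterfaceResult", function(object) {
  if (object@factinLowArea > object@isArea + 1e-9)
    return("factinLowArea must not exceed isArea")
  r <- object@clearanceRatio
  if (!is.finite(r) || r < 0 || r > 1 + 1e-9)
    return("clearanceRatio must lie in [0, 1]")
  TRUE
})

#' ColocResult: pixel-intensity colocalization metrics
#'
#' @slot pearson Pearson correlation over the analysis region (unthresholded,
#'   NA when a channel has zero variance).
#' @slot m1 Manders M1: fraction of channel-A intensity on B-positive pixels.
#' @slot m2 Manders M2: fraction of channel-B intensity on A-positive pixels.
#' @slot colocMask jointly supra-threshold pixels within the region.
#' @slot thresholds per-channel thresholds used for Manders/the mask.
#' @slot thresholdMethod "otsu", "costes" or "manual".
#' @export
setClass("ColocResult",
  representation(
    pearson = "numeric",
    m1 = "numeric",
    m2 = "numeric",
    colocMask = "matrix",
    thresholds = "numeric",
    thresholdMethod = "character"
  )
)

setValidity("ColocResult", function(object) {
  ok <- function(x, lo, hi) !is.finite(x) || (x >= lo - 1e-12 && x <= hi + 1e-12)
  if (!ok(object@pearson, -1, 1)) return("pearson must lie in [-1, 1]")
  if (!ok(object@m1, 0, 1) || !ok(object@m2, 0, 1))
    return("Manders coefficients must lie in [0, 1]")
  TRUE
})

#' IntensityProfile: per-channel MFI along a line
#'
#' @slot positions um along the line, strictly increasing.
#' @slot values matrix (position x channel) of band-averaged intensities.
#' @slot channelNames channel labels.
#' @export
setClass("IntensityProfile",
  representation(
    positions = "numeric",
    values = "matrix",
    channelNames = "character"
  )
)

setValidity("IntensityProfile", function(object) {
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  if (nrow(object@values) != length(object@positions))
    return("one row of values per position required")
  TRUE
})

#' RoiTrack: a floating region of interest over a time-lapse
#'
#' One geometry per frame (the ROI may change position frame to frame).
#' Each geometry is either a disc \code{list(center = c(x, y), radius = r)}
#' or a polygon \code{list(poly = <n x 2 matrix>)}, in pixel units.
#'
#' @slot rois list, one geometry per frame.
#' @slot label "cell" or "IS" (or caller-supplied).
#' @export
setClass("RoiTrack",
  representation(rois = "list", label = "character")
)

setValidity("RoiTrack", function(object) {
  for (r in object@rois) {
    if (!is.null(r$radius) && r$radius <= 0)
      return("ROI radius must be > 0 in every frame")
    if (!is.null(r$poly) && nrow(r$poly) < 3)
      return("polygon ROIs need >= 3 vertices")
    if (is.null(r$radius) && is.null(r$poly))
      return("each ROI must be a disc (center, radius) or polygon (poly)")
  }
  TRUE
})

#' AccumulationKinetics: programmed reporter accumulation at the synapse
#'
#' @slot onset time (s) at which reporter enrichment at the IS begins.
#' @slot duration length (s) of the enrichment plateau.
#' @slot fold multiplicative enrichment of the reporter inside the IS ROI
#'   during the plateau (1 = no accumulation).
#' @export
setClass("AccumulationKinetics",
  representation(onset = "numeric", duration = "numeric", fold = "numeric")
)

setValidity("AccumulationKinetics", function(object) {
  if (object@onset < 0 || object@duration < 0)
    return("onset and duration must be >= 0")
  if (object@fold < 1)
    return("fold must be >= 1")
  TRUE
})

#' AccumulationResult: duration of reporter accumulation at the IS
#'
#' @slot onsetTime,offsetTime,duration seconds; duration = offset - onset,
#'   0 when enrichment never crosses the detection threshold.
#' @slot peakEnrichment maximum IS-ROI MFI / cell-ROI MFI.
#' @slot enrichmentSeries per-frame enrichment ratio.
#' @slot timestamps frame times, s.
#' @export
setClass("AccumulationResult",
  representation(
    onsetTime = "numeric", offsetTime = "numeric", duration = "numeric",
    peakEnrichment = "numeric", enrichmentSeries = "numeric",
    timestamps = "numeric"
  )
)

setValidity("AccumulationResult", function(object) {
  if (object@offsetTime < object@onsetTime)
    return("offsetTime must be >= onsetTime")
  if (abs(object@duration - (object@offsetTime - object@onsetTime)) > 1e-9)
    return("duration must equal offsetTime - onsetTime")
  TRUE
})
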