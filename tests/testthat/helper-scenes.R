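# Shared fixtures: simulated scenes are expensive, so batches are built
# lazily once per test run and reused across test files.

# Test scenes run on a 0.25 um lateral grid (the generator's voxelSize
# parameter); the axial step stays at the default 0.35 um.
testVox <- c(0.25, 0.25, 0.35)

.sceneCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sceneCache)) {
    assign(key, force(expr), envir = .sceneCache)
  }
  get(key, envir = .sceneCache)
}

# 30 polarized (true MTOC PI in [0.6, 0.9]) + 30 unpolarized conjugates
# at SNR 20, measured with the default MIP-2D pipeline.
polarityBatch <- function() {
  cached("polarityBatch", {
    targets <- c(seq(0.6, 0.9, length.out = 30), rep(0, 30))
    rows <- lapply(seq_along(targets), function(i) {
      pp <- sceneAtPI(targets[i], seed = 1000L + i, mvbJitter = 0.4,
                      voxelSize = testVox)
      sim <- simulateConjugate(pp)
      pr <- polarityFromStack(sim$stack, mode = "MIP-2D")
      data.frame(
        group = if (targets[i] > 0) "polarized" else "unpolarized",
        pi_true_mtoc = sim$truth@piTrueMtoc,
        pi_true_mvb = sim$truth@piTrueMvb,
        pi_mtoc = piValue(pr$mtoc),
        pi_mvb = piValue(pr$mvb)
      )
    })
    do.call(rbind, rows)
  })
}

# A single default polarized conjugate plus its segmentation.
defaultScene <- function() {
  cached("defaultScene", {
    pp <- sceneAtPI(0.7, seed = 3L, mvbJitter = 0.4, voxelSize = testVox)
    sim <- simulateConjugate(pp)
    list(params = pp, stack = sim$stack, truth = sim$truth,
         seg = segmentConjugate(sim$stack))
  })
}

# True (analytic) T-cell body mask of a scene on its rendered grid.
trueTCellMask <- function(params, stack) {
  vs <- unname(voxelSize(stack))
  lo <- pmin(params@tCellCenter - params@tCellRadius,
             params@apcCenter - params@apcRadius) - 1
  tcg <- params@tCellCenter - lo
  acg <- params@apcCenter - lo
  D <- sqrt(sum((params@apcCenter - params@tCellCenter)^2))
  u <- (acg - tcg) / D
  d1 <- (D^2 + params@tCellRadius^2 - params@apcRadius^2) / (2 * D)
  d <- dim(stack@voxels)[1:3]
  xs <- (seq_len(d[1]) - 1) * vs[1]
  ys <- (seq_len(d[2]) - 1) * vs[2]
  zs <- (seq_len(d[3]) - 1) * vs[3]
  d2t <- outer(outer((xs - tcg[1])^2, (ys - tcg[2])^2, "+"),
               (zs - tcg[3])^2, "+")
  proj <- outer(outer((xs - tcg[1]) * u[1], (ys - tcg[2]) * u[2], "+"),
                (zs - tcg[3]) * u[3], "+")
  d2t <= params@tCellRadius^2 & proj <= d1
}

# Simulated movies over a duration grid, measured end to end.
kineticsBatch <- function() {
  cached("kineticsBatch", {
    durations <- seq(120, 600, length.out = 20)  # 2-10 min, includes 378 s scale
    durations[10] <- 378
    rows <- lapply(seq_along(durations), function(i) {
      kin <- AccumulationKinetics(onset = 90, duration = durations[i],
                                  fold = 3)
      tl <- simulateTimelapse(SceneParams(voxelSize = testVox,
                                          seed = 2000L + i),
                              kin, frameInterval = 30, totalTime = 900)
      isS <- roiMfiSeries(tl$timelapse, tl$truth$isTrack, "reporter")
      cS <- roiMfiSeries(tl$timelapse, tl$truth$cellTrack, "reporter")
      res <- accumulationDuration(isS, cS, tl$timelapse@timestamps)
      data.frame(duration_true = durations[i],
                 duration_measured = res@duration)
    })
    do.call(rbind, rows)
  })
}

# Brute-force colocalization oracle: plain pixel loops.
colocOracle <- function(a, b, tA, tB) {
  n <- length(a)
  ma <- mean(a); mb <- mean(b)
  num <- 0; da <- 0; db <- 0
  sa <- 0; sab <- 0; sb <- 0; sba <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
    sa <- sa + a[i]
    sb <- sb + b[i]
    if (b[i] > tB) sab <- sab + a[i]
    if (a[i] > tA) sba <- sba + b[i]
  }
  list(pearson = num / sqrt(da * db), m1 = sab / sa, m2 = sba / sb)
}
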