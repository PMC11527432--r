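test_that("identical parameters and seed give a bit-identical render", {
  pp <- SceneParams(voxelSize = testVox, seed = 11L)
  a <- simulateConjugate(pp)
  b <- simulateConjugate(pp)
  expect_identical(a$stack@voxels, b$stack@voxels)
  expect_identical(a$truth@piTrueMvb, b$truth@piTrueMvb)
})

test_that("disjoint cells are rejected", {
  expect_error(SceneParams(tCellCenter = c(5, 9, 6), apcCenter = c(30, 9, 6),
                           voxelSize = testVox),
               "no contact")
})

test_that("analytic ground-truth PI matches the volumetric measurement on a clean render", {
  pp <- sceneAtPI(0.65, seed = 21L, voxelSize = testVox,
                  snr = Inf, psfSigma = c(0, 0, 0))
  sim <- simulateConjugate(pp)
  pr <- polarityFromStack(sim$stack, mode = "full-3D")
  halfDiag <- sqrt(sum(testVox^2)) / 2
  C <- pr$mtoc@distanceC
  expect_lt(abs(piValue(pr$mtoc) - sim$truth@piTrueMtoc), halfDiag / C)
  expect_lt(abs(piValue(pr$mvb) - sim$truth@piTrueMvb), 3 * halfDiag / C)
})

test_that("an MTOC at the contact point measures fully polarized in the clean limit", {
  base <- SceneParams(voxelSize = testVox, seed = 31L,
                      snr = Inf, psfSigma = c(0, 0, 0))
  geom <- synapseQuant:::sceneGeometry(base)
  mtoc <- geom$synapsePoint - 0.15 * geom$u   # just inside the cell
  pp <- SceneParams(voxelSize = testVox, seed = 31L, snr = Inf,
                    psfSigma = c(0, 0, 0), mtocTrue = mtoc,
                    mvbCenterTrue = mtoc - 0.8 * geom$u)
  sim <- simulateConjugate(pp)
  pr <- polarityFromStack(sim$stack, mode = "full-3D")
  expect_gt(piValue(pr$mtoc), 0.9)
  expect_lt(piValue(pr$mtoc), 1 + 0.05)
})

test_that("higher SNR means better PI recovery (paired scenes)", {
  maeAt <- function(snr) {
    errs <- vapply(1:20, function(i) {
      pp <- sceneAtPI(0.5, seed = 400L + i, voxelSize = testVox, snr = snr)
      sim <- simulateConjugate(pp)
      pr <- polarityFromStack(sim$stack, mode = "MIP-2D")
      abs(piValue(pr$mtoc) - sim$truth@piTrueMtoc)
    }, numeric(1))
    mean(errs)
  }
  m <- c(maeAt(5), maeAt(8), maeAt(12))
  expect_lt(m[2], m[1])
  expect_lt(m[3], m[2])
})

test_that("ground-truth tables collect one row per scene", {
  sims <- lapply(1:2, function(i)
    simulateConjugate(SceneParams(voxelSize = testVox, seed = i))$truth)
  tab <- groundTruthTable(sims)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("pi_true_mtoc", "pi_true_mvb",
                    "clearance_fraction_true") %in% names(tab)))
  expect_true(all(abs(tab$pi_true_mtoc) <= 1))
})

test_that("time-lapse simulator honours its kinetics contract", {
  pp <- SceneParams(voxelSize = testVox, seed = 8L)
  kin <- AccumulationKinetics(onset = 120, duration = 300, fold = 3)
  expect_error(simulateTimelapse(pp, kin, frameInterval = 0), "> 0")
  a <- simulateTimelapse(pp, kin, frameInterval = 30, totalTime = 600)
  b <- simulateTimelapse(pp, kin, frameInterval = 30, totalTime = 600)
  expect_identical(a$timelapse@frames, b$timelapse@frames)
  expect_equal(a$truth$durationTrue, 300)
  # no accumulation programmed -> zero recovered duration
  flat <- simulateTimelapse(pp, AccumulationKinetics(fold = 1),
                            frameInterval = 30, totalTime = 600)
  isS <- roiMfiSeries(flat$timelapse, flat$truth$isTrack, "reporter")
  cS <- roiMfiSeries(flat$timelapse, flat$truth$cellTrack, "reporter")
  res <- accumulationDuration(isS, cS, flat$timelapse@timestamps)
  expect_equal(res@duration, 0)
  expect_equal(flat$truth$durationTrue, 0)
})
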