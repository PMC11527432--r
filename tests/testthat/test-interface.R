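renderAnnulus <- function(rIn = 3, rOut = 6, px = 0.1, pad = 1) {
  n <- as.integer(2 * (rOut + pad) / px) + 1L
  ctr <- (n - 1) / 2
  g <- rep(seq_len(n) - 1, n)
  h <- rep(seq_len(n) - 1, each = n)
  d <- sqrt((g - ctr)^2 + (h - ctr)^2) * px
  img <- matrix(as.numeric(d >= rIn & d <= rOut), n, n)
  attr(img, "pixelSize") <- px
  img
}

test_that("a noiseless annulus measures its analytic area ratio", {
  r <- clearanceRatio(renderAnnulus(3, 6))
  expect_equal(r@clearanceRatio, 0.25, tolerance = 0.02)
  expect_lte(r@factinLowArea, r@isArea)
})

test_that("a uniform disc has no clearance and empty images error", {
  disc <- renderAnnulus(0, 5)
  expect_equal(clearanceRatio(disc)@clearanceRatio, 0)
  blank <- matrix(0, 32, 32)
  attr(blank, "pixelSize") <- 0.1
  expect_error(clearanceRatio(blank), "no IS detected")
})

test_that("relative thresholding makes the ratio gain-invariant", {
  img <- renderAnnulus(2, 5) * 137.5
  attr(img, "pixelSize") <- 0.1
  a <- clearanceRatio(img)
  b <- clearanceRatio(img * 13)
  expect_equal(a@clearanceRatio, b@clearanceRatio, tolerance = 1e-9)
})

test_that("en-face reconstruction turns the stack through the contact plane", {
  # a stack bright only in one x-plane: the en-face view along +x is
  # uniformly bright
  v <- array(0, c(30, 24, 12, 1))
  v[15, , , 1] <- 5
  st <- ImageStack(v, c(0.2, 0.2, 0.4), "F-actin")
  ef <- enfaceReconstruct(st, "F-actin", c(14 * 0.2, 11 * 0.2, 5 * 0.4),
                          axis = c(1, 0, 0), halfSize = 1, slabUm = 0)
  expect_true(all(abs(ef - 5) < 1e-6))
  expect_equal(attr(ef, "pixelSize"), 0.2)
})

test_that("the simulated clearance disc appears dark at the interface centre", {
  pp <- SceneParams(clearanceFractionTrue = 0.5, seed = 61L,
                    voxelSize = testVox)
  sim <- simulateConjugate(pp)
  tr <- sim$truth
  ef <- enfaceReconstruct(sim$stack, "F-actin", tr@synapsePointTrue,
                          tr@synapsePointTrue - tr@cellCentroidTrue,
                          halfSize = 4, slabUm = 0.4)
  n <- nrow(ef)
  ctr <- (n + 1) / 2
  centreMean <- mean(ef[(ctr - 3):(ctr + 3), (ctr - 3):(ctr + 3)])
  ringMean <- mean(ef[ef > quantile(ef, 0.95)])
  expect_lt(centreMean, 0.4 * ringMean)
})

test_that("manual and automatic thresholds give similar clearance ratios", {
  pp <- SceneParams(clearanceFractionTrue = 0.4, seed = 71L,
                    voxelSize = testVox)
  sim <- simulateConjugate(pp)
  auto <- interfaceQuantify(sim$stack)
  manual <- interfaceQuantify(sim$stack, thresholdMethod = "manual",
                              threshold = auto@threshold * 1.1)
  expect_lt(abs(auto@clearanceRatio - manual@clearanceRatio), 0.05)
  expect_equal(auto@thresholdMethod, "midlevel")
  expect_equal(manual@thresholdMethod, "manual")
})
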