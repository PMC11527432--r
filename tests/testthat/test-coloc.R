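test_that("colocalization limits are exact", {
  set.seed(3)
  a <- matrix(runif(64, 0.2, 1), 8)
  same <- colocMetrics(a, a, thresholdMethod = "manual",
                       thresholds = c(0.1, 0.1))
  expect_equal(same@pearson, 1)
  expect_equal(same@m1, 1)
  expect_equal(same@m2, 1)
  inv <- colocMetrics(a, max(a) - a)
  expect_equal(inv@pearson, -1)
  # disjoint supports
  l <- matrix(0, 8, 8); l[1:4, ] <- 1
  r <- matrix(0, 8, 8); r[5:8, ] <- 1
  dj <- colocMetrics(l, r, thresholdMethod = "manual",
                     thresholds = c(0.5, 0.5))
  expect_equal(dj@m1, 0)
  expect_equal(dj@m2, 0)
  # zero variance -> Pearson undefined with a reason
  z <- colocMetrics(matrix(1, 4, 4), matrix(runif(16), 4))
  expect_true(is.na(z@pearson))
})

test_that("metrics equal a brute-force pixel loop on small images", {
  set.seed(17)
  for (i in 1:6) {
    a <- matrix(runif(256), 16)
    b <- matrix(pmax(0, 0.6 * a + rnorm(256, 0, 0.2)), 16)
    th <- c(0.5, 0.3)
    got <- colocMetrics(a, b, thresholdMethod = "manual", thresholds = th)
    want <- colocOracle(as.vector(a), as.vector(b), th[1], th[2])
    expect_equal(got@pearson, want$pearson, tolerance = 1e-10)
    expect_equal(got@m1, want$m1, tolerance = 1e-10)
    expect_equal(got@m2, want$m2, tolerance = 1e-10)
  }
})

test_that("Pearson is invariant to affine gain; Manders M1 grows as tB drops", {
  set.seed(5)
  a <- matrix(runif(144), 12)
  b <- matrix(runif(144), 12)
  base <- colocMetrics(a, b)
  gained <- colocMetrics(a * 3 + 0.7, b)
  expect_equal(base@pearson, gained@pearson, tolerance = 1e-12)
  m1s <- vapply(seq(0.9, 0.1, by = -0.2), function(tb)
    colocMetrics(a, b, thresholdMethod = "manual",
                 thresholds = c(0.5, tb))@m1, numeric(1))
  expect_true(all(diff(m1s) >= 0))
})

test_that("RGB recoding of the overlay never changes the metrics", {
  sc <- defaultScene()
  seg <- sc$seg
  out <- interfaceColocalization(sc$stack, "MVB", "F-actin",
                                 seg@synapsePoint,
                                 seg@synapsePoint - seg@cellCentroid)
  raw <- colocMetrics(out$enfaceA, out$enfaceB)
  expect_equal(out$result@pearson, raw@pearson)
  expect_equal(out$result@m1, raw@m1)
  expect_true(all(dim(out$overlay)[3] == 3))
  expect_true(all(out$overlay >= 0 & out$overlay <= 1))
  # overlay is white exactly on the joint supra-threshold mask
  white <- out$overlay[, , 1] == 1 & out$overlay[, , 2] == 1 &
    out$overlay[, , 3] == 1
  expect_true(all(white[out$result@colocMask]))
})

test_that("MFI profiles resolve plateaus and reject degenerate lines", {
  img <- matrix(1.5, 40, 40)
  flat <- mfiProfile(img, c(2, 20), c(37, 20))
  expect_true(all(abs(flat@values - 1.5) < 1e-9))
  stripe <- matrix(0, 40, 40)
  stripe[18:23, ] <- 4
  prof <- mfiProfile(stripe, c(2, 20), c(37, 20), width = 3)
  plateau <- sum(prof@values[, 1] > 2)
  expect_lt(abs(plateau - 6), 2)
  expect_error(mfiProfile(img, c(5, 5), c(5, 5)), "zero-length")
  expect_error(mfiProfile(img, c(-3, 5), c(10, 5)), "outside")
  # trough between the two cortical peaks of a cleared interface
  pp <- SceneParams(clearanceFractionTrue = 0.5, seed = 81L,
                    voxelSize = testVox)
  sim <- simulateConjugate(pp)
  tr <- sim$truth
  ef <- enfaceReconstruct(sim$stack, "F-actin", tr@synapsePointTrue,
                          tr@synapsePointTrue - tr@cellCentroidTrue,
                          halfSize = 4, slabUm = 0.4)
  n <- nrow(ef)
  mid <- (n - 1) / 2
  p <- mfiProfile(ef, c(0, mid), c(n - 1, mid),
                  pixelSize = attr(ef, "pixelSize"))
  vals <- p@values[, 1]
  ctrIdx <- which.min(abs(p@positions - max(p@positions) / 2))
  centre <- mean(vals[(ctrIdx - 2):(ctrIdx + 2)])
  expect_lt(centre, 0.5 * max(vals))
  peaks <- range(which(vals > 0.8 * max(vals)))
  expect_true(peaks[1] < ctrIdx && peaks[2] > ctrIdx)
})
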