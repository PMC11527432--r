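test_that("polarization index reproduces the defining geometry", {
  expect_equal(piValue(polarizationIndex(c(0, 0, 0), c(10, 0, 0),
                                         c(10, 0, 0))), 1)
  expect_equal(piValue(polarizationIndex(c(0, 0, 0), c(-10, 0, 0),
                                         c(10, 0, 0))), -1)
  expect_equal(piValue(polarizationIndex(c(0, 0, 0), c(5, 5, 0),
                                         c(10, 0, 0))), 0.5)
  # invariant under uniform scaling of all coordinates
  expect_equal(piValue(polarizationIndex(c(0, 0, 0) * 2, c(5, 5, 0) * 2,
                                         c(10, 0, 0) * 2)), 0.5)
  expect_error(polarizationIndex(c(1, 2, 3), c(0, 0, 0), c(1, 2, 3)),
               "degenerate axis")
})

test_that("PI agrees with a coordinate-geometry oracle and its symmetries", {
  set.seed(11)
  for (i in 1:50) {
    cc <- rnorm(3, 0, 3)
    syn <- cc + rnorm(3, 0, 4)
    m <- cc + rnorm(3, 0, 2)
    if (sqrt(sum((syn - cc)^2)) < 1e-3) next
    r <- polarizationIndex(cc, m, syn)
    # oracle: explicit projection-point construction
    u <- (syn - cc) / sqrt(sum((syn - cc)^2))
    projPoint <- cc + sum((m - cc) * u) * u
    signedAB <- sqrt(sum((projPoint - cc)^2)) * sign(sum((m - cc) * u))
    expect_equal(piValue(r), signedAB / sqrt(sum((syn - cc)^2)),
                 tolerance = 1e-9)
    # rotation invariance under one rigid rotation of all landmarks
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rz %*% Rx
    rot <- polarizationIndex(drop(R %*% cc), drop(R %*% m),
                             drop(R %*% syn))
    expect_equal(piValue(rot), piValue(r), tolerance = 1e-9)
    # antisymmetry: reflecting the mass centre through the cell centre
    refl <- polarizationIndex(cc, 2 * cc - m, syn)
    expect_equal(piValue(refl), -piValue(r), tolerance = 1e-9)
  }
})

test_that("out-of-range PI values are reported and flagged, not clamped", {
  r <- polarizationIndex(c(0, 0, 0), c(30, 0, 0), c(10, 0, 0))
  expect_equal(piValue(r), 3)
  expect_true(r@flagged)
  expect_false(polarizationIndex(c(0, 0, 0), c(5, 0, 0),
                                 c(10, 0, 0))@flagged)
})

test_that("stack-level PI recovers the simulator truth in both modes", {
  pp <- sceneAtPI(0.65, seed = 41L, voxelSize = testVox, snr = Inf)
  sim <- simulateConjugate(pp)
  mip <- polarityFromStack(sim$stack, mode = "MIP-2D")
  expect_lt(abs(piValue(mip$mtoc) - sim$truth@piTrueMtoc), 0.05)
  expect_equal(mip$mtoc@mode, "MIP-2D")
  # organelle on the contact axis: flattening preserves the projection
  full <- polarityFromStack(sim$stack, mode = "full-3D")
  expect_lt(abs(piValue(full$mtoc) - piValue(mip$mtoc)), 0.02)
  # unpolarized scene scores near zero
  pp0 <- sceneAtPI(0, seed = 43L, voxelSize = testVox)
  sim0 <- simulateConjugate(pp0)
  mip0 <- polarityFromStack(sim0$stack, mode = "MIP-2D")
  expect_lt(abs(piValue(mip0$mtoc)), 0.1)
})

test_that("MVB-MTOC coupling handles exact, degenerate and jittered input", {
  r <- mvbMtocCoupling(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(r$pearson_r, 1)
  const <- mvbMtocCoupling(c(0.3, 0.3, 0.3), c(0.1, 0.5, 0.9))
  expect_true(is.na(const$pearson_r))
  expect_match(attr(const$pearson_r, "reason"), "zero variance")
  expect_error(mvbMtocCoupling(c(0.1, 0.2), c(0.1, 0.2)), ">= 3")
  centers <- matrix(rnorm(9), 3)
  withDist <- mvbMtocCoupling(c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.8),
                              centers, centers + 0.1)
  expect_equal(withDist$center_distance_mean_um, sqrt(3 * 0.01),
               tolerance = 1e-9)
})
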