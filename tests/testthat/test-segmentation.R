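# Analytic two-sphere phantom: solid spheres, no noise, no blur.
phantomStack <- function(c1, r1, c2, r2, vox = c(0.25, 0.25, 0.35),
                         margin = 1) {
  lo <- pmin(c1 - r1, c2 - r2) - margin
  hi <- pmax(c1 + r1, c2 + r2) + margin
  n <- as.integer(ceiling((hi - lo) / vox)) + 1L
  xs <- (seq_len(n[1]) - 1) * vox[1] + lo[1]
  ys <- (seq_len(n[2]) - 1) * vox[2] + lo[2]
  zs <- (seq_len(n[3]) - 1) * vox[3] + lo[3]
  dist2 <- function(p) outer(outer((xs - p[1])^2, (ys - p[2])^2, "+"),
                             (zs - p[3])^2, "+")
  cell <- (dist2(c1) <= r1^2) * 1
  apc <- (dist2(c2) <= r2^2) * 1
  v <- array(0, c(n, 2L))
  v[, , , 1] <- apc
  v[, , , 2] <- cell
  list(stack = ImageStack(v, vox, c("APC", "F-actin")), origin = lo)
}

test_that("two-sphere phantom centroids are recovered within one voxel", {
  ph <- phantomStack(c(6, 8, 6), 4, c(14, 8, 6), 4.5)
  masks <- segmentCells(ph$stack)
  vs <- unname(voxelSize(ph$stack))
  cen <- synapseQuant:::maskCentroid(masks$tCellMask, vs)
  expect_lt(max(abs(cen - (c(6, 8, 6) - ph$origin))), max(vs))
  cenA <- synapseQuant:::maskCentroid(masks$apcMask, vs)
  expect_lt(max(abs(cenA - (c(14, 8, 6) - ph$origin))), max(vs))
  expect_false(any(masks$tCellMask & masks$apcMask))
})

test_that("tangent spheres meet at the tangency point; separated spheres do not", {
  ph <- phantomStack(c(6, 8, 6), 4, c(14, 8, 6), 4)  # tangent at x = 10
  masks <- segmentCells(ph$stack)
  vs <- unname(voxelSize(ph$stack))
  syn <- detectSynapsePoint(masks$tCellMask, masks$apcMask, vs)
  expect_lt(max(abs(syn - (c(10, 8, 6) - ph$origin))), 2 * max(vs))
  far <- phantomStack(c(6, 8, 6), 3, c(16, 8, 6), 3)
  fm <- segmentCells(far$stack)
  expect_error(detectSynapsePoint(fm$tCellMask, fm$apcMask, vs),
               "no contact")
})

test_that("a blank stack yields a clear segmentation error", {
  st <- ImageStack(array(0, c(12, 12, 4, 2)), c(0.25, 0.25, 0.35),
                   c("APC", "F-actin"))
  expect_error(segmentCells(st), "cell not found")
})

test_that("simulated conjugates segment accurately at SNR 20", {
  sc <- defaultScene()
  trueT <- trueTCellMask(sc$params, sc$stack)
  expect_gte(synapseQuant:::jaccard(trueT, sc$seg@tCellMask), 0.8)
  err <- abs(sc$seg@synapsePoint - sc$truth@synapsePointTrue)
  expect_true(all(err <= 3 * unname(voxelSize(sc$stack))))
})

test_that("center of mass matches hand-computed values and a brute-force loop", {
  v <- array(0, c(20, 6, 4))
  st1 <- ImageStack(array(v, c(dim(v), 1)), c(1, 1, 1), "c")
  # single bright voxel
  v1 <- v; v1[5, 3, 2] <- 9
  st1@voxels[, , , 1] <- v1
  expect_equal(centerOfMass(st1, "c"), c(4, 2, 1))
  # intensities 1 and 3 at x = 0 and 4 um -> weighted mean x = 3 um
  v2 <- v; v2[1, 2, 2] <- 1; v2[5, 2, 2] <- 3
  st2 <- ImageStack(array(v2, c(dim(v), 1)), c(1, 1, 1), "c")
  expect_equal(centerOfMass(st2, "c")[1], 3)
  # uniform sphere -> its centre
  xs <- seq_len(20) - 1; ys <- seq_len(6) - 1; zs <- seq_len(4) - 1
  d2 <- outer(outer((xs - 9)^2, (ys - 2)^2, "+"), (zs - 1.5)^2, "+")
  v3 <- (d2 <= 4) * 1
  st3 <- ImageStack(array(v3, c(dim(v), 1)), c(1, 1, 1), "c")
  expect_equal(centerOfMass(st3, "c"), c(9, 2, 1.5), tolerance = 1e-9)
  # brute-force oracle with background subtraction and mask
  set.seed(7)
  v4 <- array(runif(20 * 6 * 4), c(20, 6, 4))
  mask <- d2 <= 6
  st4 <- ImageStack(array(v4, c(dim(v4), 1)), c(0.5, 0.5, 0.5), "c")
  got <- centerOfMass(st4, "c", mask)
  bg <- median(v4[!mask])
  num <- c(0, 0, 0); den <- 0
  for (i in 1:20) for (j in 1:6) for (k in 1:4) {
    if (!mask[i, j, k]) next
    w <- max(v4[i, j, k] - bg, 0)
    num <- num + w * (c(i, j, k) - 1) * 0.5
    den <- den + w
  }
  expect_equal(got, num / den, tolerance = 1e-9)
  # empty weighted mass
  expect_error(centerOfMass(st1, "c", array(FALSE, dim(v))), "empty")
})

test_that("landmarks are translation-equivariant under whole-voxel shifts", {
  sc <- defaultScene()
  v <- sc$stack@voxels
  d <- dim(v)
  shift <- c(4L, 3L, 0L)
  v2 <- array(0, d)
  v2[(1 + shift[1]):d[1], (1 + shift[2]):d[2], , ] <-
    v[1:(d[1] - shift[1]), 1:(d[2] - shift[2]), , ]
  st2 <- ImageStack(v2, unname(voxelSize(sc$stack)), channelNames(sc$stack))
  seg2 <- segmentConjugate(st2)
  offs <- shift * unname(voxelSize(sc$stack))
  expect_equal(seg2@mtocCenter, sc$seg@mtocCenter + offs, tolerance = 0.05)
  expect_equal(seg2@synapsePoint, sc$seg@synapsePoint + offs,
               tolerance = 0.15)
})
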