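test_that("ROI MFI series have the obvious limits", {
  f <- array(2.5, c(10, 10, 1, 4))
  tl <- TimeLapse(f, c(0, 30, 60, 90), channelNames = "reporter")
  tr <- staticRoiTrack(c(4, 4), 2, 4)
  expect_equal(roiMfiSeries(tl, tr, "reporter"), rep(2.5, 4))
  # a one-pixel ROI is that pixel's trace
  f2 <- f
  f2[3, 5, 1, ] <- c(1, 2, 3, 4)
  tl2 <- TimeLapse(f2, c(0, 30, 60, 90), channelNames = "reporter")
  one <- staticRoiTrack(c(2, 4), 0.4, 4)
  expect_equal(roiMfiSeries(tl2, one, "reporter"), c(1, 2, 3, 4))
  # ROI off the frame errors
  out <- staticRoiTrack(c(50, 50), 1, 4)
  expect_error(roiMfiSeries(tl, out, "reporter"), "outside")
  # track must cover every frame
  expect_error(roiMfiSeries(tl, staticRoiTrack(c(4, 4), 2, 3), "reporter"),
               "every frame")
})

test_that("accumulation scoring follows the thresholded-run rule", {
  ts <- (0:30) * 30
  cell <- rep(10, 31)
  # constant at baseline -> zero duration
  none <- accumulationDuration(rep(10, 31), cell, ts)
  expect_equal(none@duration, 0)
  # enrichment 2x baseline on frames 5-17 (0-based) -> 390 s by the
  # midpoint rule, within one frame interval of the programmed 378 s
  isS <- rep(10, 31)
  isS[6:18] <- 20
  r <- accumulationDuration(isS, cell, ts)
  expect_equal(r@duration, 390)
  expect_lt(abs(r@duration - 378), 30 + 1e-9)
  expect_equal(r@peakEnrichment, 2)
  # the rule is invariant to a common intensity gain
  r2 <- accumulationDuration(isS * 7.3, cell * 7.3, ts)
  expect_equal(r2@duration, r@duration)
  expect_error(accumulationDuration(isS, cell, ts, k = 0.8), "k must be")
  expect_error(accumulationDuration(isS[1:4], cell[1:4], ts[1:4]),
               "too short")
})

test_that("programmed movie durations are recovered within one frame interval", {
  kb <- kineticsBatch()
  err <- abs(kb$duration_measured - kb$duration_true)
  expect_lte(mean(err), 30)
  # the 378 s reference magnitude is recovered within one frame
  ref <- kb[kb$duration_true == 378, ]
  expect_lte(abs(ref$duration_measured - 378), 30)
})
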