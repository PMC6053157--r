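test_that("illumination correction is identity on flat frames", {
  fr <- matrix(137.5, 60, 80)
  out <- correctIllumination(fr)
  expect_equal(out, fr, tolerance = 1e-6)
})

test_that("illumination correction flattens a pure ramp", {
  ramp <- matrix(seq(0.8, 1.2, length.out = 120), 80, 120, byrow = TRUE) * 150
  out <- correctIllumination(ramp)
  expect_lt(diff(range(out)) / median(out), 0.01)
})

test_that("a ramp-lit disk segments fully only after correction", {
  H <- 120; W <- 200
  fr <- drawDisk(matrix(200, H, W), 60, 100, 25, 70)
  ramp <- matrix(seq(0.7, 1.3, length.out = W), H, W, byrow = TRUE)
  lit <- fr * ramp
  trueArea <- pi * 25^2 * 0.04
  aCorr <- measureAggregateAreas(
    segmentAggregates(correctIllumination(lit), pixelScale = 0.2), 0.2)
  expect_length(aCorr, 1)
  expect_equal(aCorr, trueArea, tolerance = 0.05)
  aRaw <- measureAggregateAreas(segmentAggregates(lit, pixelScale = 0.2), 0.2)
  ## without correction the global threshold mis-segments the scene
  ## (missing the object entirely or measuring it badly)
  expect_true(length(aRaw) == 0 ||
                max(abs(aRaw - trueArea)) / trueArea > 0.25)
})

test_that("segmentation handles blank frames and resolves disjoint objects", {
  blank <- matrix(200, 60, 60)
  m <- segmentAggregates(blank, pixelScale = 0.2)
  expect_equal(max(m@labels), 0)
  expect_length(measureAggregateAreas(m, 0.2), 0)
  two <- drawDisk(drawDisk(matrix(200, 80, 160), 40, 40, 15, 70),
                  40, 120, 20, 70)
  m2 <- segmentAggregates(two, pixelScale = 0.2)
  expect_equal(max(m2@labels), 2)
  a2 <- measureAggregateAreas(m2, 0.2)
  expect_equal(sort(a2), sort(c(pi * 15^2, pi * 20^2) * 0.04),
               tolerance = 0.05)
})

test_that("area measurement is exactly quadratic in the pixel scale", {
  lab <- matrix(0L, 100, 100)
  lab[1:50, 1:50] <- 1L                    # 2500 px component
  m <- new("AggregateMask", labels = lab)
  expect_equal(measureAggregateAreas(m, 0.2), 100, tolerance = 1e-12)
  expect_equal(measureAggregateAreas(m, 0.4),
               4 * measureAggregateAreas(m, 0.2), tolerance = 1e-12)
  lab2 <- matrix(0L, 300, 300)
  lab2[1:25, 1:20] <- 1L; lab2[30:129, 1:50] <- 2L; lab2[150:299, 1:200] <- 3L
  m2 <- new("AggregateMask", labels = lab2)
  expect_equal(measureAggregateAreas(m2, 0.2), c(500, 5000, 30000) * 0.04)
})

test_that("total measured area is invariant under intensity rescaling", {
  set.seed(4)
  g <- genAggregateFrames(nFrames = 1, seed = 4)
  fr <- g$stack@frames[[1]]
  a1 <- sum(measureAggregateAreas(segmentAggregates(fr, pixelScale = 0.2), 0.2))
  a2 <- sum(measureAggregateAreas(segmentAggregates(3.7 * fr,
                                                    pixelScale = 0.2), 0.2))
  expect_identical(a1, a2)
})

test_that("recording summaries use frame-then-recording averaging", {
  rec <- summarizeRecording(list(c(100, 300), 200))
  expect_equal(rec@perFrameMean, c(200, 200))
  expect_equal(recordingMean(rec), 200)
  single <- summarizeRecording(list(50))
  expect_equal(recordingMean(single), 50)
  expect_equal(single@recordingStderr, 0)
  allEmpty <- summarizeRecording(list(numeric(0), numeric(0)))
  expect_true(is.na(recordingMean(allEmpty)))
  expect_equal(allEmpty@nEmptyFrames, 2)
  mixed <- summarizeRecording(list(numeric(0), c(10, 30)))
  expect_equal(recordingMean(mixed), 20)   # empty frame excluded
  expect_equal(mixed@nEmptyFrames, 1)
})

test_that("size-class binning is half-open and conserves counts", {
  cnt <- classifySizeBins(c(90, 150, 2000), c(0, 100, 500, 1500, 3500, Inf))
  expect_equal(unname(cnt), c(1, 1, 0, 1, 0))
  expect_equal(sum(cnt), 3)
  expect_equal(unname(classifySizeBins(c(100, 500), c(0, 100, 500, Inf))),
               c(0, 1, 1))                 # edges belong to the upper bin
  expect_equal(sum(classifySizeBins(numeric(0))), 0)
  expect_error(classifySizeBins(1, c(5, 2)), class = "rheoflowConfigError")
})

test_that("generated scenes are sized accurately by the detection chain", {
  g <- genAggregateFrames(nFrames = 25, seed = 13)
  rec <- analyzeAggregateStack(g$stack)
  nOK <- 0; errs <- c()
  for (f in seq_along(g$stack@frames)) {
    tr <- sort(g$truth@objects$trueAreaUm2[g$truth@objects$frame == f])
    det <- sort(frameAreas(rec)[[f]])
    if (length(tr) == length(det)) {
      nOK <- nOK + 1
      errs <- c(errs, abs(det - tr) / tr)
    }
  }
  expect_equal(nOK, length(g$stack@frames))   # every count correct
  expect_lt(mean(errs), 0.1)
  ## generator size classes round-trip through the configured bins
  cnt <- classifySizeBins(g$truth@objects$trueAreaUm2)
  expect_equal(sum(cnt), nrow(g$truth@objects))
  expect_equal(as.numeric(cnt),
               as.numeric(table(factor(g$truth@objects$sizeClass,
                                       levels = 1:5))))
})

test_that("recording means are stable across disjoint halves", {
  g <- genAggregateFrames(nFrames = 60, seed = 21)
  rec <- analyzeAggregateStack(g$stack)
  pfm <- rec@perFrameMean
  m1 <- mean(pfm[1:30], na.rm = TRUE)
  m2 <- mean(pfm[31:60], na.rm = TRUE)
  expect_lt(abs(m1 - m2) / mean(c(m1, m2)), 0.15)
})
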