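test_that("generators are fully deterministic under a fixed seed", {
  a <- genParticleFrames(uniformDuctField(1), nPairs = 2, dt = 1,
                         wholeChannel = TRUE, seed = 42)
  b <- genParticleFrames(uniformDuctField(1), nPairs = 2, dt = 1,
                         wholeChannel = TRUE, seed = 42)
  expect_identical(a$pairs[[1]]@frameA, b$pairs[[1]]@frameA)
  expect_identical(a$pairs[[2]]@frameB, b$pairs[[2]]@frameB)
  g1 <- genAggregateFrames(nFrames = 3, seed = 8)
  g2 <- genAggregateFrames(nFrames = 3, seed = 8)
  expect_identical(g1$stack@frames, g2$stack@frames)
  expect_identical(g1$truth@objects, g2$truth@objects)
  g3 <- genAggregateFrames(nFrames = 3, seed = 9)
  expect_false(identical(g1$stack@frames[[1]], g3$stack@frames[[1]]))
})

test_that("viscosity samples are reproducible and carry their provenance", {
  c1 <- genViscositySamples("carreau", tableTwoCarreau$h5, c(0.5, 100),
                            m = 20, noise = "gaussian", noiseSigma = 0.02,
                            seed = 31)
  c2 <- genViscositySamples("carreau", tableTwoCarreau$h5, c(0.5, 100),
                            m = 20, noise = "gaussian", noiseSigma = 0.02,
                            seed = 31)
  expect_identical(viscosities(c1), viscosities(c2))
  expect_equal(c1@meta$seed, 31)
  expect_equal(c1@meta$model, "carreau")
  ## written CSV is byte-identical across repeated generation
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  writeViscosityCurveCSV(c1, p1); writeViscosityCurveCSV(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(genViscositySamples("powerlaw", list(K = 1, n = 1),
                                   c(-1, 10)), class = "rheoflowConfigError")
})

test_that("synthetic co-flow truth is self-consistent with the inversion", {
  sim <- genCoflowExperiment(muRatio = 3, qRatio = 4, qTest = 10,
                             gridShape = c(151, 151))
  ## the solved interface is snapped to the FD grid line, so the realized
  ## pump ratio sits near (not exactly at) the nominal 4
  expect_equal(sim$truth@qRef / sim$truth@qTest, 4, tolerance = 0.03)
  expect_equal(sim$truth@qTest, 10, tolerance = 1e-9)
  prob <- coflowProblem(muRef = sim$truth@muRef, qRef = sim$truth@qRef,
                        qTest = sim$truth@qTest)
  mu <- apparentViscosity(prob, sim$truth@geometry)
  expect_equal(as.numeric(mu), 3, tolerance = 1e-2)
  ## symmetric case
  sym <- genCoflowExperiment(muRatio = 1, qRatio = 1,
                             gridShape = c(101, 101))
  expect_equal(interfaceY(sym$truth), 0, tolerance = 1e-2)
})

test_that("blood flow rates in the microliter range give aggregation-range shear", {
  for (q in c(5, 20, 35)) {
    sim <- genCoflowExperiment(muRatio = 5, qRatio = 4, qTest = q,
                               gridShape = c(101, 101))
    expect_gt(shearRate(sim$truth), 1)
    expect_lt(shearRate(sim$truth), 200)
  }
  ## slower, more viscous blood sits inside the 1-50 1/s band
  slow <- genCoflowExperiment(muRatio = 8, qRatio = 4, qTest = 5,
                              gridShape = c(101, 101))
  expect_gt(shearRate(slow$truth), 1)
  expect_lt(shearRate(slow$truth), 50)
})

test_that("particle pairs follow the field and respect the dt guard", {
  ## zero-velocity field: frames identical up to rendered noise
  gen0 <- genParticleFrames(uniformDuctField(0), nPairs = 1, dt = 1,
                            wholeChannel = TRUE, noiseSigma = 0, seed = 3)
  expect_equal(gen0$pairs[[1]]@frameA, gen0$pairs[[1]]@frameB)
  ## uniform field: every stored truth displacement identical
  genU <- genParticleFrames(uniformDuctField(2), nPairs = 1, dt = 1,
                            wholeChannel = TRUE, seed = 3)
  expect_equal(length(unique(genU$truth$displacement_px)), 1)
  ## displacement beyond the 10 px guard is rejected
  expect_error(genParticleFrames(uniformDuctField(5), nPairs = 1, dt = 10,
                                 wholeChannel = TRUE, seed = 1),
               class = "rheoflowConfigError")
})

test_that("aggregate scenes honour the packing contract", {
  ## zero target coverage produces blank frames and zero detections
  g0 <- genAggregateFrames(nFrames = 2, areaFraction = 0, seed = 5)
  expect_equal(nrow(g0$truth@objects), 0)
  rec0 <- analyzeAggregateStack(g0$stack)
  expect_equal(rec0@nEmptyFrames, 2)
  expect_error(genAggregateFrames(nFrames = 1, areaFraction = 0.6),
               class = "rheoflowConfigError")
})

test_that("three disjoint disks are detected with their analytic areas", {
  set.seed(10)
  H <- 160; W <- 320
  radii <- c(15, 20, 28)
  fr <- matrix(200, H, W)
  fr <- drawDisk(fr, 40, 60, radii[1], 70)
  fr <- drawDisk(fr, 90, 160, radii[2], 70)
  fr <- drawDisk(fr, 60, 260, radii[3], 70)
  fr <- fr + matrix(rnorm(H * W, 0, 4), H, W)
  m <- segmentAggregates(correctIllumination(fr), pixelScale = 0.2)
  a <- sort(measureAggregateAreas(m, 0.2))
  expect_length(a, 3)
  expect_equal(a, sort(pi * radii^2 * 0.04), tolerance = 0.05)
})

test_that("crowded scenes undercount distinct objects (high-hematocrit proxy)", {
  dilute <- genAggregateFrames(nFrames = 4, areaFraction = 0.04, seed = 17)
  crowded <- genAggregateFrames(nFrames = 4, areaFraction = 0.35, seed = 17)
  countRatio <- function(g) {
    rec <- analyzeAggregateStack(g$stack)
    det <- sum(vapply(frameAreas(rec), length, integer(1)))
    det / nrow(g$truth@objects)
  }
  expect_gt(countRatio(dilute), 0.95)
  expect_lt(countRatio(crowded), countRatio(dilute))
})

test_that("truth sidecars serialize the full experiment state", {
  sim <- genCoflowExperiment(muRatio = 2, gridShape = c(101, 101), seed = 12)
  path <- tempfile(fileext = ".json")
  writeTruthSidecar(sim$truth, path)
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(side$mu_test_cP, 2)
  expect_equal(side$geometry$interface_Y, interfaceY(sim$truth))
  expect_equal(side$seed, 12)
  ## FD field CSV round-trips
  pcsv <- tempfile(fileext = ".csv")
  writeDuctFieldCSV(sim$field, pcsv)
  df <- read.csv(pcsv)
  expect_equal(nrow(df), 101 * 101)
  expect_equal(max(df$u_mm_s), max(sim$field@velocity))
})
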