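test_that("background removal zeroes static content and clips at zero", {
  fr <- matrix(5, 8, 8)
  out <- removeBackground(list(fr, fr, fr))
  expect_true(all(vapply(out, function(f) all(f == 0), logical(1))))
  ## adding a constant to every frame changes nothing after removal
  set.seed(1)
  stack <- lapply(1:4, function(i) matrix(runif(64, 0, 10), 8, 8))
  shifted <- lapply(stack, function(f) f + 7)
  expect_equal(removeBackground(stack), removeBackground(shifted))
  expect_error(removeBackground(list(fr)), class = "rheoflowConfigError")
})

test_that("displacement-to-velocity scaling is exact arithmetic", {
  vf <- new("VectorField", gridRow = 1, gridCol = 1,
            dx = matrix(10), dy = matrix(0),
            valid = matrix(TRUE), replaced = matrix(FALSE))
  expect_equal(displacementToVelocity(vf, 2, 0.27)@dx[1, 1], 1.35)
  expect_equal(displacementToVelocity(vf, 15, 0.2)@dx[1, 1] * 10 / 10,
               8 * 0.2 / 15 * 10 / 8, tolerance = 1e-12)
  vf0 <- vf; vf0@dx <- matrix(0)
  expect_equal(displacementToVelocity(vf0, 2, 0.27)@dx[1, 1], 0)
  ## scaling equivariance: dt times c divides velocities by c exactly
  a <- displacementToVelocity(vf, 3, 0.27)@dx
  b <- displacementToVelocity(vf, 6, 0.27)@dx
  expect_equal(a, 2 * b)
})

test_that("profile averaging reproduces the quadratic RMS identities", {
  mk <- function(u) new("VectorField", gridRow = c(10, 20), gridCol = c(10, 20),
                        dx = matrix(u, 2, 2), dy = matrix(0, 2, 2),
                        valid = matrix(TRUE, 2, 2),
                        replaced = matrix(FALSE, 2, 2))
  prof <- temporalAverageProfile(list(mk(1), mk(2), mk(3)))
  expect_equal(prof@u, c(2, 2))
  expect_equal(prof@rms, c(1, 1))       # (3*14 - 36) / (3*2) = 1
  prof2 <- temporalAverageProfile(list(mk(0), mk(2)))
  expect_equal(prof2@rms, c(sqrt(2), sqrt(2)))
  prof3 <- temporalAverageProfile(list(mk(5), mk(5), mk(5)))
  expect_equal(prof3@rms, c(0, 0))
})

test_that("the RMS equals the sample standard deviation on random series", {
  set.seed(7)
  for (rep in 1:5) {
    u <- rnorm(20, 5, 2)
    flds <- lapply(u, function(ui)
      new("VectorField", gridRow = 1, gridCol = 1, dx = matrix(ui),
          dy = matrix(0), valid = matrix(TRUE), replaced = matrix(FALSE)))
    prof <- temporalAverageProfile(flds)
    expect_equal(prof@rms[1], sd(u), tolerance = 1e-12)
  }
  expect_error(temporalAverageProfile(list()), class = "rheoflowConfigError")
})

test_that("identical frames yield zero displacement everywhere", {
  set.seed(3)
  fld <- uniformDuctField(1)
  gen <- genParticleFrames(fld, nPairs = 1, dt = 1e-6, wholeChannel = TRUE,
                           seedingDensity = 0.03, noiseSigma = 0, seed = 3)
  vf <- pivMultipass(gen$pairs[[1]])
  expect_true(all(abs(vf@dx[vf@valid]) < 0.01))
  expect_true(all(abs(vf@dy[vf@valid]) < 0.01))
})

test_that("a uniform 6 px shift is recovered within 0.1 px", {
  fld <- uniformDuctField(1)
  gen <- genParticleFrames(fld, nPairs = 2, dt = 6 * 0.27,
                           wholeChannel = TRUE, seedingDensity = 0.03,
                           seed = 5)
  errs <- unlist(lapply(gen$pairs, function(pr) {
    vf <- pivMultipass(pr)
    vf@dx[vf@valid & !vf@replaced] - 6
  }))
  expect_lt(abs(mean(errs)), 0.05)
  expect_lt(sqrt(mean(errs^2)), 0.1)
})

test_that("a linear shear field's slope is recovered within 5 percent", {
  slope <- 0.03                      # mm/s per um across the width
  fld <- linearShearDuctField(slope)
  gen <- genParticleFrames(fld, nPairs = 3, wholeChannel = TRUE,
                           seedingDensity = 0.04, seed = 9)
  fields <- lapply(gen$pairs, function(pr)
    displacementToVelocity(pivMultipass(pr), gen$dt, gen$pixelScale))
  prof <- temporalAverageProfile(fields, pixelScale = gen$pixelScale)
  sel <- is.finite(prof@u) & prof@y > 10 & prof@y < 100
  fit <- lm(u ~ y, data.frame(y = prof@y[sel], u = prof@u[sel]))
  expect_equal(unname(coef(fit)[2]), slope, tolerance = 0.05)
})

test_that("blood-layer detection finds the seeded band", {
  ## rectangular density: exactly [0, 22] um
  y <- seq(0.5, 109.5, by = 1)
  dens <- as.numeric(y <= 22)
  layer <- detectBloodLayer(dens, y)
  expect_lt(abs(layer[1] - 0.5), 1)
  expect_lt(abs(layer[2] - 22), 1.1)
  ## uniform density covers the full width
  layerU <- detectBloodLayer(rep(1, length(y)), y)
  expect_equal(layerU, c(0.5, 109.5))
  expect_error(detectBloodLayer(c(0, 0, 0, 0), 1:4),
               class = "rheoflowDetectionError")
})

test_that("synthetic blood stream width is recovered from tracer density", {
  sim <- genCoflowExperiment(muRatio = 4, qRatio = 4, qTest = 8,
                             gridShape = c(101, 101))
  gen <- genParticleFrames(sim$field, nPairs = 4, seed = 2)
  dens <- tracerDensityProfile(lapply(gen$pairs, slot, "frameA"))
  yPx <- (seq_along(dens) - 0.5) * gen$pixelScale
  layer <- detectBloodLayer(dens, yPx)
  w2 <- (0.5 + interfaceY(sim$truth)) * 110
  expect_lt(abs(diff(layer) - w2), 4.32)   # within one final-pass grid step
})

test_that("shear-rate estimation matches exact profiles and unit contract", {
  y <- seq(0, 100, by = 2)                 # um
  prof <- new("VelocityProfile", y = y, u = 2e-3 * y,  # u = 2 mm/s per mm
              rms = rep(0, length(y)), nFields = 2)
  est <- estimateShearRate(prof, c(0, 100))
  expect_equal(shearRate(est), 2, tolerance = 1e-10)
  expect_equal(est@rSquared, 1, tolerance = 1e-10)
  profU <- new("VelocityProfile", y = y, u = rep(1.5, length(y)),
               rms = rep(0, length(y)), nFields = 2)
  expect_equal(shearRate(estimateShearRate(profU, c(0, 100))), 0,
               tolerance = 1e-10)
  expect_error(estimateShearRate(prof, c(0, 3)), class = "rheoflowFitError")
})

test_that("mid-plane FD shear matches a direct slope of the FD profile", {
  sim <- genCoflowExperiment(muRatio = 5, qRatio = 4, qTest = 8,
                             gridShape = c(151, 151))
  prof <- midPlaneProfile(sim$field)
  w2 <- (0.5 + interfaceY(sim$field)) * 110
  win <- c(0.1, 0.9) * w2
  sel <- prof@y >= win[1] & prof@y <= win[2]
  direct <- unname(coef(lm(u ~ y, data.frame(y = prof@y[sel],
                                             u = prof@u[sel])))[2]) * 1000
  expect_equal(shearRate(sim$truth), direct, tolerance = 0.05)
})
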