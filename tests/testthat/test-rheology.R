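test_that("power-law viscosity evaluates the constitutive law", {
  expect_equal(powerLawViscosity(c(0.5, 1, 7), K = 3, n = 1), rep(3, 3))
  expect_equal(powerLawViscosity(1, K = 4.2, n = 0.3), 4.2)
  ## 10 percent hematocrit parameters at 10 1/s
  expect_equal(powerLawViscosity(10, K = 50.9, n = 0.156),
               50.9 * 10^(0.156 - 1), tolerance = 1e-12)
  expect_equal(powerLawViscosity(10, K = 50.9, n = 0.156), 7.2898,
               tolerance = 1e-4)
  expect_error(powerLawViscosity(0, 1, 0.5), class = "rheoflowDomainError")
  expect_error(powerLawViscosity(-1, 1, 0.5), class = "rheoflowDomainError")
})

test_that("Carreau viscosity evaluates the constitutive law and limits", {
  expect_equal(carreauViscosity(0, 20, 2, 3, 0.3), 20)      # zero-shear
  expect_equal(carreauViscosity(c(0.1, 10, 500), 7, 7, 3, 0.3), rep(7, 3))
  ## 15 percent hematocrit parameters at 1 1/s
  expect_equal(carreauViscosity(1, 118.6, 2.3, 3.312, 0.362), 54.9836,
               tolerance = 1e-4)
  ## plateau limits for shear-thinning parameters; the approach to the
  ## infinite-shear plateau is algebraic, (lambda*g)^(n-1), so the residual
  ## at finite shear is bounded by exactly that factor
  for (p in tableTwoCarreau) {
    expect_equal(carreauViscosity(1e-8, p["mu0"], p["muInf"], p["lambda"],
                                  p["n"]),
                 unname(p["mu0"]), tolerance = 1e-6, ignore_attr = TRUE)
    resid <- carreauViscosity(1e8, p["mu0"], p["muInf"], p["lambda"],
                              p["n"]) - p[["muInf"]]
    bound <- (p[["mu0"]] - p[["muInf"]]) *
      (p[["lambda"]] * 1e8)^(p[["n"]] - 1)
    expect_gt(resid, 0)
    expect_lt(resid, 1.01 * bound)
    expect_lt(resid / p[["muInf"]], 1e-3)
  }
})

test_that("both models are strictly shear thinning for n < 1", {
  g <- exp(seq(log(0.01), log(1000), length.out = 200))
  expect_true(all(diff(powerLawViscosity(g, 50.9, 0.156)) < 0))
  expect_true(all(diff(carreauViscosity(g, 89.9, 1.6, 3.312, 0.369)) < 0))
})

test_that("goodness of fit reproduces the hand-computed identities", {
  g0 <- goodnessOfFit(c(1, 2, 3), c(1, 2, 3), p = 2)
  expect_equal(g0@rmse, 0)
  expect_equal(g0@rSquared, 1)
  expect_equal(goodnessOfFit(c(1, 2, 3), c(1, 2, 4), p = 2)@rmse, 1)
  expect_equal(goodnessOfFit(c(0, 0, 0), c(1, 1, 1), p = 1)@rmse,
               sqrt(3 / 2))
  ## p = 0 reduces to the population-style residual RMS
  x <- c(1, 4, 2, 8); f <- c(2, 3, 2, 9)
  expect_equal(goodnessOfFit(x, f, p = 0)@rmse,
               sqrt(mean((x - f)^2)))
  expect_error(goodnessOfFit(1:3, 1:3, p = 3), class = "rheoflowDomainError")
  expect_error(goodnessOfFit(1:3, 1:4, p = 1), class = "rheoflowShapeError")
})

test_that("relative viscosity is an exact quotient", {
  expect_equal(relativeViscosity(2.19, 2.19), 1)
  expect_equal(relativeViscosity(4.38, 2.19), 2)
  expect_equal(relativeViscosity(0, 2.19), 0)    # degenerate but allowed
  expect_error(relativeViscosity(1, 0), class = "rheoflowDomainError")
})

test_that("power-law fitting round-trips noiseless model data exactly", {
  cv <- genViscositySamples("powerlaw", list(K = 1, n = 1), c(1, 50), m = 20)
  f <- fitPowerLaw(cv)
  expect_equal(unname(fitParameters(f)), c(1, 1), tolerance = 1e-12)
  for (p in tableOnePowerLaw) {
    cv <- genViscositySamples("powerlaw", as.list(p), c(1, 50), m = 40)
    f <- fitPowerLaw(cv)
    expect_equal(fitParameters(f), p, tolerance = 1e-10)
    expect_equal(f@rSquared, 1, tolerance = 1e-9)
    expect_lt(f@rmse, 1e-9)
  }
})

test_that("power-law fit transforms correctly under shear-rate rescaling", {
  cv <- genViscositySamples("powerlaw", list(K = 12, n = 0.4), c(1, 50),
                            m = 30, noise = "lognormal", noiseSigma = 0.1,
                            seed = 2)
  f1 <- fitPowerLaw(cv)
  c_ <- 3.5
  cv2 <- viscosityCurve(shearRates(cv) * c_, viscosities(cv))
  f2 <- fitPowerLaw(cv2)
  expect_equal(fitParameters(f2)[["n"]], fitParameters(f1)[["n"]],
               tolerance = 1e-9)
  expect_equal(fitParameters(f2)[["K"]],
               fitParameters(f1)[["K"]] *
                 c_^(1 - fitParameters(f1)[["n"]]), tolerance = 1e-9)
})

test_that("noisy power-law fits recover the generator within 5 percent", {
  cv <- genViscositySamples("powerlaw", list(K = 50.9, n = 0.156), c(1, 50),
                            m = 50, noise = "lognormal", noiseSigma = 0.05,
                            seed = 1)
  f <- fitPowerLaw(cv)
  expect_equal(fitParameters(f)[["K"]], 50.9, tolerance = 0.05)
  expect_equal(fitParameters(f)[["n"]], 0.156, tolerance = 0.05)
})

test_that("Carreau fitting round-trips noiseless model data", {
  for (p in tableTwoCarreau) {
    cv <- genViscositySamples("carreau", as.list(p), c(0.5, 100), m = 60)
    f <- fitCarreau(cv)
    expect_equal(fitParameters(f), p, tolerance = 1e-3)
    expect_true(f@converged)
  }
  ## truth initialization is a stationary point
  p <- tableTwoCarreau$h10
  cv <- genViscositySamples("carreau", as.list(p), c(0.5, 100), m = 60)
  f <- fitCarreau(cv, init = as.list(p))
  expect_equal(fitParameters(f), p, tolerance = 1e-6)
})

test_that("noisy Carreau fits recover identifiable parameters", {
  p <- tableTwoCarreau$h15
  cv <- genViscositySamples("carreau", as.list(p), c(0.5, 100), m = 60,
                            noise = "gaussian", noiseSigma = 0.02, seed = 1)
  f <- fitCarreau(cv)
  ## the zero-shear plateau and the index are well constrained by the
  ## sampled window; muInf and lambda live partly outside it and carry
  ## more noise
  expect_equal(fitParameters(f)[["mu0"]], p[["mu0"]], tolerance = 0.1)
  expect_equal(fitParameters(f)[["n"]], p[["n"]], tolerance = 0.1)
  expect_equal(fitParameters(f)[["lambda"]], p[["lambda"]], tolerance = 0.25)
  expect_equal(fitParameters(f)[["muInf"]], p[["muInf"]], tolerance = 0.25)
})

test_that("fixing lambda reduces the degrees of freedom and is honoured", {
  p <- tableTwoCarreau$h5
  cv <- genViscositySamples("carreau", as.list(p), c(0.5, 100), m = 60)
  f <- fitCarreau(cv, fixed = c(lambda = 3.313))
  expect_equal(f@p, 3)
  expect_equal(f@fixed[["lambda"]], 3.313)
  expect_false("lambda" %in% names(fitParameters(f)))
  expect_equal(fitParameters(f)[["mu0"]], p[["mu0"]], tolerance = 1e-3)
})

test_that("fit reports carry warnings for non-thinning or negative index", {
  set.seed(6)
  g <- exp(seq(log(1), log(50), length.out = 12))
  ## shear-thickening data: n > 1 is fine, but a negative index must warn
  cvNeg <- viscosityCurve(g, 5 * g^(-1.2))    # slope -1.2 -> n = -0.2
  f <- fitPowerLaw(cvNeg)
  expect_lt(fitParameters(f)[["n"]], 0)
  expect_true(length(f@warnings) > 0)
  expect_error(fitPowerLaw(viscosityCurve(g[1:2], c(1, 2))),
               class = "rheoflowDomainError")
})

test_that("predictViscosity evaluates the fitted model", {
  p <- tableOnePowerLaw$h10
  cv <- genViscositySamples("powerlaw", as.list(p), c(1, 50), m = 40)
  f <- fitPowerLaw(cv)
  expect_equal(predictViscosity(f, 10),
               powerLawViscosity(10, p[["K"]], p[["n"]]), tolerance = 1e-9)
})
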