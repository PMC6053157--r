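## Two-fluid stratified laminar flow in a rectangular channel.
##
## Model: two immiscible fluids of viscosities mu1 (reference, e.g. PBS) and
## mu2 (test, e.g. blood) flow side by side along x in a channel of width w
## (y direction, y in [-w/2, w/2]) and depth h (z direction), driven by a
## common axial pressure gradient G.  The axial momentum balance
## mu_k * (u_yy + u_zz) = -G holds in each stream, with no-slip walls and
## continuity of velocity and shear stress mu * du/dy at the flat interface
## y = Y * w.  The flow-rate ratio Q1/Q2 then depends only on the viscosity
## ratio mu2/mu1, the interface position Y and the aspect ratio beta = h/w,
## which is what makes the channel usable as a comparator viscometer: with
## the pump-imposed Q1/Q2 and the observed interface, the series can be
## inverted for the unknown test viscosity.
##
## Numerics: each odd Fourier mode cos(n*pi*z/h) across the depth decouples.
## The plane-Poiseuille part (h^2/4 - z^2) * G / (2 mu_k) is split off and
## integrated in closed form; the remaining harmonic correction is solved
## per mode as a 4x4 linear system in a basis of exponentials with
## non-positive arguments, so nothing overflows however small beta is.  The
## per-mode flow contributions then decay like n^-5.

.rheoflowError <- function(subclass, message, data = list()) {
  stop(structure(
    class = c(subclass, "rheoflowError", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  ))
}

.checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                         openLower = FALSE, openUpper = FALSE) {
  if (length(x) != 1 || !is.finite(x))
    .rheoflowError("rheoflowDomainError",
                   sprintf("%s must be a single finite number", name))
  bad <- if (openLower) x <= lower else x < lower
  bad <- bad || if (openUpper) x >= upper else x > upper
  if (bad)
    .rheoflowError("rheoflowDomainError",
                   sprintf("%s = %g is outside its admissible range", name, x))
  invisible(x)
}

## Per-mode flow-rate contributions of the harmonic correction, plus the
## closed-form plane-Poiseuille baseline.  Works in units w = 1, G = 1,
## mu1 = 1, mu2 = muRatio; only the ratio Q1/Q2 is used downstream.
.seriesFlowComponents <- function(muRatio, interfaceY, aspectBeta,
                                  maxTerms = 201, relTol = 1e-12) {
  h <- aspectBeta
  mu1 <- 1
  mu2 <- muRatio
  d1 <- 0.5 - interfaceY   # reference-stream width (fluid 1, y > Y)
  d2 <- 0.5 + interfaceY   # test-stream width (fluid 2, y < Y)

  Q1 <- h^3 * d1 / (12 * mu1)
  Q2 <- h^3 * d2 / (12 * mu2)

  converged <- FALSE
  nUsed <- 0
  lastPartials <- c(Q1 = Q1, Q2 = Q2)
  for (m in seq_len(maxTerms)) {
    n <- 2 * m - 1
    k <- n * pi / h
    s <- (-1)^((n - 1) / 2)
    g <- 4 * s / (h * k^3)          # Fourier coefficient of (h^2/4 - z^2)/2
    E1 <- exp(-k * d1)
    E2 <- exp(-k * d2)
    ## unknowns (alpha, gamma, delta, eps): correction V1 in fluid 1 is
    ## alpha*exp(-k(1/2 - y)) + gamma*exp(-k(y - Y)), V2 analogous.
    A <- rbind(
      c(1, E1, 0, 0),                       # V1(wall 1) = -g/mu1
      c(0, 0, E2, 1),                       # V2(wall 2) = -g/mu2
      c(E1, 1, -1, -E2),                    # velocity continuity at Y
      c(mu1 * E1, -mu1, -mu2, mu2 * E2)     # shear-stress continuity at Y
    )
    rhs <- c(-g / mu1, -g / mu2, g * (1 / mu2 - 1 / mu1), 0)
    x <- solve(A, rhs)
    Iz <- (2 / k) * s
    q1 <- Iz * (x[1] + x[2]) * (1 - E1) / k
    q2 <- Iz * (x[3] + x[4]) * (1 - E2) / k
    lastPartials <- c(Q1 = Q1, Q2 = Q2)
    Q1 <- Q1 + q1
    Q2 <- Q2 + q2
    nUsed <- n
    if (abs(q1) < relTol * abs(Q1) && abs(q2) < relTol * abs(Q2)) {
      converged <- TRUE
      break
    }
  }
  list(Q1 = Q1, Q2 = Q2, nTerms = nUsed, converged = converged,
       lastPartials = lastPartials, finalPartials = c(Q1 = Q1, Q2 = Q2))
}

#' Flow-rate ratio of two stratified streams in a rectangular channel
#'
#' Evaluates the analytical series solution for two co-flowing laminar
#' streams in a rectangular duct and returns the flow-rate ratio
#' `Q1/Q2` (reference over test) as a function of the viscosity ratio
#' `mu2/mu1`, the dimensionless interface position `Y` and the channel
#' aspect ratio `beta = h/w`.  This is the forward map of the microfluidic
#' comparator viscometer.
#'
#' The series is evaluated mode by mode over odd Fourier indices across the
#' channel depth; hyperbolic-function ratios are recast as exponentials of
#' non-positive arguments, so the evaluation is overflow-safe for any aspect
#' ratio.  Truncation stops when adding a term changes both partial flow
#' sums by less than `relTol` relative, or at `maxTerms` terms.
#'
#' @param muRatio viscosity ratio mu_test / mu_ref, positive.
#' @param interfaceY dimensionless interface position in (-0.5, 0.5);
#'   `Y = 1/2 - w1/w` with the reference stream on the side `y > Y`.
#' @param aspectBeta channel aspect ratio h/w, positive.
#' @param settings a [SeriesSettings-class] object.
#' @return The flow-rate ratio Q1/Q2 (positive scalar), with attributes
#'   `nTerms` (odd index of the last term used) and `converged`.
#' @examples
#' seriesFlowRatio(1, 0, 60 / 110)   # symmetric split: exactly 1
#' seriesFlowRatio(5, 0, 60 / 110)   # more viscous test stream lags behind
#' @export
seriesFlowRatio <- function(muRatio, interfaceY, aspectBeta,
                            settings = seriesSettings()) {
  .checkScalar(muRatio, "muRatio", lower = 0, openLower = TRUE)
  .checkScalar(interfaceY, "interfaceY", lower = -0.5, upper = 0.5,
               openLower = TRUE, openUpper = TRUE)
  .checkScalar(aspectBeta, "aspectBeta", lower = 0, openLower = TRUE)
  comp <- .seriesFlowComponents(muRatio, interfaceY, aspectBeta,
                                maxTerms = settings@maxTerms,
                                relTol = settings@relTol)
  if (!comp$converged) {
    ## accept benign truncation (terms decay like n^-5); only refuse when
    ## the remaining change is far from the requested tolerance
    lastChange <- max(abs(comp$finalPartials - comp$lastPartials) /
                        abs(comp$finalPartials))
    if (lastChange > 1e6 * settings@relTol)
      .rheoflowError("rheoflowConvergenceError",
                     sprintf(paste0("series not converged after %d terms ",
                                    "(last relative change %.3g)"),
                             comp$nTerms, lastChange),
                     data = list(lastPartials = comp$lastPartials,
                                 finalPartials = comp$finalPartials))
  }
  structure(comp$Q1 / comp$Q2, nTerms = comp$nTerms,
            converged = comp$converged)
}

#' Invert the co-flow series for the viscosity ratio
#'
#' Finds the viscosity ratio `r = mu_test / mu_ref` whose forward flow-rate
#' ratio [seriesFlowRatio()] matches an observed `Q1/Q2` at known interface
#' position and aspect ratio.  The forward map is strictly increasing in the
#' viscosity ratio (a more viscous test stream carries less flow), which is
#' verified numerically on the bracket before root refinement by a
#' bracketing method.
#'
#' @param flowRatio observed Q1/Q2, positive.
#' @param interfaceY dimensionless interface position in (-0.5, 0.5).
#' @param aspectBeta channel aspect ratio h/w.
#' @param settings a [SeriesSettings-class] object.
#' @param bracket search interval for the viscosity ratio.
#' @return the viscosity ratio (scalar), reproducing `flowRatio` to better
#'   than 1e-8 relative.
#' @examples
#' fr <- seriesFlowRatio(3.7, 0.1, 60 / 110)
#' solveViscosityRatio(fr, 0.1, 60 / 110)  # 3.7
#' @export
solveViscosityRatio <- function(flowRatio, interfaceY, aspectBeta,
                                settings = seriesSettings(),
                                bracket = c(1e-3, 1e3)) {
  .checkScalar(flowRatio, "flowRatio", lower = 0, openLower = TRUE)
  f <- function(logR) {
    log(as.numeric(seriesFlowRatio(exp(logR), interfaceY, aspectBeta,
                                   settings))) - log(flowRatio)
  }
  lo <- log(bracket[1]); hi <- log(bracket[2])
  fLo <- f(lo); fHi <- f(hi)
  ## monotonicity check on an interior grid before trusting the bracket
  grid <- seq(lo, hi, length.out = 5)
  fg <- vapply(grid, f, numeric(1))
  if (any(diff(fg) <= 0))
    .rheoflowError("rheoflowInversionError",
                   "forward flow-ratio map is not strictly increasing on the bracket")
  if (fLo * fHi > 0)
    .rheoflowError("rheoflowInversionError",
                   sprintf(paste0("no sign change in bracket: forward values ",
                                  "%.6g at %.3g and %.6g at %.3g for target %.6g"),
                           exp(fLo) * flowRatio, bracket[1],
                           exp(fHi) * flowRatio, bracket[2], flowRatio),
                   data = list(bracket = bracket,
                               forward = flowRatio * exp(c(fLo, fHi))))
  root <- stats::uniroot(f, lower = lo, upper = hi, f.lower = fLo,
                         f.upper = fHi, tol = 1e-12)
  exp(root$root)
}

#' Invert the co-flow series for the interface position
#'
#' Finds the interface position `Y` at which two streams with a given
#' viscosity ratio split the channel so that the flow-rate ratio matches the
#' pump-imposed `Q1/Q2`.  The forward map is strictly decreasing in `Y`
#' (pushing the interface towards the reference-side wall shrinks the
#' reference stream).
#'
#' @inheritParams solveViscosityRatio
#' @param muRatio viscosity ratio mu_test / mu_ref.
#' @param bracket search interval for Y inside (-0.5, 0.5).
#' @return interface position Y reproducing `flowRatio` to better than 1e-8
#'   relative.
#' @examples
#' solveInterfacePosition(1, 1, 60 / 110)  # symmetric: 0
#' @export
solveInterfacePosition <- function(flowRatio, muRatio, aspectBeta,
                                   settings = seriesSettings(),
                                   bracket = c(-0.499, 0.499)) {
  .checkScalar(flowRatio, "flowRatio", lower = 0, openLower = TRUE)
  .checkScalar(muRatio, "muRatio", lower = 0, openLower = TRUE)
  f <- function(Y) {
    log(as.numeric(seriesFlowRatio(muRatio, Y, aspectBeta, settings))) -
      log(flowRatio)
  }
  fLo <- f(bracket[1]); fHi <- f(bracket[2])
  if (fLo * fHi > 0)
    .rheoflowError("rheoflowInversionError",
                   sprintf("no interface position in (%.3f, %.3f) yields Q1/Q2 = %.6g",
                           bracket[1], bracket[2], flowRatio),
                   data = list(forward = flowRatio * exp(c(fLo, fHi))))
  root <- stats::uniroot(f, lower = bracket[1], upper = bracket[2],
                         f.lower = fLo, f.upper = fHi, tol = 1e-12)
  root$root
}

#' Finite-difference two-fluid duct-flow field
#'
#' Solves the axial momentum balance `div(mu grad u) = -G` on the rectangular
#' cross-section with piecewise-constant viscosity, no-slip walls and
#' continuity of velocity and shear stress at the fluid interface, using a
#' conservative second-order five-point scheme (face viscosities taken at
#' face midpoints, so the interfacial flux condition is built in).  The
#' interface is snapped to the nearest transverse grid line.  This solver is
#' deliberately independent of [seriesFlowRatio()] and serves as its
#' cross-check, as well as the velocity-field source for the synthetic
#' particle-image generator.
#'
#' @param geometry a [ChannelGeometry-class] (micrometres).
#' @param muRef,muTest viscosities of the reference and test fluids (cP).
#' @param pressureGradient axial pressure gradient (Pa/m), positive for flow
#'   in +x.
#' @param gridShape integer length 2, nodes across (width, depth); both at
#'   least 51.
#' @return a [DuctField-class] with velocity in mm/s and per-stream flow
#'   rates in uL/hr.  The geometry slot carries the snapped interface.
#' @examples
#' geom <- channelGeometry(110, 60, interfaceY = 0)
#' fld <- fdVelocityField(geom, 1, 5, 1e5, gridShape = c(101, 101))
#' flowRatio(fld)
#' @export
fdVelocityField <- function(geometry, muRef, muTest, pressureGradient,
                            gridShape = c(201, 201)) {
  stopifnot(is(geometry, "ChannelGeometry"))
  .checkScalar(muRef, "muRef", lower = 0, openLower = TRUE)
  .checkScalar(muTest, "muTest", lower = 0, openLower = TRUE)
  .checkScalar(pressureGradient, "pressureGradient", lower = 0,
               openLower = TRUE)
  if (any(gridShape < 51))
    .rheoflowError("rheoflowDomainError", "gridShape must be at least 51 x 51")

  w <- geometry@width * 1e-6           # m
  h <- geometry@depth * 1e-6           # m
  mu1 <- muRef * 1e-3                  # Pa s
  mu2 <- muTest * 1e-3
  G <- pressureGradient

  ny <- gridShape[1]; nz <- gridShape[2]
  y <- seq(-w / 2, w / 2, length.out = ny)
  z <- seq(-h / 2, h / 2, length.out = nz)
  hy <- y[2] - y[1]; hz <- z[2] - z[1]

  iy <- which.min(abs(y - geometry@interfaceY * w))
  if (iy == 1 || iy == ny)
    .rheoflowError("rheoflowSolverError",
                   "interface snapped onto a wall; refine the grid or move Y")
  ySnap <- y[iy]
  muAt <- function(yy) ifelse(yy > ySnap, mu1, mu2)   # fluid 1 on y > Y

  nyi <- ny - 2; nzi <- nz - 2
  N <- nyi * nzi
  ii <- rep(2:(ny - 1), times = nzi)
  jj <- rep(2:(nz - 1), each = nyi)
  r <- seq_len(N)

  muW <- muAt(y[ii] - hy / 2); muE <- muAt(y[ii] + hy / 2)
  muC <- muAt(y[ii])           # z faces share the node's y
  cW <- muW / hy^2; cE <- muE / hy^2; cS <- muC / hz^2; cN <- muC / hz^2

  hasW <- ii > 2; hasE <- ii < ny - 1; hasS <- jj > 2; hasN <- jj < nz - 1
  I <- c(r, r[hasW], r[hasE], r[hasS], r[hasN])
  J <- c(r, r[hasW] - 1, r[hasE] + 1, r[hasS] - nyi, r[hasN] + nyi)
  V <- c(cW + cE + cS + cN, -cW[hasW], -cE[hasE], -cS[hasS], -cN[hasN])
  A <- Matrix::sparseMatrix(i = I, j = J, x = V, dims = c(N, N))
  u <- tryCatch(
    as.numeric(Matrix::solve(A, rep(G, N))),
    error = function(e) .rheoflowError("rheoflowSolverError",
                                       paste("linear solve failed:",
                                             conditionMessage(e)))
  )

  U <- matrix(0, ny, nz)
  U[2:(ny - 1), 2:(nz - 1)] <- matrix(u, nyi, nzi)

  trapz <- function(x, f) sum(diff(x) * (utils::head(f, -1) +
                                           utils::tail(f, -1)) / 2)
  qy <- apply(U, 1, function(row) trapz(z, row))      # m^2/s per unit y
  Q1 <- trapz(y[iy:ny], qy[iy:ny])                    # m^3/s, reference side
  Q2 <- trapz(y[1:iy], qy[1:iy])
  toULhr <- 3.6e12

  muMap <- matrix(muAt(y), ny, nz) / 1e-3
  muMap[iy, ] <- (muRef + muTest) / 2                 # interface line, cosmetic

  geomSnap <- channelGeometry(geometry@width, geometry@depth,
                              interfaceY = ySnap / w)
  new("DuctField", gridY = y * 1e6, gridZ = z * 1e6,
      velocity = U * 1e3, viscosityMap = muMap,
      flowRate1 = Q1 * toULhr, flowRate2 = Q2 * toULhr,
      geometry = geomSnap)
}

#' Apparent viscosity of the test stream from a co-flow measurement
#'
#' Given the pump-imposed flow rates, the reference-fluid viscosity and the
#' observed interface position, inverts the stratified-flow series for the
#' viscosity ratio and returns the apparent viscosity of the test fluid.
#'
#' @param problem a [CoflowProblem-class] carrying muRef, qRef and qTest.
#' @param geometry a [ChannelGeometry-class] carrying the interface position.
#' @param settings a [SeriesSettings-class].
#' @return apparent test-fluid viscosity in the units of `muRef` (cP), with
#'   attribute `muRatio`.
#' @examples
#' geom <- channelGeometry(110, 60, interfaceY = 0.1)
#' prob <- coflowProblem(muRef = 1, qRef = 40, qTest = 10)
#' apparentViscosity(prob, geom)
#' @export
apparentViscosity <- function(problem, geometry,
                              settings = seriesSettings()) {
  stopifnot(is(problem, "CoflowProblem"), is(geometry, "ChannelGeometry"))
  ratio <- solveViscosityRatio(flowRatio(problem), interfaceY(geometry),
                               aspectRatio(geometry), settings)
  structure(problem@muRef * ratio, muRatio = ratio)
}
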