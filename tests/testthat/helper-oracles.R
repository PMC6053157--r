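## Independent oracles and small builders used across the test files.

## Closed-form volumetric flow rate of a SINGLE fluid in a rectangular duct
## of width w (m), depth h (m), viscosity mu (Pa s) under pressure gradient
## G (Pa/m): the classical textbook series (independent of the package's
## finite-difference and two-fluid series code paths).
singleFluidDuctFlow <- function(w, h, mu, G, nTerms = 400) {
  n <- seq(1, 2 * nTerms - 1, by = 2)
  s <- sum(tanh(n * pi * w / (2 * h)) / n^5)
  G * h^3 * w / (12 * mu) * (1 - 192 * h / (pi^5 * w) * s)
}

## A DuctField with spatially constant velocity (mm/s), for uniform-shift
## particle generation.
uniformDuctField <- function(u, width = 110, depth = 60, n = 101) {
  g <- channelGeometry(width, depth, interfaceY = 0)
  y <- seq(-width / 2, width / 2, length.out = n)
  z <- seq(-depth / 2, depth / 2, length.out = n)
  new("DuctField", gridY = y, gridZ = z,
      velocity = matrix(u, n, n), viscosityMap = matrix(1, n, n),
      flowRate1 = 1, flowRate2 = 1, geometry = g)
}

## A DuctField whose mid-plane profile is an exact linear shear ramp
## u = slope * y (mm/s, y in um from the row-1 wall).
linearShearDuctField <- function(slope, width = 110, depth = 60, n = 101) {
  fld <- uniformDuctField(0, width, depth, n)
  yWall <- fld@gridY - min(fld@gridY)
  fld@velocity <- matrix(rep(slope * yWall, n), n, n)
  fld
}

## Draw a filled disk of the given radius into a matrix (background bg,
## object level obj), by pixel-center test.
drawDisk <- function(frame, cy, cx, r, level) {
  yy <- outer(seq_len(nrow(frame)), rep(1, ncol(frame)))
  xx <- outer(rep(1, nrow(frame)), seq_len(ncol(frame)))
  frame[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- level
  frame
}

tableOnePowerLaw <- list(
  h5 = c(K = 9.9, n = 0.603),
  h10 = c(K = 50.9, n = 0.156),
  h15 = c(K = 62.2, n = 0.197)
)

tableTwoCarreau <- list(
  h5 = c(mu0 = 26.9, muInf = 1.6, lambda = 3.313, n = 0.353),
  h10 = c(mu0 = 89.9, muInf = 1.6, lambda = 3.312, n = 0.369),
  h15 = c(mu0 = 118.6, muInf = 2.3, lambda = 3.312, n = 0.362)
)
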