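## Micro-PIV: multi-pass cross-correlation velocimetry on tracer-particle
## image pairs, temporal/streamwise profile averaging with RMS uncertainty,
## blood-layer localization from the tracer-density profile, and shear-rate
## extraction as the slope of the profile within the blood layer.
##
## Image convention: matrices with rows = transverse position y (across the
## channel width, row 1 on the test-fluid/blood side wall) and columns =
## streamwise position x (flow direction).

#' Remove the static background from an image stack
#'
#' Subtracts a per-pixel temporal background from every frame, clipping at
#' zero.  The default background model is the per-pixel temporal minimum,
#' which is robust for sparse bright tracers over a static background; the
#' per-pixel temporal mean is available by configuration.  The operation is
#' invariant to adding a constant to all frames.
#'
#' @param stack list of intensity matrices of identical shape (at least 2).
#' @param method `"minimum"` (default) or `"mean"`.
#' @return list of background-subtracted frames.
#' @examples
#' fr <- matrix(5, 8, 8)
#' removeBackground(list(fr, fr))[[1]][1, 1]  # 0
#' @export
removeBackground <- function(stack, method = c("minimum", "mean")) {
  method <- match.arg(method)
  if (!is.list(stack) || length(stack) < 2)
    .rheoflowError("rheoflowConfigError",
                   "background removal needs at least 2 frames")
  d <- dim(stack[[1]])
  if (!all(vapply(stack, function(f) identical(dim(f), d), logical(1))))
    .rheoflowError("rheoflowShapeError", "frames must share one shape")
  arr <- array(unlist(stack), dim = c(d, length(stack)))
  bg <- if (method == "minimum") apply(arr, c(1, 2), min)
        else apply(arr, c(1, 2), mean)
  lapply(stack, function(f) pmax(f - bg, 0))
}

## Anisotropic window weighting: Gaussian, elongated in the streamwise (x)
## direction with the given x:y aspect.  Matches the elongated-window
## weighting used for strongly unidirectional micro-flows.
.windowWeight <- function(win, xWeightRatio) {
  sx <- win / 4
  sy <- sx / xWeightRatio
  cy <- (win + 1) / 2
  row <- exp(-((seq_len(win) - cy)^2) / (2 * sy^2))   # rows = y
  col <- exp(-((seq_len(win) - cy)^2) / (2 * sx^2))   # cols = x
  outer(row, col)
}

## Circular FFT cross-correlation of two equally sized windows (mean
## subtracted, weighted); returns the correlation plane with zero shift at
## index (1, 1), wrapping negative shifts to the far end.
.xcorrPlane <- function(A, B) {
  fa <- stats::fft(A)
  fb <- stats::fft(B)
  Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / length(A)
}

## Three-point Gaussian sub-pixel interpolation along one axis.
.subpixelGauss <- function(cm, c0, cp) {
  eps <- 1e-12
  if (c0 <= 0) return(0)
  cm <- max(cm, eps * c0); cp <- max(cp, eps * c0)
  den <- log(cm) + log(cp) - 2 * log(c0)
  if (den >= 0) return(0)
  d <- 0.5 * (log(cm) - log(cp)) / den
  if (!is.finite(d) || abs(d) > 1) 0 else d
}

## One interrogation of a window pair; returns c(dy, dx, signal) with the
## displacement in pixels relative to zero shift (NA if the windows carry
## no signal) and the root energy of window A as a seeding-signal measure.
## The correlation plane is divided by the weight-autocorrelation envelope:
## without this, the window weighting multiplies the particle correlation
## peak by a lag-dependent factor that biases uncompensated displacements
## towards zero.
.interrogate <- function(A, B, weight, maxShift, envelope) {
  A <- A - mean(A); B <- B - mean(B)
  nA <- sqrt(sum(A^2)); nB <- sqrt(sum(B^2))
  if (nA == 0 || nB == 0) return(c(NA_real_, NA_real_, nA))
  C <- .xcorrPlane(A * weight, B * weight) / (nA * nB) / envelope
  ## lags where the weighting envelope has lost (almost) all support are
  ## unmeasurable: the division there only amplifies noise
  C[envelope < 0.05 * max(envelope)] <- -Inf
  win <- nrow(C)
  shifts <- c(0:maxShift, (win - maxShift):(win - 1)) # allowed circular lags
  sub <- C[shifts + 1, shifts + 1, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  iy <- shifts[pk[1]]; ix <- shifts[pk[2]]
  wrap <- function(i) ((i %% win) + win) %% win + 1
  c0 <- C[iy + 1, ix + 1]
  dy <- .subpixelGauss(C[wrap(iy - 1), ix + 1], c0, C[wrap(iy + 1), ix + 1])
  dx <- .subpixelGauss(C[iy + 1, wrap(ix - 1)], c0, C[iy + 1, wrap(ix + 1)])
  toSigned <- function(i) if (i > win / 2) i - win else i
  c(toSigned(iy) + dy, toSigned(ix) + dx, nA)
}

## Pad a matrix by one row/column on each side using linear extrapolation,
## so border vectors see a symmetric 3x3 neighborhood.  In a sheared flow a
## mirror or replicate pad would bias the border medians towards the
## interior; linear extrapolation continues the local gradient instead.
.padLinear <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  top <- if (nr >= 2) 2 * M[1, ] - M[2, ] else M[1, ]
  bot <- if (nr >= 2) 2 * M[nr, ] - M[nr - 1, ] else M[nr, ]
  M2 <- rbind(top, M, bot)
  left <- if (nc >= 2) 2 * M2[, 1] - M2[, 2] else M2[, 1]
  right <- if (nc >= 2) 2 * M2[, nc] - M2[, nc - 1] else M2[, nc]
  unname(cbind(left, M2, right))
}

## Normalized median test (3x3 neighborhood) on one displacement component;
## the field is linear-extrapolation padded first so that border vectors in
## a strong transverse gradient are not flagged against a one-sided
## neighborhood.
.normMedianResidual <- function(M) {
  P <- .padLinear(M)
  nr <- nrow(M); nc <- ncol(M)
  res <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nb <- P[i:(i + 2), j:(j + 2)]
    nb <- nb[-5]                       # drop the candidate itself
    nb <- nb[is.finite(nb)]
    if (length(nb) < 3) { res[i, j] <- 0; next }
    md <- stats::median(nb)
    rm_ <- stats::median(abs(nb - md))
    res[i, j] <- abs(M[i, j] - md) / (rm_ + 0.1)
  }
  res
}

.localMedianPadded <- function(P, i, j) {
  nb <- P[i:(i + 2), j:(j + 2)]
  nb <- nb[-5]
  nb <- nb[is.finite(nb)]
  if (length(nb)) stats::median(nb) else NA_real_
}

## Validate a displacement field: normalized median test on both components,
## invalid vectors replaced by local medians and marked.
.validateField <- function(dy, dx, valid, threshold = 2) {
  bad <- !valid | !is.finite(dx) | !is.finite(dy)
  dxw <- dx; dxw[bad] <- NA; dyw <- dy; dyw[bad] <- NA
  rx <- .normMedianResidual(dxw); ry <- .normMedianResidual(dyw)
  flag <- bad | (is.finite(rx) & rx > threshold) |
               (is.finite(ry) & ry > threshold)
  dxw[flag] <- NA; dyw[flag] <- NA
  Px <- .padLinear(dxw); Py <- .padLinear(dyw)
  replaced <- matrix(FALSE, nrow(dx), ncol(dx))
  for (i in seq_len(nrow(dx))) for (j in seq_len(ncol(dx))) {
    if (flag[i, j]) {
      mx <- .localMedianPadded(Px, i, j); my <- .localMedianPadded(Py, i, j)
      if (is.finite(mx) && is.finite(my)) {
        dx[i, j] <- mx; dy[i, j] <- my; replaced[i, j] <- TRUE
      } else {
        dx[i, j] <- NA_real_; dy[i, j] <- NA_real_
      }
    }
  }
  list(dy = dy, dx = dx, valid = !flag | replaced, replaced = replaced,
       flagged = flag)
}

## Window-center grid for a given window size and overlap.
.pivGrid <- function(extent, win, step) {
  starts <- seq(1, extent - win + 1, by = step)
  list(starts = starts, centers = starts + win / 2 - 0.5)
}

#' Multi-pass cross-correlation PIV on one image pair
#'
#' Estimates the displacement field between the two frames of a
#' [ParticleImagePair-class] by normalized FFT cross-correlation over
#' interrogation windows, refined in two passes: a coarse pass at
#' `initialWindow` whose (validated) displacements shift the second-pass
#' interrogation windows, and a final pass at `finalWindow` with the given
#' overlap.  Windows are weighted anisotropically (streamwise:transverse =
#' `xWeightRatio`:1) before correlation, the correlation peak is located to
#' sub-pixel accuracy with a three-point Gaussian fit, and vectors failing a
#' normalized median test (threshold 2, 3x3 neighborhood) are replaced by
#' local medians and marked — never silently overwritten.
#'
#' @param pair a [ParticleImagePair-class].
#' @param initialWindow coarse-pass window size in pixels (default 64).
#' @param finalWindow final-pass window size in pixels (default 32).
#' @param overlap window overlap fraction (default 0.5).
#' @param xWeightRatio streamwise:transverse window-weighting aspect
#'   (default 4).
#' @return a [VectorField-class] with displacements in pixels (`dx`
#'   streamwise, `dy` transverse), a validity mask and a replacement mask.
#' @export
pivMultipass <- function(pair, initialWindow = 64, finalWindow = 32,
                         overlap = 0.5, xWeightRatio = 4) {
  stopifnot(is(pair, "ParticleImagePair"))
  a <- pair@frameA; b <- pair@frameB
  if (nrow(a) < initialWindow || ncol(a) < initialWindow)
    .rheoflowError("rheoflowDomainError",
                   "frames must be larger than the initial window")
  wins <- unique(c(initialWindow, finalWindow))
  predDx <- NULL; predDy <- NULL; predRow <- NULL; predCol <- NULL

  for (p in seq_along(wins)) {
    win <- wins[p]
    step <- max(1L, as.integer(round(win * (1 - overlap))))
    gr <- .pivGrid(nrow(a), win, step)
    gc <- .pivGrid(ncol(a), win, step)
    nr <- length(gr$starts); nc <- length(gc$starts)
    dy <- matrix(NA_real_, nr, nc); dx <- matrix(NA_real_, nr, nc)
    pdy <- matrix(0L, nr, nc); pdx <- matrix(0L, nr, nc)
    if (!is.null(predDx)) {
      ## nearest-neighbour predictor from the coarser grid, rounded to
      ## integer pixels so the second-pass windows stay aligned
      ri <- vapply(gr$centers, function(y) which.min(abs(predRow - y)),
                   integer(1))
      ci <- vapply(gc$centers, function(x) which.min(abs(predCol - x)),
                   integer(1))
      pdy[] <- as.integer(round(predDy[ri, ci, drop = FALSE]))
      pdx[] <- as.integer(round(predDx[ri, ci, drop = FALSE]))
    }
    weight <- .windowWeight(win, xWeightRatio)
    envelope <- .xcorrPlane(weight, weight)
    envelope <- pmax(envelope, 1e-3 * max(envelope))
    maxShift <- as.integer(floor(win / 3))
    sig <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      r0 <- gr$starts[i]; c0 <- gc$starts[j]
      ## clamp the shifted window of frame B inside the image
      r0b <- min(max(r0 + pdy[i, j], 1L), nrow(a) - win + 1L)
      c0b <- min(max(c0 + pdx[i, j], 1L), ncol(a) - win + 1L)
      clamped <- (r0b - r0 != pdy[i, j]) || (c0b - c0 != pdx[i, j])
      pdy[i, j] <- r0b - r0; pdx[i, j] <- c0b - c0
      if (clamped && p > 1) {
        ## the refinement pass cannot compensate this window at the frame
        ## edge; an uncompensated measurement here would be biased
        dy[i, j] <- NA_real_; dx[i, j] <- NA_real_
        next
      }
      A <- a[r0:(r0 + win - 1), c0:(c0 + win - 1)]
      B <- b[r0b:(r0b + win - 1), c0b:(c0b + win - 1)]
      d <- .interrogate(A, B, weight, maxShift, envelope)
      sig[i, j] <- d[3]
      if (any(!is.finite(d[1:2])) || any(abs(d[1:2]) > win / 2)) {
        dy[i, j] <- NA_real_; dx[i, j] <- NA_real_
      } else {
        dy[i, j] <- pdy[i, j] + d[1]; dx[i, j] <- pdx[i, j] + d[2]
      }
    }
    ## gate windows with next to no particle signal (e.g. outside the
    ## seeded layer): their "vectors" are noise peaks, and left in place
    ## they would contaminate the median-test neighborhoods
    sigThr <- 0.1 * stats::quantile(sig, 0.95, na.rm = TRUE)
    gate <- which(sig < sigThr)
    dy[gate] <- NA_real_; dx[gate] <- NA_real_
    val <- .validateField(dy, dx, valid = is.finite(dx) & is.finite(dy))
    dy <- val$dy; dx <- val$dx
    predDy <- dy; predDx <- dx
    predDy[!val$valid] <- 0; predDx[!val$valid] <- 0
    predRow <- gr$centers; predCol <- gc$centers
    lastGrid <- list(row = gr$centers, col = gc$centers)
    lastVal <- val
  }
  new("VectorField", gridRow = lastGrid$row, gridCol = lastGrid$col,
      dx = dx, dy = dy, valid = lastVal$valid,
      replaced = lastVal$replaced, units = "px")
}

#' Scale a displacement field to velocity units
#'
#' Applies the exact arithmetic contract `v[mm/s] = d[px] * pixelScale[um/px]
#' / dt[ms]` to both components.
#'
#' @param field a [VectorField-class] in pixels.
#' @param dt inter-frame time (ms).
#' @param pixelScale micrometres per pixel.
#' @return a [VectorField-class] in mm/s.
#' @examples
#' ## 10 px at 0.27 um/px over 2 ms -> 1.35 mm/s
#' @export
displacementToVelocity <- function(field, dt, pixelScale) {
  stopifnot(is(field, "VectorField"))
  .checkScalar(dt, "dt", lower = 0, openLower = TRUE)
  .checkScalar(pixelScale, "pixelScale", lower = 0, openLower = TRUE)
  f <- field
  f@dx <- field@dx * pixelScale / dt
  f@dy <- field@dy * pixelScale / dt
  f@units <- "mm/s"
  f
}

#' Average velocity fields into one transverse profile with RMS uncertainty
#'
#' Computes, at every grid point, the temporal mean over the N fields and
#' the root-mean-square fluctuation
#' `RMS = sqrt((N * sum(u_i^2) - (sum(u_i))^2) / (N (N - 1)))`
#' (algebraically the sample standard deviation), then averages both along
#' the streamwise direction to produce a single representative profile.
#'
#' @param fields list of [VectorField-class] objects on identical grids
#'   (at least 2), in velocity units.
#' @param pixelScale micrometres per pixel used to convert the transverse
#'   grid to micrometres (default 1: positions remain in pixels).
#' @return a [VelocityProfile-class]; `y` is measured from the row-1 wall.
#' @export
temporalAverageProfile <- function(fields, pixelScale = 1) {
  if (length(fields) < 2)
    .rheoflowError("rheoflowConfigError",
                   "need at least 2 fields for a temporal RMS")
  g1 <- fields[[1]]
  same <- vapply(fields, function(f)
    identical(f@gridRow, g1@gridRow) && identical(f@gridCol, g1@gridCol),
    logical(1))
  if (!all(same))
    .rheoflowError("rheoflowShapeError", "fields must share one grid")
  N <- length(fields)
  arr <- array(unlist(lapply(fields, function(f) f@dx)),
               dim = c(dim(g1@dx), N))
  sum1 <- apply(arr, c(1, 2), function(v) sum(v, na.rm = TRUE))
  sum2 <- apply(arr, c(1, 2), function(v) sum(v^2, na.rm = TRUE))
  nEff <- apply(arr, c(1, 2), function(v) sum(is.finite(v)))
  meanU <- ifelse(nEff > 0, sum1 / nEff, NA_real_)
  rmsU <- ifelse(nEff > 1,
                 sqrt(pmax(nEff * sum2 - sum1^2, 0) / (nEff * (nEff - 1))),
                 NA_real_)
  profU <- rowMeans(meanU, na.rm = TRUE)
  profR <- rowMeans(rmsU, na.rm = TRUE)
  new("VelocityProfile", y = g1@gridRow * pixelScale, u = profU,
      rms = profR, nFields = N)
}

#' Transverse tracer-density profile of an image stack
#'
#' Averages background-removed frames over time and the streamwise
#' direction, yielding a per-row fluorescence-density proxy used to locate
#' the seeded (blood) layer.
#'
#' @param stack list of intensity matrices (the raw tracer frames).
#' @return numeric vector, one value per image row.
#' @export
tracerDensityProfile <- function(stack) {
  clean <- removeBackground(stack)
  rowMeans(Reduce(`+`, clean) / length(clean))
}

#' Locate the seeded blood layer from a transverse density profile
#'
#' Returns the maximal contiguous transverse interval over which the tracer
#' density is at least `thresholdFraction` of its maximum.  Interval edges
#' are refined to sub-sample positions by linear interpolation of the
#' threshold crossings.
#'
#' @param density numeric density profile across the channel width.
#' @param y transverse positions of the profile samples (um); defaults to
#'   sample indices.
#' @param thresholdFraction fraction of the maximum density (default 0.5).
#' @return numeric length 2: `c(yLo, yHi)` in the units of `y`.
#' @export
detectBloodLayer <- function(density, y = seq_along(density),
                             thresholdFraction = 0.5) {
  if (length(density) != length(y))
    .rheoflowError("rheoflowShapeError", "density and y must match")
  if (!any(is.finite(density)) || max(density, na.rm = TRUE) <= 0)
    .rheoflowError("rheoflowDetectionError",
                   "no tracer signal anywhere across the channel")
  thr <- thresholdFraction * max(density, na.rm = TRUE)
  above <- density >= thr
  above[is.na(above)] <- FALSE
  if (!any(above))
    .rheoflowError("rheoflowDetectionError",
                   "no position reaches the density threshold")
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(runs$values)
  best <- k[which.max(runs$lengths[k])]
  i0 <- starts[best]; i1 <- ends[best]
  yLo <- y[i0]; yHi <- y[i1]
  if (i0 > 1) {   # sub-sample edge by linear interpolation of the crossing
    f <- (thr - density[i0 - 1]) / (density[i0] - density[i0 - 1])
    yLo <- y[i0 - 1] + f * (y[i0] - y[i0 - 1])
  }
  if (i1 < length(y)) {
    f <- (density[i1] - thr) / (density[i1] - density[i1 + 1])
    yHi <- y[i1] + f * (y[i1 + 1] - y[i1])
  }
  c(yLo, yHi)
}

#' Shear rate from the slope of a velocity profile within the blood layer
#'
#' Fits an ordinary least-squares line to `u` versus `y` over the central
#' `innerFraction` of the detected layer and returns the slope converted to
#' 1/s (profile in mm/s versus um implies a factor of 1000).
#'
#' @param profile a [VelocityProfile-class] (u in mm/s, y in um).
#' @param layer numeric length 2, the blood-layer interval (um).
#' @param innerFraction central fraction of the layer used for the fit
#'   (default 0.8, avoiding wall and interface bias).
#' @return a [ShearEstimate-class].
#' @export
estimateShearRate <- function(profile, layer, innerFraction = 0.8) {
  stopifnot(is(profile, "VelocityProfile"))
  ctr <- mean(layer)
  half <- innerFraction * diff(range(layer)) / 2
  win <- c(ctr - half, ctr + half)
  sel <- profile@y >= win[1] & profile@y <= win[2] & is.finite(profile@u)
  if (sum(sel) < 3)
    .rheoflowError("rheoflowFitError",
                   sprintf("only %d profile points inside the fit window",
                           sum(sel)))
  fit <- stats::lm(u ~ y, data = data.frame(y = profile@y[sel],
                                            u = profile@u[sel]))
  slope <- unname(stats::coef(fit)[2])        # mm/s per um
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((profile@u[sel] - mean(profile@u[sel]))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  new("ShearEstimate", shearRate = slope * 1000,
      intercept = unname(stats::coef(fit)[1]),
      fitWindow = win, rSquared = r2)
}
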