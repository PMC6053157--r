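## Synthetic-data generation with ground truth.  Every input the analysis
## chain consumes can be generated here: two-fluid duct velocity fields,
## tracer-particle image pairs advected by those fields, bright-field
## aggregate recordings, and noisy viscosity-shear curves.  Each generator
## is fully determined by its seed and returns the truth alongside the
## artifact, so every downstream stage can be tested against known answers.

#' Generate a synthetic co-flow experiment with ground truth
#'
#' Solves the interface position implied by the pump-imposed flow-rate
#' ratio and the chosen viscosity ratio, builds the finite-difference
#' two-fluid velocity field scaled to the requested test-stream flow rate,
#' and records the mid-depth blood-layer shear rate (the ordinary
#' least-squares slope of the true mid-plane profile over the central
#' `innerFraction` of the blood layer — the same windowed-slope definition
#' the velocimetry stage estimates).
#'
#' @param muRatio viscosity ratio mu_test / mu_ref.
#' @param qRatio pump-imposed flow-rate ratio Q_ref / Q_test (default 4,
#'   the reference stream running four times faster than the blood).
#' @param qTest test-stream (blood) flow rate in uL/hr (default 10).
#' @param muRef reference-fluid viscosity in cP (default 1.0; a synthetic
#'   stand-in for a saline reference, not a measured value).
#' @param width,depth channel dimensions in um (default 110 x 60).
#' @param gridShape finite-difference resolution (default 201 x 201).
#' @param innerFraction central fraction of the blood layer defining the
#'   shear-rate truth (default 0.8, matching [estimateShearRate()]).
#' @param seed integer seed recorded in the truth (this generator itself is
#'   deterministic; the seed governs downstream image generation).
#' @return list with elements `truth` ([ExperimentTruth-class]) and
#'   `field` ([DuctField-class]).
#' @examples
#' exp <- genCoflowExperiment(muRatio = 3, qRatio = 4, gridShape = c(101, 101))
#' shearRate(exp$truth)
#' @export
genCoflowExperiment <- function(muRatio, qRatio = 4, qTest = 10, muRef = 1,
                                width = 110, depth = 60,
                                gridShape = c(201, 201),
                                innerFraction = 0.8, seed = 1L) {
  .checkScalar(muRatio, "muRatio", lower = 0, openLower = TRUE)
  .checkScalar(qRatio, "qRatio", lower = 0, openLower = TRUE)
  beta <- depth / width
  Y <- solveInterfacePosition(qRatio, muRatio, beta)
  geom <- channelGeometry(width, depth, interfaceY = Y)
  fld <- fdVelocityField(geom, muRef, muRef * muRatio,
                         pressureGradient = 1e5, gridShape = gridShape)
  scale <- qTest / fld@flowRate2          # the PDE is linear in G
  fld@velocity <- fld@velocity * scale
  fld@flowRate1 <- fld@flowRate1 * scale
  fld@flowRate2 <- fld@flowRate2 * scale

  prof <- midPlaneProfile(fld)
  layer <- c(0, (0.5 + interfaceY(fld)) * width)   # blood side: wall to interface
  sh <- estimateShearRate(prof, layer, innerFraction = innerFraction)

  truth <- new("ExperimentTruth", geometry = fld@geometry,
               muRef = muRef, muTest = muRef * muRatio,
               qRef = fld@flowRate1, qTest = fld@flowRate2,
               midPlaneShearRate = shearRate(sh),
               pressureGradient = 1e5 * scale, seed = seed)
  list(truth = truth, field = fld)
}

#' Mid-depth velocity profile of a duct field
#'
#' Extracts the axial velocity along the channel width at the mid-depth
#' plane (z closest to 0) as a [VelocityProfile-class], with `y` measured
#' from the test-fluid (blood) side wall.
#'
#' @param field a [DuctField-class].
#' @return a [VelocityProfile-class] with zero RMS (it is exact).
#' @export
midPlaneProfile <- function(field) {
  stopifnot(is(field, "DuctField"))
  iz <- which.min(abs(field@gridZ))
  yWall <- field@gridY - min(field@gridY)
  new("VelocityProfile", y = yWall, u = field@velocity[, iz],
      rms = rep(0, length(yWall)), nFields = 1)
}

## Render Gaussian spots into an image; positions in (row, col) pixels.
.renderSpots <- function(H, W, rows, cols, amp, sigma) {
  img <- matrix(0, H, W)
  ext <- ceiling(3 * sigma)
  off <- -ext:ext
  for (p in seq_along(rows)) {
    r0 <- round(rows[p]); c0 <- round(cols[p])
    ri <- r0 + off; ci <- c0 + off
    keepR <- ri >= 1 & ri <= H; keepC <- ci >= 1 & ci <= W
    if (!any(keepR) || !any(keepC)) next
    gy <- exp(-((ri[keepR] - rows[p])^2) / (2 * sigma^2))
    gx <- exp(-((ci[keepC] - cols[p])^2) / (2 * sigma^2))
    img[ri[keepR], ci[keepC]] <- img[ri[keepR], ci[keepC]] +
      amp[p] * outer(gy, gx)
  }
  img
}

#' Generate tracer-particle image pairs advected by a duct field
#'
#' Places tracer particles uniformly at random inside the seeded (blood)
#' layer, renders them as Gaussian intensity spots, and advects them by the
#' local mid-depth velocity over `dt` for the second frame (particles
#' leaving the frame re-enter on the left, emulating fresh particles
#' arriving).  Additive Gaussian noise and an optional static illumination
#' ramp complete the images.  The exact displacement-vs-y table is stored
#' as ground truth.
#'
#' @param field a [DuctField-class] (typically from
#'   [genCoflowExperiment()]).
#' @param nPairs number of image pairs (default 10).
#' @param dt inter-frame time in ms; `NULL` (default) picks dt so the
#'   largest displacement is 8 px, inside the 6-10 px target used for
#'   accurate correlation.
#' @param pixelScale um per pixel (default 0.27).
#' @param imageWidthPx streamwise image size in pixels (default 192).
#' @param seedingDensity particles per px^2 within the seeded layer
#'   (default 0.05).
#' @param particleDiameterPx rendered spot diameter (default 3 px).
#' @param noiseSigma additive Gaussian noise sigma on the 8-bit-like
#'   intensity scale (default 2; spot amplitude is about 120).
#' @param rampFraction static multiplicative illumination ramp across x
#'   (default 0: uniform illumination).
#' @param wholeChannel seed tracers across the whole width instead of the
#'   blood layer only (default FALSE).
#' @param seed integer RNG seed; identical seeds give identical stacks.
#' @return list with `pairs` (list of [ParticleImagePair-class]), `dt`,
#'   `pixelScale`, and `truth`: a data.frame of y (um from the blood-side
#'   wall), u (mm/s) and displacement (px).
#' @export
genParticleFrames <- function(field, nPairs = 10, dt = NULL,
                              pixelScale = 0.27, imageWidthPx = 192,
                              seedingDensity = 0.05,
                              particleDiameterPx = 3, noiseSigma = 2,
                              rampFraction = 0, wholeChannel = FALSE,
                              seed = 1L) {
  stopifnot(is(field, "DuctField"))
  if (seedingDensity <= 0)
    .rheoflowError("rheoflowConfigError", "seedingDensity must be positive")
  set.seed(seed)
  width <- field@geometry@width
  H <- round(width / pixelScale)
  W <- imageWidthPx
  prof <- midPlaneProfile(field)
  uFun <- stats::approxfun(prof@y, prof@u, rule = 2)
  w2 <- (0.5 + interfaceY(field)) * width           # blood-layer width, um
  layerTopPx <- if (wholeChannel) H else max(2, floor(w2 / pixelScale))
  uMax <- max(prof@u[prof@y <= (if (wholeChannel) width else w2)])
  if (is.null(dt)) dt <- 8 * pixelScale / uMax      # ms: 8 px at the fastest
  maxDisp <- uMax * dt / pixelScale
  if (maxDisp > min(10, W / 2))
    .rheoflowError("rheoflowConfigError",
                   sprintf("dt gives %.1f px displacement (over the limit)",
                           maxDisp))
  ## seed an upstream margin as wide as the largest displacement so that
  ## fresh particles enter the frame in exposure B instead of wrapping
  margin <- ceiling(maxDisp)
  nP <- round(seedingDensity * layerTopPx * (W + margin))
  sigma <- particleDiameterPx / 2
  ramp <- if (rampFraction > 0)
    matrix(seq(1 - rampFraction / 2, 1 + rampFraction / 2,
               length.out = W), H, W, byrow = TRUE)
  else 1

  pairs <- vector("list", nPairs)
  for (k in seq_len(nPairs)) {
    ry <- stats::runif(nP, 0.5, layerTopPx + 0.5)
    rx <- stats::runif(nP, 0.5 - margin, W + 0.5)
    amp <- stats::runif(nP, 100, 140)
    yUm <- (ry - 0.5) * pixelScale
    disp <- uFun(yUm) * dt / pixelScale
    rxB <- rx + disp
    a <- .renderSpots(H, W, ry, rx, amp, sigma) * ramp +
      matrix(stats::rnorm(H * W, 0, noiseSigma), H, W)
    b <- .renderSpots(H, W, ry, rxB, amp, sigma) * ramp +
      matrix(stats::rnorm(H * W, 0, noiseSigma), H, W)
    pairs[[k]] <- particleImagePair(pmax(a, 0), pmax(b, 0), dt, pixelScale)
  }
  yTab <- (seq_len(H) - 0.5) * pixelScale
  list(pairs = pairs, dt = dt, pixelScale = pixelScale,
       truth = data.frame(y_um = yTab, u_mm_s = uFun(yTab),
                          displacement_px = uFun(yTab) * dt / pixelScale))
}

## ---------------------------------------------------------------------------
## Aggregate-scene generation
## ---------------------------------------------------------------------------

## Rasterize one object into a logical mask over the full frame.
## Returns NULL when the object falls outside the frame.
.rasterObject <- function(shape, H, W, cy, cx, sizePar, rng) {
  mask <- matrix(FALSE, H, W)
  if (shape == "disk") {
    r <- sizePar
    ri <- max(1, floor(cy - r - 1)):min(H, ceiling(cy + r + 1))
    ci <- max(1, floor(cx - r - 1)):min(W, ceiling(cx + r + 1))
    ri <- ri[ri >= 1 & ri <= H]; ci <- ci[ci >= 1 & ci <= W]
    if (!length(ri) || !length(ci)) return(NULL)
    sub <- outer(ri - cy, ci - cx, function(a, b) a^2 + b^2 <= r^2)
    mask[ri, ci] <- sub
  } else if (shape == "rouleau") {
    ## chain of overlapping ellipses: long axis perpendicular to the chain,
    ## like a stack of coins seen edge-on
    k <- sizePar$k
    aAx <- sizePar$a; bAx <- sizePar$b
    theta <- sizePar$theta
    step <- 1.4 * bAx
    jitter <- sizePar$jitter
    for (e in seq_len(k)) {
      t <- (e - (k + 1) / 2) * step
      ecy <- cy + t * sin(theta) + jitter[e, 1]
      ecx <- cx + t * cos(theta) + jitter[e, 2]
      phi <- theta + pi / 2 + jitter[e, 3]
      ext <- aAx + 2
      rlo <- max(1, floor(ecy - ext)); rhi <- min(H, ceiling(ecy + ext))
      clo <- max(1, floor(ecx - ext)); chi <- min(W, ceiling(ecx + ext))
      if (rlo > rhi || clo > chi) next
      ri <- rlo:rhi; ci <- clo:chi
      dy <- outer(ri - ecy, rep(1, length(ci)))
      dx <- outer(rep(1, length(ri)), ci - ecx)
      xr <- dx * cos(phi) + dy * sin(phi)
      yr <- -dx * sin(phi) + dy * cos(phi)
      mask[ri, ci] <- mask[ri, ci] | (xr^2 / aAx^2 + yr^2 / bAx^2 <= 1)
    }
  } else {                                 # cluster: connected union of disks
    nd <- sizePar$n; rd <- sizePar$r
    for (d in seq_len(nd)) {
      dcy <- cy + sizePar$offY[d]; dcx <- cx + sizePar$offX[d]
      rlo <- max(1, floor(dcy - rd - 1)); rhi <- min(H, ceiling(dcy + rd + 1))
      clo <- max(1, floor(dcx - rd - 1)); chi <- min(W, ceiling(dcx + rd + 1))
      if (rlo > rhi || clo > chi) next
      ri <- rlo:rhi; ci <- clo:chi
      mask[ri, ci] <- mask[ri, ci] |
        outer(ri - dcy, ci - dcx, function(a, b) a^2 + b^2 <= rd^2)
    }
  }
  if (!any(mask)) NULL else mask
}

#' Generate bright-field frames of flowing RBC aggregates with ground truth
#'
#' Renders dark aggregate-shaped objects (disks, rouleaux as chains of
#' overlapping ellipses, clusters as unions of disks) on a bright
#' background with a multiplicative illumination ramp and additive Gaussian
#' noise.  Frames are statistically independent (objects are re-drawn each
#' frame; the analysis chain does no tracking).  Object placement keeps a
#' minimum separation at low packing; at area fractions above 0.25 limited
#' overlap is allowed, emulating the crowding that makes single-frame
#' sizing ill-posed at higher hematocrit.
#'
#' @param nFrames number of frames (default 50).
#' @param frameShape integer length 2, frame size in pixels (default
#'   300 x 640, i.e. 60 x 128 um at 0.2 um/px — the transverse extent of
#'   the recorded strip).
#' @param areaFraction target fraction of the frame covered by objects (a
#'   hematocrit proxy; default 0.05).  Must be < 0.5.
#' @param shapeMix named probabilities for `disk`, `rouleau`, `cluster`.
#' @param sizeDistribution list describing the disk-equivalent area
#'   distribution: `meanlog` and `sdlog` of a log-normal in um^2 (default
#'   meanlog log(300), sdlog 0.6 — spanning single cells to large
#'   aggregates).
#' @param illuminationRampFraction total relative variation of the
#'   multiplicative illumination across the frame (default 0.2).
#' @param noiseSigma additive Gaussian noise sigma (default 4 on the
#'   0-255-like scale; background 200, objects near 70).
#' @param pixelScale um per pixel (default 0.2).
#' @param minSeparationPx minimum bounding-box separation between objects
#'   (default 3).
#' @param seed integer RNG seed.
#' @return list with `stack` ([FrameStack-class]) and `truth`
#'   ([AggregateSceneTruth-class]); `truth@objects` holds one row per
#'   rendered object with its rasterized true area in um^2.
#' @export
genAggregateFrames <- function(nFrames = 50, frameShape = c(300, 640),
                               areaFraction = 0.05,
                               shapeMix = c(disk = 0.4, rouleau = 0.4,
                                            cluster = 0.2),
                               sizeDistribution = list(meanlog = log(300),
                                                       sdlog = 0.6),
                               illuminationRampFraction = 0.2,
                               noiseSigma = 4, pixelScale = 0.2,
                               minSeparationPx = 3, seed = 1L) {
  if (areaFraction >= 0.5)
    .rheoflowError("rheoflowConfigError",
                   "areaFraction >= 0.5 makes single-frame sizing ill-posed")
  set.seed(seed)
  H <- frameShape[1]; W <- frameShape[2]
  bg <- 200; objLevel <- 70
  ramp <- matrix(seq(1 - illuminationRampFraction / 2,
                     1 + illuminationRampFraction / 2, length.out = W),
                 H, W, byrow = TRUE)
  allowOverlap <- areaFraction > 0.25
  frames <- vector("list", nFrames)
  objRows <- list()
  for (f in seq_len(nFrames)) {
    occupied <- matrix(FALSE, H, W)
    sceneMask <- matrix(FALSE, H, W)
    targetPx <- areaFraction * H * W
    placedPx <- 0
    objIdx <- 0
    while (placedPx < targetPx) {
      shape <- sample(names(shapeMix), 1, prob = shapeMix)
      targetAreaUm2 <- stats::rlnorm(1, sizeDistribution$meanlog,
                                     sizeDistribution$sdlog)
      targetPxArea <- targetAreaUm2 / pixelScale^2
      sizePar <- switch(shape,
        disk = sqrt(targetPxArea / pi),
        rouleau = {
          bAx <- 6; aAx <- 20   # half-axes px: 8 um long axis at 0.2 um/px
          k <- max(3, min(20, round(targetPxArea / (1.4 * bAx * 2 * aAx))))
          list(k = k, a = aAx, b = bAx, theta = stats::runif(1, 0, pi),
               jitter = matrix(stats::rnorm(3 * k, 0, c(1, 1, 0.08)),
                               k, 3, byrow = TRUE))
        },
        cluster = {
          rd <- 10
          nd <- max(5, min(40, round(targetPxArea / (pi * rd^2) * 2)))
          ## overlapping random walk of disks: each disk touches the
          ## previous one, so the union is always connected
          offY <- numeric(nd); offX <- numeric(nd)
          for (d in seq_len(nd)[-1]) {
            ang <- stats::runif(1, 0, 2 * pi)
            ## head back towards the seed disk when the walk strays, so the
            ## blob stays compact; the step length (< 2 r) keeps it connected
            if (sqrt(offY[d - 1]^2 + offX[d - 1]^2) > 4 * rd)
              ang <- atan2(-offY[d - 1], -offX[d - 1]) +
                stats::rnorm(1, 0, 0.5)
            stp <- stats::runif(1, 0.7, 1.3) * rd
            offY[d] <- offY[d - 1] + stp * sin(ang)
            offX[d] <- offX[d - 1] + stp * cos(ang)
          }
          list(n = nd, r = rd, offY = offY, offX = offX)
        })
      ok <- FALSE
      for (try in 1:50) {
        cy <- stats::runif(1, 10, H - 10); cx <- stats::runif(1, 10, W - 10)
        mask <- .rasterObject(shape, H, W, cy, cx, sizePar, NULL)
        if (is.null(mask)) next
        ## dilate by the separation margin via bounding box test
        bb <- which(mask, arr.ind = TRUE)
        r0 <- max(1, min(bb[, 1]) - minSeparationPx)
        r1 <- min(H, max(bb[, 1]) + minSeparationPx)
        c0 <- max(1, min(bb[, 2]) - minSeparationPx)
        c1 <- min(W, max(bb[, 2]) + minSeparationPx)
        if (!any(occupied[r0:r1, c0:c1]) || allowOverlap) { ok <- TRUE; break }
      }
      if (!ok) {
        if (placedPx / (H * W) > 0.8 * areaFraction) break
        .rheoflowError("rheoflowGenerationError",
                       "could not place objects at the requested area fraction")
      }
      occupied <- occupied | mask
      sceneMask <- sceneMask | mask
      objIdx <- objIdx + 1
      px <- sum(mask)
      placedPx <- placedPx + px
      objRows[[length(objRows) + 1]] <-
        data.frame(frame = f, shape = shape,
                   trueAreaUm2 = px * pixelScale^2,
                   centroidRow = mean(which(mask, arr.ind = TRUE)[, 1]),
                   centroidCol = mean(which(mask, arr.ind = TRUE)[, 2]))
    }
    soft <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(sceneMask * 1), sigma = 1)))
    frame <- (bg - (bg - objLevel) * pmin(soft, 1)) * ramp +
      matrix(stats::rnorm(H * W, 0, noiseSigma), H, W)
    frames[[f]] <- pmax(frame, 0)
  }
  objects <- if (length(objRows)) do.call(rbind, objRows) else
    data.frame(frame = integer(0), shape = character(0),
               trueAreaUm2 = numeric(0), centroidRow = numeric(0),
               centroidCol = numeric(0))
  objects$sizeClass <- findInterval(objects$trueAreaUm2,
                                    c(0, 100, 500, 1500, 3500, Inf))
  truth <- new("AggregateSceneTruth", objects = objects,
               illumination = list(rampFraction = illuminationRampFraction),
               noiseSigma = noiseSigma, seed = seed)
  list(stack = frameStack(frames, pixelScale = pixelScale), truth = truth)
}

#' Generate viscosity-shear samples from a rheological model
#'
#' Evaluates the requested model at log-spaced shear rates and optionally
#' perturbs the viscosities with seeded multiplicative noise.  Generator
#' parameters are embedded in the curve metadata.
#'
#' @param model `"powerlaw"` or `"carreau"`.
#' @param parameters named list/vector: `K`, `n` for the power law;
#'   `mu0`, `muInf`, `lambda`, `n` for Carreau.
#' @param gammaRange length-2 positive range of shear rates (1/s).
#' @param m number of samples (at least 5).
#' @param noise `"none"` (default), `"lognormal"` (`mu * exp(sigma * Z)`)
#'   or `"gaussian"` (`mu * (1 + sigma * Z)`).
#' @param noiseSigma noise magnitude.
#' @param plasmaViscosity,hematocrit,temperature optional curve metadata.
#' @param seed integer RNG seed.
#' @return a [ViscosityCurve-class].
#' @examples
#' cv <- genViscositySamples("powerlaw", list(K = 50.9, n = 0.156),
#'                           c(1, 50), m = 40)
#' fitPowerLaw(cv)
#' @export
genViscositySamples <- function(model = c("powerlaw", "carreau"), parameters,
                                gammaRange = c(1, 50), m = 40,
                                noise = c("none", "lognormal", "gaussian"),
                                noiseSigma = 0.05,
                                plasmaViscosity = NA_real_,
                                hematocrit = NA_real_,
                                temperature = NA_real_, seed = 1L) {
  model <- match.arg(model)
  noise <- match.arg(noise)
  if (m < 5)
    .rheoflowError("rheoflowConfigError", "m must be at least 5")
  if (any(gammaRange <= 0))
    .rheoflowError("rheoflowConfigError", "gammaRange must be positive")
  p <- as.list(parameters)
  g <- exp(seq(log(gammaRange[1]), log(gammaRange[2]), length.out = m))
  mu <- if (model == "powerlaw")
    powerLawViscosity(g, p$K, p$n)
  else
    carreauViscosity(g, p$mu0, p$muInf, p$lambda, p$n)
  if (noise != "none") {
    set.seed(seed)
    z <- stats::rnorm(m)
    mu <- if (noise == "lognormal") mu * exp(noiseSigma * z)
          else mu * (1 + noiseSigma * z)
  }
  viscosityCurve(g, mu, plasmaViscosity = plasmaViscosity,
                 hematocrit = hematocrit, temperature = temperature,
                 meta = list(model = model, parameters = p,
                             gammaRange = gammaRange, noise = noise,
                             noiseSigma = noiseSigma, seed = seed))
}
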