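#' @import methods
NULL

## ---------------------------------------------------------------------------
## Channel geometry and co-flow problem containers
## ---------------------------------------------------------------------------

#' ChannelGeometry: rectangular microchannel with a stratified two-fluid split
#'
#' Describes a rectangular channel of width `w` (the direction along which the
#' two co-flowing streams are stacked) and depth `h`, together with the
#' position of the fluid-fluid interface.  The interface is stored as the
#' dimensionless coordinate `Y`, referenced to the channel centerline across
#' the width, so that `Y = 1/2 - w1/w` where `w1` is the width occupied by the
#' reference stream.  By this convention the reference fluid (fluid 1)
#' occupies the side `y > Y`, `Y = 0` means equal stream widths, and
#' `Y -> +0.5` means the reference stream vanishes.
#'
#' @slot width numeric, channel width w in micrometres.
#' @slot depth numeric, channel depth h in micrometres.
#' @slot interfaceY numeric, dimensionless interface position in (-0.5, 0.5).
#' @export
setClass("ChannelGeometry",
  representation(width = "numeric", depth = "numeric", interfaceY = "numeric"),
  prototype(width = 110, depth = 60, interfaceY = 0)
)

setValidity("ChannelGeometry", function(object) {
  msg <- character(0)
  if (length(object@width) != 1 || !is.finite(object@width) || object@width <= 0)
    msg <- c(msg, "width must be a single positive finite number")
  if (length(object@depth) != 1 || !is.finite(object@depth) || object@depth <= 0)
    msg <- c(msg, "depth must be a single positive finite number")
  if (length(object@interfaceY) != 1 || !is.finite(object@interfaceY) ||
      object@interfaceY <= -0.5 || object@interfaceY >= 0.5)
    msg <- c(msg, "interfaceY must lie strictly inside (-0.5, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelGeometry
#'
#' Either `interfaceY` or `widthRef` (the width of the reference stream, in
#' micrometres) may be given; they are deterministic functions of one another,
#' `Y = 1/2 - w1/w`.
#'
#' @param width channel width in micrometres (default 110).
#' @param depth channel depth in micrometres (default 60).
#' @param interfaceY dimensionless interface position in (-0.5, 0.5).
#' @param widthRef width of the reference stream in micrometres; used to set
#'   `interfaceY` when the latter is missing.
#' @return A [ChannelGeometry-class] object.
#' @examples
#' geom <- channelGeometry(width = 110, depth = 60, widthRef = 55)
#' interfaceY(geom)  # 0
#' @export
channelGeometry <- function(width = 110, depth = 60, interfaceY = NULL,
                            widthRef = NULL) {
  if (is.null(interfaceY)) {
    if (is.null(widthRef)) interfaceY <- 0
    else interfaceY <- 0.5 - widthRef / width
  }
  new("ChannelGeometry", width = as.numeric(width), depth = as.numeric(depth),
      interfaceY = as.numeric(interfaceY))
}

#' SeriesSettings: truncation control for the stratified-flow series
#'
#' @slot maxTerms integer, maximum number of odd series terms.
#' @slot relTol numeric, relative truncation tolerance on the partial sums.
#' @export
setClass("SeriesSettings",
  representation(maxTerms = "numeric", relTol = "numeric"),
  prototype(maxTerms = 400, relTol = 1e-12)
)

setValidity("SeriesSettings", function(object) {
  if (object@maxTerms < 1) return("maxTerms must be >= 1")
  if (object@relTol <= 0) return("relTol must be > 0")
  TRUE
})

#' Construct SeriesSettings
#' @param maxTerms maximum number of odd series terms (default 400).
#' @param relTol relative truncation tolerance (default 1e-12).
#' @return A [SeriesSettings-class] object.
#' @export
seriesSettings <- function(maxTerms = 400, relTol = 1e-12) {
  new("SeriesSettings", maxTerms = maxTerms, relTol = relTol)
}

#' CoflowProblem: one co-flow viscometry measurement
#'
#' @slot muRef numeric, viscosity of the reference fluid (cP).
#' @slot muTest numeric, viscosity of the test fluid (cP); `NA` until solved.
#' @slot qRef numeric, flow rate of the reference fluid (uL/hr).
#' @slot qTest numeric, flow rate of the test fluid (uL/hr).
#' @slot pressureGradient numeric, axial pressure gradient (Pa/m), optional.
#' @export
setClass("CoflowProblem",
  representation(muRef = "numeric", muTest = "numeric",
                 qRef = "numeric", qTest = "numeric",
                 pressureGradient = "numeric"),
  prototype(muTest = NA_real_, pressureGradient = NA_real_)
)

setValidity("CoflowProblem", function(object) {
  msg <- character(0)
  if (!is.finite(object@muRef) || object@muRef <= 0)
    msg <- c(msg, "muRef must be positive")
  if (!is.na(object@muTest) && object@muTest <= 0)
    msg <- c(msg, "muTest must be positive when set")
  if (!is.finite(object@qRef) || object@qRef <= 0 ||
      !is.finite(object@qTest) || object@qTest <= 0)
    msg <- c(msg, "flow rates must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a CoflowProblem
#' @param muRef reference-fluid viscosity (cP).
#' @param qRef,qTest flow rates of the reference and test streams (uL/hr).
#' @param muTest test-fluid viscosity (cP) if already known.
#' @param pressureGradient axial pressure gradient (Pa/m), optional.
#' @return A [CoflowProblem-class] object.
#' @export
coflowProblem <- function(muRef, qRef, qTest, muTest = NA_real_,
                          pressureGradient = NA_real_) {
  new("CoflowProblem", muRef = muRef, muTest = muTest,
      qRef = qRef, qTest = qTest, pressureGradient = pressureGradient)
}

#' DuctField: a two-fluid axial velocity field on a rectangular cross-section
#'
#' @slot gridY numeric, transverse positions across the width (um), centered.
#' @slot gridZ numeric, positions across the depth (um), centered.
#' @slot velocity matrix, axial velocity u(y, z) in mm/s (rows follow gridY).
#' @slot viscosityMap matrix, viscosity at each node (cP).
#' @slot flowRate1 numeric, reference-stream flow rate (uL/hr).
#' @slot flowRate2 numeric, test-stream flow rate (uL/hr).
#' @slot geometry ChannelGeometry used to build the field.
#' @export
setClass("DuctField",
  representation(gridY = "numeric", gridZ = "numeric",
                 velocity = "matrix", viscosityMap = "matrix",
                 flowRate1 = "numeric", flowRate2 = "numeric",
                 geometry = "ChannelGeometry")
)

setValidity("DuctField", function(object) {
  d <- dim(object@velocity)
  if (d[1] != length(object@gridY) || d[2] != length(object@gridZ))
    return("velocity dimensions must match gridY x gridZ")
  if (!all(dim(object@viscosityMap) == d))
    return("viscosityMap must match velocity dimensions")
  TRUE
})

## ---------------------------------------------------------------------------
## Velocimetry containers
## ---------------------------------------------------------------------------

#' ParticleImagePair: one tracer-particle frame pair for PIV
#'
#' @slot frameA,frameB matrix, intensity images (rows = transverse y,
#'   columns = streamwise x).
#' @slot dt numeric, inter-frame time in milliseconds.
#' @slot pixelScale numeric, micrometres per pixel.
#' @export
setClass("ParticleImagePair",
  representation(frameA = "matrix", frameB = "matrix",
                 dt = "numeric", pixelScale = "numeric")
)

setValidity("ParticleImagePair", function(object) {
  if (!identical(dim(object@frameA), dim(object@frameB)))
    return("frameA and frameB must have identical shapes")
  if (object@dt <= 0) return("dt must be positive")
  if (object@pixelScale <= 0) return("pixelScale must be positive")
  TRUE
})

#' Construct a ParticleImagePair
#' @param frameA,frameB intensity matrices of identical shape.
#' @param dt inter-frame time (ms).
#' @param pixelScale micrometres per pixel.
#' @return A [ParticleImagePair-class] object.
#' @export
particleImagePair <- function(frameA, frameB, dt, pixelScale) {
  new("ParticleImagePair", frameA = frameA, frameB = frameB,
      dt = dt, pixelScale = pixelScale)
}

#' VectorField: displacement (or velocity) vectors on a PIV interrogation grid
#'
#' @slot gridRow,gridCol numeric, window-center positions in pixels.
#' @slot dx,dy matrix, streamwise and transverse components.  In pixels after
#'   [pivMultipass()], in mm/s after [displacementToVelocity()].
#' @slot valid logical matrix, FALSE where the vector failed validation.
#' @slot replaced logical matrix, TRUE where the vector was replaced by a
#'   local median (never silently overwritten).
#' @slot units character, `"px"` or `"mm/s"`.
#' @export
setClass("VectorField",
  representation(gridRow = "numeric", gridCol = "numeric",
                 dx = "matrix", dy = "matrix",
                 valid = "matrix", replaced = "matrix", units = "character"),
  prototype(units = "px")
)

setValidity("VectorField", function(object) {
  d <- c(length(object@gridRow), length(object@gridCol))
  for (s in c("dx", "dy", "valid", "replaced"))
    if (!all(dim(slot(object, s)) == d))
      return(sprintf("%s must be a %d x %d matrix", s, d[1], d[2]))
  TRUE
})

#' VelocityProfile: temporally and streamwise averaged transverse profile
#'
#' @slot y numeric, transverse positions (um measured from the test-fluid
#'   side wall).
#' @slot u numeric, mean streamwise velocity (mm/s).
#' @slot rms numeric, root-mean-square fluctuation of the velocity over the
#'   N repeated fields (mm/s), equal to the sample standard deviation.
#' @slot nFields integer, number of fields averaged.
#' @export
setClass("VelocityProfile",
  representation(y = "numeric", u = "numeric", rms = "numeric",
                 nFields = "numeric")
)

setValidity("VelocityProfile", function(object) {
  if (length(object@y) != length(object@u) ||
      length(object@y) != length(object@rms))
    return("y, u and rms must have equal length")
  if (any(object@rms < 0, na.rm = TRUE)) return("rms must be non-negative")
  TRUE
})

#' ShearEstimate: shear rate from the slope of a velocity profile
#'
#' @slot shearRate numeric, slope in 1/s.
#' @slot intercept numeric, fitted intercept (mm/s).
#' @slot fitWindow numeric length 2, transverse window used for the fit (um).
#' @slot rSquared numeric, coefficient of determination of the line fit.
#' @export
setClass("ShearEstimate",
  representation(shearRate = "numeric", intercept = "numeric",
                 fitWindow = "numeric", rSquared = "numeric")
)

## ---------------------------------------------------------------------------
## Aggregate-imaging containers
## ---------------------------------------------------------------------------

#' FrameStack: a bright-field recording of flowing aggregates
#'
#' @slot frames list of intensity matrices sharing one shape.
#' @slot pixelScale numeric, micrometres per pixel.
#' @slot frameRate numeric, frames per second (metadata only).
#' @export
setClass("FrameStack",
  representation(frames = "list", pixelScale = "numeric",
                 frameRate = "numeric"),
  prototype(frameRate = NA_real_)
)

setValidity("FrameStack", function(object) {
  if (length(object@frames) == 0) return("frames must be non-empty")
  d <- dim(object@frames[[1]])
  ok <- vapply(object@frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) return("all frames must share one shape")
  if (object@pixelScale <= 0) return("pixelScale must be positive")
  TRUE
})

#' Construct a FrameStack
#' @param frames list of intensity matrices.
#' @param pixelScale micrometres per pixel (default 0.2).
#' @param frameRate frames per second (metadata).
#' @return A [FrameStack-class] object.
#' @export
frameStack <- function(frames, pixelScale = 0.2, frameRate = NA_real_) {
  new("FrameStack", frames = frames, pixelScale = pixelScale,
      frameRate = frameRate)
}

#' AggregateMask: labeled connected components in one frame
#'
#' @slot labels integer matrix; 0 is background, objects are 1..K.
#' @slot frameIndex integer, provenance.
#' @export
setClass("AggregateMask",
  representation(labels = "matrix", frameIndex = "numeric"),
  prototype(frameIndex = NA_real_)
)

#' AggregateRecord: per-frame and per-recording aggregate size statistics
#'
#' The recording mean is the mean of per-frame means (frames with zero
#' detected aggregates are excluded from the mean-of-means and counted in
#' `nEmptyFrames`), matching a frame-then-recording averaging protocol.
#'
#' @slot perFrameAreas list of numeric vectors, areas (um^2) per frame.
#' @slot perFrameMean numeric, mean area per frame (NA for empty frames).
#' @slot recordingMean numeric, mean of the per-frame means (um^2).
#' @slot recordingStderr numeric, standard error over per-frame means.
#' @slot sizeClassCounts numeric, histogram over configured bins.
#' @slot binEdges numeric, the bin edges used.
#' @slot nEmptyFrames integer, frames with no detected aggregate.
#' @export
setClass("AggregateRecord",
  representation(perFrameAreas = "list", perFrameMean = "numeric",
                 recordingMean = "numeric", recordingStderr = "numeric",
                 sizeClassCounts = "numeric", binEdges = "numeric",
                 nEmptyFrames = "numeric")
)

## ---------------------------------------------------------------------------
## Rheology containers
## ---------------------------------------------------------------------------

#' ViscosityCurve: paired (shear rate, apparent viscosity) samples
#'
#' @slot shearRates numeric, shear rates in 1/s, all positive.
#' @slot viscosities numeric, apparent viscosities (cP), all positive.
#' @slot plasmaViscosity numeric, donor plasma viscosity (cP), optional.
#' @slot hematocrit numeric, percent, metadata.
#' @slot temperature numeric, degrees C, metadata.
#' @slot meta list, free-form provenance (generator parameters, seed, ...).
#' @export
setClass("ViscosityCurve",
  representation(shearRates = "numeric", viscosities = "numeric",
                 plasmaViscosity = "numeric", hematocrit = "numeric",
                 temperature = "numeric", meta = "list"),
  prototype(plasmaViscosity = NA_real_, hematocrit = NA_real_,
            temperature = NA_real_, meta = list())
)

setValidity("ViscosityCurve", function(object) {
  msg <- character(0)
  if (length(object@shearRates) != length(object@viscosities))
    msg <- c(msg, "shearRates and viscosities must have equal length")
  if (any(object@shearRates <= 0)) msg <- c(msg, "shearRates must be positive")
  if (any(object@viscosities <= 0)) msg <- c(msg, "viscosities must be positive")
  if (!is.na(object@plasmaViscosity) && object@plasmaViscosity <= 0)
    msg <- c(msg, "plasmaViscosity must be positive when set")
  if (length(msg)) msg else TRUE
})

#' Construct a ViscosityCurve
#' @param shearRates shear rates (1/s).
#' @param viscosities apparent viscosities (cP).
#' @param plasmaViscosity donor plasma viscosity (cP), optional.
#' @param hematocrit hematocrit percent, metadata.
#' @param temperature temperature in degrees C, metadata.
#' @param meta list of provenance metadata.
#' @return A [ViscosityCurve-class] object.
#' @export
viscosityCurve <- function(shearRates, viscosities,
                           plasmaViscosity = NA_real_,
                           hematocrit = NA_real_, temperature = NA_real_,
                           meta = list()) {
  new("ViscosityCurve", shearRates = as.numeric(shearRates),
      viscosities = as.numeric(viscosities),
      plasmaViscosity = plasmaViscosity, hematocrit = hematocrit,
      temperature = temperature, meta = meta)
}

#' RheologyFit: fitted non-Newtonian model parameters
#'
#' `model` is `"powerlaw"` (parameters `K`, `n`) or `"carreau"` (parameters
#' `mu0`, `muInf`, `lambda`, `n`, with shape parameter `a` fixed at 2 for the
#' Carreau special case).  `rSquared` and `rmse` are always reported on the
#' linear (untransformed) viscosity scale; `rmse` uses `m - p` degrees of
#' freedom where `p` counts the free parameters.
#'
#' @slot model character, `"powerlaw"` or `"carreau"`.
#' @slot parameters numeric, named fitted parameters.
#' @slot fixed numeric, named parameters held fixed (possibly empty).
#' @slot rSquared numeric.
#' @slot rmse numeric, same units as the fitted viscosities.
#' @slot m numeric, number of data points.
#' @slot p numeric, number of free parameters.
#' @slot converged logical.
#' @slot warnings character, attached diagnostics (e.g. negative index n).
#' @export
setClass("RheologyFit",
  representation(model = "character", parameters = "numeric",
                 fixed = "numeric", rSquared = "numeric", rmse = "numeric",
                 m = "numeric", p = "numeric", converged = "logical",
                 warnings = "character"),
  prototype(fixed = setNames(numeric(0), character(0)),
            warnings = character(0))
)

#' GoodnessOfFit: RMSE and R-squared with degrees-of-freedom bookkeeping
#'
#' @slot m numeric, number of data points.
#' @slot p numeric, number of fitted parameters.
#' @slot rmse numeric.
#' @slot rSquared numeric.
#' @export
setClass("GoodnessOfFit",
  representation(m = "numeric", p = "numeric", rmse = "numeric",
                 rSquared = "numeric")
)

## ---------------------------------------------------------------------------
## Synthetic-experiment truth containers
## ---------------------------------------------------------------------------

#' ExperimentTruth: ground truth for one synthetic co-flow experiment
#'
#' @slot geometry ChannelGeometry (interfaceY solved from the flow-rate and
#'   viscosity ratios).
#' @slot muRef,muTest numeric, viscosities (cP).
#' @slot qRef,qTest numeric, flow rates (uL/hr).
#' @slot midPlaneShearRate numeric, 1/s: the ordinary-least-squares slope of
#'   the true mid-depth velocity profile over the central fraction of the
#'   test-fluid (blood) layer — the same windowed-slope definition the
#'   velocimetry stage estimates.
#' @slot pressureGradient numeric, Pa/m.
#' @slot seed numeric, RNG seed that determines all stochastic outputs.
#' @export
setClass("ExperimentTruth",
  representation(geometry = "ChannelGeometry",
                 muRef = "numeric", muTest = "numeric",
                 qRef = "numeric", qTest = "numeric",
                 midPlaneShearRate = "numeric",
                 pressureGradient = "numeric", seed = "numeric")
)

#' AggregateSceneTruth: ground truth for a generated aggregate recording
#'
#' @slot objects data.frame with one row per rendered object: frame, shape
#'   (`disk`, `rouleau`, `cluster`), trueAreaUm2, centroidRow, centroidCol,
#'   sizeClass.
#' @slot illumination list, illumination-field parameters.
#' @slot noiseSigma numeric.
#' @slot seed numeric.
#' @export
setClass("AggregateSceneTruth",
  representation(objects = "data.frame", illumination = "list",
                 noiseSigma = "numeric", seed = "numeric")
)

#' ExperimentConfig: resolved configuration for a pipeline run
#'
#' @slot values list, validated configuration values.
#' @export
setClass("ExperimentConfig", representation(values = "list"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ChannelGeometry", function(object) {
  cat(sprintf("ChannelGeometry: %g x %g um (beta = %.4f), interface Y = %.4f\n",
              object@width, object@depth, object@depth / object@width,
              object@interfaceY))
  cat(sprintf("  reference stream width w1 = %.2f um, test stream w2 = %.2f um\n",
              (0.5 - object@interfaceY) * object@width,
              (0.5 + object@interfaceY) * object@width))
})

setMethod("show", "DuctField", function(object) {
  cat(sprintf("DuctField: %d x %d nodes, u in [0, %.4g] mm/s\n",
              length(object@gridY), length(object@gridZ),
              max(object@velocity)))
  cat(sprintf("  Q1 (reference) = %.4g uL/hr, Q2 (test) = %.4g uL/hr, Q1/Q2 = %.4g\n",
              object@flowRate1, object@flowRate2,
              object@flowRate1 / object@flowRate2))
})

setMethod("show", "VelocityProfile", function(object) {
  cat(sprintf("VelocityProfile: %d transverse points, N = %d fields\n",
              length(object@y), as.integer(object@nFields)))
  cat(sprintf("  u in [%.4g, %.4g] mm/s, median RMS %.4g mm/s\n",
              min(object@u, na.rm = TRUE), max(object@u, na.rm = TRUE),
              stats::median(object@rms, na.rm = TRUE)))
})

setMethod("show", "ShearEstimate", function(object) {
  cat(sprintf("ShearEstimate: %.4g 1/s (fit window %.1f-%.1f um, R^2 = %.4f)\n",
              object@shearRate, object@fitWindow[1], object@fitWindow[2],
              object@rSquared))
})

setMethod("show", "AggregateRecord", function(object) {
  cat(sprintf("AggregateRecord: %d frames (%d empty), recording mean %.4g um^2 (stderr %.3g)\n",
              length(object@perFrameAreas), as.integer(object@nEmptyFrames),
              object@recordingMean, object@recordingStderr))
  if (length(object@sizeClassCounts)) {
    cat("  size classes:",
        paste(names(object@sizeClassCounts), object@sizeClassCounts,
              sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "ViscosityCurve", function(object) {
  cat(sprintf("ViscosityCurve: %d points, shear %.3g-%.3g 1/s, viscosity %.3g-%.3g cP\n",
              length(object@shearRates), min(object@shearRates),
              max(object@shearRates), min(object@viscosities),
              max(object@viscosities)))
  if (!is.na(object@plasmaViscosity))
    cat(sprintf("  plasma viscosity %.3g cP\n", object@plasmaViscosity))
})

setMethod("show", "RheologyFit", function(object) {
  cat(sprintf("RheologyFit [%s]: %s\n", object@model,
              paste(names(object@parameters),
                    signif(object@parameters, 5), sep = " = ",
                    collapse = ", ")))
  cat(sprintf("  R^2 = %.4f, RMSE = %.4g (m = %d, p = %d)%s\n",
              object@rSquared, object@rmse, as.integer(object@m),
              as.integer(object@p),
              if (object@converged) "" else "  [NOT CONVERGED]"))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "ExperimentTruth", function(object) {
  cat(sprintf("ExperimentTruth: muTest/muRef = %.4g, Q1/Q2 = %.4g, Y = %.4f\n",
              object@muTest / object@muRef, object@qRef / object@qTest,
              object@geometry@interfaceY))
  cat(sprintf("  mid-plane blood-layer shear rate %.4g 1/s (seed %d)\n",
              object@midPlaneShearRate, as.integer(object@seed)))
})
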