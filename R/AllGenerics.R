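## Accessor generics.  Slot access from user code is discouraged; these are
## the supported surface.

#' Interface position accessor
#' @param x a ChannelGeometry, DuctField or ExperimentTruth.
#' @return dimensionless interface position Y in (-0.5, 0.5).
#' @export
setGeneric("interfaceY", function(x) standardGeneric("interfaceY"))

#' @rdname interfaceY
#' @export
setMethod("interfaceY", "ChannelGeometry", function(x) x@interfaceY)
#' @rdname interfaceY
#' @export
setMethod("interfaceY", "DuctField", function(x) x@geometry@interfaceY)
#' @rdname interfaceY
#' @export
setMethod("interfaceY", "ExperimentTruth", function(x) x@geometry@interfaceY)

#' Channel aspect ratio beta = depth / width
#' @param x a ChannelGeometry or DuctField.
#' @return dimensionless aspect ratio.
#' @export
setGeneric("aspectRatio", function(x) standardGeneric("aspectRatio"))

#' @rdname aspectRatio
#' @export
setMethod("aspectRatio", "ChannelGeometry", function(x) x@depth / x@width)
#' @rdname aspectRatio
#' @export
setMethod("aspectRatio", "DuctField", function(x) aspectRatio(x@geometry))

#' Flow-rate ratio Q1/Q2 (reference over test)
#' @param x a DuctField or CoflowProblem.
#' @return dimensionless flow-rate ratio.
#' @export
setGeneric("flowRatio", function(x) standardGeneric("flowRatio"))

#' @rdname flowRatio
#' @export
setMethod("flowRatio", "DuctField", function(x) x@flowRate1 / x@flowRate2)
#' @rdname flowRatio
#' @export
setMethod("flowRatio", "CoflowProblem", function(x) x@qRef / x@qTest)

#' Shear rates of a viscosity curve
#' @param x a ViscosityCurve.
#' @return numeric vector (1/s).
#' @export
setGeneric("shearRates", function(x) standardGeneric("shearRates"))
#' @rdname shearRates
#' @export
setMethod("shearRates", "ViscosityCurve", function(x) x@shearRates)

#' Apparent viscosities of a viscosity curve
#' @param x a ViscosityCurve.
#' @return numeric vector (cP).
#' @export
setGeneric("viscosities", function(x) standardGeneric("viscosities"))
#' @rdname viscosities
#' @export
setMethod("viscosities", "ViscosityCurve", function(x) x@viscosities)

#' Donor plasma viscosity of a curve
#' @param x a ViscosityCurve.
#' @return numeric (cP), possibly `NA`.
#' @export
setGeneric("plasmaViscosity", function(x) standardGeneric("plasmaViscosity"))
#' @rdname plasmaViscosity
#' @export
setMethod("plasmaViscosity", "ViscosityCurve", function(x) x@plasmaViscosity)

#' Fitted parameters of a rheology fit
#' @param x a RheologyFit.
#' @return named numeric vector of fitted (free) parameters.
#' @export
setGeneric("fitParameters", function(x) standardGeneric("fitParameters"))
#' @rdname fitParameters
#' @export
setMethod("fitParameters", "RheologyFit", function(x) x@parameters)

#' Shear rate of a shear estimate
#' @param x a ShearEstimate or ExperimentTruth.
#' @return shear rate in 1/s.
#' @export
setGeneric("shearRate", function(x) standardGeneric("shearRate"))
#' @rdname shearRate
#' @export
setMethod("shearRate", "ShearEstimate", function(x) x@shearRate)
#' @rdname shearRate
#' @export
setMethod("shearRate", "ExperimentTruth", function(x) x@midPlaneShearRate)

#' Recording-level mean aggregate area
#' @param x an AggregateRecord.
#' @return mean of per-frame mean areas (um^2).
#' @export
setGeneric("recordingMean", function(x) standardGeneric("recordingMean"))
#' @rdname recordingMean
#' @export
setMethod("recordingMean", "AggregateRecord", function(x) x@recordingMean)

#' Per-frame aggregate areas
#' @param x an AggregateRecord.
#' @return list of numeric vectors (um^2), one per frame.
#' @export
setGeneric("frameAreas", function(x) standardGeneric("frameAreas"))
#' @rdname frameAreas
#' @export
setMethod("frameAreas", "AggregateRecord", function(x) x@perFrameAreas)

#' @describeIn VelocityProfile-class coerce to data.frame with columns
#'   `y_um`, `u_mm_s`, `rms_mm_s`.
#' @param x a VelocityProfile.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "VelocityProfile", function(x, ...) {
  data.frame(y_um = x@y, u_mm_s = x@u, rms_mm_s = x@rms)
})

#' @describeIn ViscosityCurve-class coerce to data.frame with columns
#'   `shear_rate_s1`, `viscosity_cP` (and `relative_viscosity` when a plasma
#'   viscosity is present).
#' @param x a ViscosityCurve.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "ViscosityCurve", function(x, ...) {
  df <- data.frame(shear_rate_s1 = x@shearRates, viscosity_cP = x@viscosities)
  if (!is.na(x@plasmaViscosity))
    df$relative_viscosity <- x@viscosities / x@plasmaViscosity
  df
})
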