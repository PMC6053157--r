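## Plain-text readers and writers for the package's standard artifacts.

#' Read a viscosity curve from CSV
#'
#' Expects columns `shear_rate_s1` and `viscosity_cP`, with optional
#' `plasma_viscosity_cP`, `hematocrit_pct` and `temperature_C` (constant
#' per file).
#'
#' @param path CSV file path.
#' @return a [ViscosityCurve-class].
#' @export
readViscosityCurveCSV <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("shear_rate_s1", "viscosity_cP")
  if (!all(need %in% names(df)))
    .rheoflowError("rheoflowIOError",
                   paste("missing columns:",
                         paste(setdiff(need, names(df)), collapse = ", ")))
  pick1 <- function(col) if (col %in% names(df)) df[[col]][1] else NA_real_
  viscosityCurve(df$shear_rate_s1, df$viscosity_cP,
                 plasmaViscosity = pick1("plasma_viscosity_cP"),
                 hematocrit = pick1("hematocrit_pct"),
                 temperature = pick1("temperature_C"))
}

#' Write a viscosity curve to CSV
#'
#' @param curve a [ViscosityCurve-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeViscosityCurveCSV <- function(curve, path) {
  df <- data.frame(shear_rate_s1 = shearRates(curve),
                   viscosity_cP = viscosities(curve))
  if (!is.na(plasmaViscosity(curve)))
    df$plasma_viscosity_cP <- plasmaViscosity(curve)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a duct velocity field as long-format CSV
#'
#' Columns `y_um`, `z_um`, `u_mm_s`.
#'
#' @param field a [DuctField-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDuctFieldCSV <- function(field, path) {
  stopifnot(is(field, "DuctField"))
  df <- expand.grid(y_um = field@gridY, z_um = field@gridZ)
  df$u_mm_s <- as.vector(field@velocity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic experiment as JSON
#'
#' @param truth an [ExperimentTruth-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTruthSidecar <- function(truth, path) {
  stopifnot(is(truth, "ExperimentTruth"))
  g <- truth@geometry
  jsonlite::write_json(list(
    geometry = list(width_um = g@width, depth_um = g@depth,
                    aspect_beta = g@depth / g@width,
                    interface_Y = g@interfaceY),
    mu_ref_cP = truth@muRef, mu_test_cP = truth@muTest,
    q_ref_uL_hr = truth@qRef, q_test_uL_hr = truth@qTest,
    mid_plane_shear_rate_s1 = truth@midPlaneShearRate,
    pressure_gradient_Pa_m = truth@pressureGradient,
    seed = truth@seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a rheology fit report as JSON
#'
#' @param fit a [RheologyFit-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFitReport <- function(fit, path) {
  stopifnot(is(fit, "RheologyFit"))
  jsonlite::write_json(list(
    model = fit@model,
    parameters = as.list(fit@parameters),
    fixed = as.list(fit@fixed),
    r_squared = fit@rSquared, rmse = fit@rmse,
    m = fit@m, p = fit@p, converged = fit@converged,
    warnings = fit@warnings
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a velocity profile as CSV
#'
#' Columns `y_um`, `u_mm_s`, `rms_mm_s`.
#'
#' @param profile a [VelocityProfile-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVelocityProfileCSV <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
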