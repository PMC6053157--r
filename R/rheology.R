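## Shear-thinning constitutive models and their fitting.
##
## Power law (Ostwald-de Waele): stress tau = K * shearRate^n, hence
## apparent viscosity mu = K * shearRate^(n - 1).  K is the consistency
## index in (viscosity unit) * s^(n-1) of the input curve and n the
## dimensionless behaviour index (n < 1: shear thinning).
##
## Carreau: mu(shearRate) = muInf + (mu0 - muInf) *
## (1 + (lambda * shearRate)^a)^((n - 1) / a), the a = 2 special case of
## the Carreau-Yasuda law; mu0 and muInf are the zero- and infinite-shear
## plateaus, lambda the relaxation time in seconds.

#' Power-law apparent viscosity
#'
#' @param shearRate shear rate(s) in 1/s, strictly positive (the power-law
#'   viscosity diverges at zero shear for n < 1).
#' @param K consistency index, positive.
#' @param n behaviour index.
#' @return apparent viscosity `K * shearRate^(n - 1)`; the shear stress is
#'   the return value times the shear rate.
#' @examples
#' powerLawViscosity(10, K = 50.9, n = 0.156)
#' @export
powerLawViscosity <- function(shearRate, K, n) {
  .checkScalar(K, "K", lower = 0, openLower = TRUE)
  if (any(!is.finite(shearRate)) || any(shearRate <= 0))
    .rheoflowError("rheoflowDomainError",
                   "shearRate must be positive and finite")
  K * shearRate^(n - 1)
}

#' Carreau apparent viscosity
#'
#' @param shearRate shear rate(s) in 1/s; zero is allowed and returns `mu0`.
#' @param mu0 zero-shear viscosity, positive.
#' @param muInf infinite-shear viscosity, positive.
#' @param lambda relaxation time in seconds, non-negative.
#' @param n power-law index.
#' @param a Carreau-Yasuda shape parameter; 2 (the default) gives the
#'   Carreau model.
#' @return apparent viscosity at the given shear rate(s).
#' @examples
#' carreauViscosity(1, mu0 = 118.6, muInf = 2.3, lambda = 3.312, n = 0.362)
#' @export
carreauViscosity <- function(shearRate, mu0, muInf, lambda, n, a = 2) {
  .checkScalar(mu0, "mu0", lower = 0, openLower = TRUE)
  .checkScalar(muInf, "muInf", lower = 0, openLower = TRUE)
  .checkScalar(lambda, "lambda", lower = 0)
  if (any(!is.finite(shearRate)) || any(shearRate < 0))
    .rheoflowError("rheoflowDomainError",
                   "shearRate must be non-negative and finite")
  muInf + (mu0 - muInf) * (1 + (lambda * shearRate)^a)^((n - 1) / a)
}

#' Goodness of fit: RMSE with degrees of freedom, and R-squared
#'
#' `RMSE = sqrt(sum((muExp - muFit)^2) / (m - p))` where `m` is the number
#' of data points and `p` the number of fitted parameters; `R^2 = 1 -
#' SS_res / SS_tot` with `SS_tot` about the mean of `muExp`.
#'
#' @param muExp,muFit numeric vectors of equal length.
#' @param p number of fitted parameters (must be < m).
#' @return a [GoodnessOfFit-class].
#' @examples
#' gof <- goodnessOfFit(c(1, 2, 3), c(1, 2, 4), p = 2)  # RMSE 1
#' @export
goodnessOfFit <- function(muExp, muFit, p) {
  m <- length(muExp)
  if (length(muFit) != m)
    .rheoflowError("rheoflowShapeError", "muExp and muFit must match")
  if (m <= p)
    .rheoflowError("rheoflowDomainError",
                   sprintf("m = %d data points cannot constrain p = %d parameters",
                           m, p))
  ssRes <- sum((muExp - muFit)^2)
  ssTot <- sum((muExp - mean(muExp))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else if (ssRes == 0) 1 else -Inf
  new("GoodnessOfFit", m = m, p = p, rmse = sqrt(ssRes / (m - p)),
      rSquared = r2)
}

#' Relative viscosity
#'
#' Divides the apparent viscosity by the donor-specific plasma viscosity,
#' removing donor-to-donor differences in plasma protein content.
#'
#' @param muApp apparent viscosity (any unit).
#' @param muPlasma plasma viscosity (same unit), strictly positive.
#' @return dimensionless relative viscosity.
#' @examples
#' relativeViscosity(4.38, 2.19)  # 2
#' @export
relativeViscosity <- function(muApp, muPlasma) {
  if (!is.finite(muPlasma) || muPlasma <= 0)
    .rheoflowError("rheoflowDomainError", "muPlasma must be positive")
  muApp / muPlasma
}

#' Fit the power-law model by log-log linear least squares
#'
#' Ordinary least squares of `log(mu)` on `log(shearRate)`: the slope is
#' `n - 1` and the intercept `log(K)`.  R-squared and the RMSE (with p = 2
#' degrees-of-freedom correction) are reported on the linear, untransformed
#' viscosity scale.
#'
#' @param curve a [ViscosityCurve-class] with at least 3 points.
#' @return a [RheologyFit-class] with parameters `K` and `n`.  A warning
#'   string is attached when n < 0.
#' @export
fitPowerLaw <- function(curve) {
  stopifnot(is(curve, "ViscosityCurve"))
  g <- curve@shearRates; mu <- curve@viscosities
  if (length(g) < 3)
    .rheoflowError("rheoflowDomainError", "need at least 3 points")
  bad <- which(g <= 0 | mu <= 0)
  if (length(bad))
    .rheoflowError("rheoflowDomainError",
                   paste("non-positive data at indices",
                         paste(bad, collapse = ", ")))
  fit <- stats::lm(log(mu) ~ log(g))
  n <- unname(stats::coef(fit)[2]) + 1
  K <- exp(unname(stats::coef(fit)[1]))
  muHat <- K * g^(n - 1)
  gof <- goodnessOfFit(mu, muHat, p = 2)
  warn <- if (n < 0) "behaviour index n < 0" else character(0)
  new("RheologyFit", model = "powerlaw",
      parameters = c(K = K, n = n), rSquared = gof@rSquared,
      rmse = gof@rmse, m = gof@m, p = 2, converged = TRUE, warnings = warn)
}

#' Fit the Carreau model by Levenberg-Marquardt nonlinear least squares
#'
#' Minimizes `sum((mu - muCarreau)^2)` with the shape parameter fixed at
#' a = 2.  Positivity of `mu0`, `muInf` and `lambda` is enforced by fitting
#' their logarithms.  The default initialization is data driven: `mu0` at
#' the largest and `muInf` at the smallest observed viscosity, `lambda` at
#' 1 s and `n` at 0.5.  Any of the four parameters may be held fixed, in
#' which case the RMSE degrees of freedom shrink accordingly.
#'
#' @param curve a [ViscosityCurve-class] with at least 5 points.
#' @param init optional named list/vector overriding the default starting
#'   values (`mu0`, `muInf`, `lambda`, `n`).
#' @param fixed optional named numeric vector of parameters to hold fixed,
#'   e.g. `c(lambda = 3.313)`.
#' @param a Carreau-Yasuda shape parameter (default 2; override for the
#'   Carreau-Yasuda generalization).
#' @param maxIter maximum Levenberg-Marquardt iterations.
#' @return a [RheologyFit-class] with parameters `mu0`, `muInf`, `lambda`,
#'   `n` (free parameters in `fitParameters()`, fixed ones in the `fixed`
#'   slot).  Non-convergence raises a fit error carrying the best-so-far
#'   parameters.
#' @export
fitCarreau <- function(curve, init = NULL, fixed = NULL, a = 2,
                       maxIter = 200) {
  stopifnot(is(curve, "ViscosityCurve"))
  g <- curve@shearRates; mu <- curve@viscosities
  pAll <- c("mu0", "muInf", "lambda", "n")
  fixedNames <- names(fixed)
  if (!all(fixedNames %in% pAll))
    .rheoflowError("rheoflowConfigError", "unknown fixed parameter name")
  free <- setdiff(pAll, fixedNames)
  p <- length(free)
  if (length(g) <= p)
    .rheoflowError("rheoflowDomainError",
                   sprintf("need more than %d points", p))

  start <- list(mu0 = max(mu), muInf = min(mu), lambda = 1, n = 0.5)
  if (!is.null(init)) start[names(init)] <- as.list(init)
  if (!is.null(fixed)) start[fixedNames] <- as.list(fixed)

  ## log-transform the positive parameters
  toTheta <- function(vals) {
    th <- c(lmu0 = log(vals$mu0), lmuInf = log(vals$muInf),
            llambda = log(vals$lambda), n = vals$n)
    th[c(mu0 = "lmu0", muInf = "lmuInf", lambda = "llambda",
         n = "n")[free]]
  }
  model <- function(th) {
    vals <- start
    if ("mu0" %in% free) vals$mu0 <- exp(th[["lmu0"]])
    if ("muInf" %in% free) vals$muInf <- exp(th[["lmuInf"]])
    if ("lambda" %in% free) vals$lambda <- exp(th[["llambda"]])
    if ("n" %in% free) vals$n <- th[["n"]]
    vals
  }
  resid <- function(th) {
    v <- model(th)
    mu - (v$muInf + (v$mu0 - v$muInf) *
            (1 + (v$lambda * g)^a)^((v$n - 1) / a))
  }
  out <- minpack.lm::nls.lm(par = toTheta(start), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxIter, ftol = 1e-15,
                              ptol = 1e-15))
  v <- model(out$par)
  pars <- c(mu0 = v$mu0, muInf = v$muInf, lambda = v$lambda, n = v$n)
  converged <- out$info %in% 1:4
  if (!converged)
    .rheoflowError("rheoflowFitError",
                   sprintf("Levenberg-Marquardt did not converge (info %d): %s",
                           out$info, out$message),
                   data = list(parameters = pars,
                               residualNorm = out$deviance))
  muHat <- carreauViscosity(g, v$mu0, v$muInf, v$lambda, v$n, a = a)
  gof <- goodnessOfFit(mu, muHat, p = p)
  warn <- character(0)
  if (v$n < 0) warn <- c(warn, "index n < 0")
  if (v$mu0 <= v$muInf) warn <- c(warn, "mu0 <= muInf: not shear thinning")
  new("RheologyFit", model = "carreau", parameters = pars[free],
      fixed = if (is.null(fixed)) stats::setNames(numeric(0), character(0))
              else unlist(fixed),
      rSquared = gof@rSquared, rmse = gof@rmse, m = gof@m, p = p,
      converged = TRUE, warnings = warn)
}

#' Evaluate a fitted rheology model
#'
#' @param fit a [RheologyFit-class].
#' @param shearRate shear rate(s) in 1/s.
#' @return predicted apparent viscosity.
#' @export
predictViscosity <- function(fit, shearRate) {
  stopifnot(is(fit, "RheologyFit"))
  pars <- c(fit@parameters, fit@fixed)
  if (fit@model == "powerlaw")
    powerLawViscosity(shearRate, pars[["K"]], pars[["n"]])
  else
    carreauViscosity(shearRate, pars[["mu0"]], pars[["muInf"]],
                     pars[["lambda"]], pars[["n"]])
}
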