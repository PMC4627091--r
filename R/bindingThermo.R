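## Two-state binding model.  A fluorogenic aptamer S binds its ligand D to a
## fluorescent complex SD with dissociation constant Kd = [S][D]/[SD]; the
## observed spot signal is proportional to the bound fraction
## (D/Kd)/(1 + D/Kd).  Free energies in kcal/mol, temperatures in kelvin,
## concentrations in uM unless stated otherwise.

#' Fraction of aptamer bound at a given free-ligand concentration
#'
#' @param D ligand concentration(s), uM (>= 0); assumed free (no depletion).
#' @param Kd dissociation constant, uM (> 0).
#' @return bound fraction in `[0, 1)`, strictly increasing in `D`.
#' @export
#' @examples
#' fractionBound(1.18, 1.18)   # half saturation
#' fractionBound(43.5, 1.18)
fractionBound <- function(D, Kd) {
  if (any(Kd <= 0)) .stopf("Kd must be > 0")
  if (any(D < 0)) .stopf("ligand concentration must be >= 0")
  r <- D / Kd
  r / (1 + r)
}

#' Fit the two-state binding isotherm to a titration curve
#'
#' Nonlinear least squares of `signal = amplitude * fractionBound(D, Kd)`
#' (Levenberg-Marquardt on log-parameters, multi-start from three log-spaced
#' Kd initial values, Kd box-bounded to `[0.01 * min(D), 100 * max(D)]`).
#' Fitting the plateau amplitude rather than normalising by the
#' highest-concentration signal avoids the low bias that arises when the top
#' concentration is only a few tens of Kd; `normalizeAtMax = TRUE` restores
#' the normalise-by-top-point convention (amplitude fixed at 1 on the
#' normalised scale).
#'
#' Curves whose maximum absolute signal is below `minSignal` are flagged
#' `non_fluorogenic` and carry no Kd.
#'
#' @param conc ligand concentrations, uM, strictly ascending.
#' @param signal normalised spot signals, same length.
#' @param temperature optional temperature (kelvin) annotation.
#' @param normalizeAtMax logical; normalise signals to the top-concentration
#'   point and fix the amplitude (compatibility mode).
#' @param minSignal non-fluorogenic threshold on `max(abs(signal))`.
#' @return a [BindingFit].
#' @export
#' @examples
#' D <- dfhbiSeries()
#' y <- 0.8 * fractionBound(D, 1.18)
#' fitBinding(D, y)
fitBinding <- function(conc, signal, temperature = NA_real_,
                       normalizeAtMax = FALSE, minSignal = 0.02) {
  conc <- as.numeric(conc); signal <- as.numeric(signal)
  if (length(conc) != length(signal))
    .stopf("conc and signal must have the same length")
  keep <- is.finite(conc) & is.finite(signal)
  conc <- conc[keep]; signal <- signal[keep]
  if (length(conc) < 4L)
    .stopf("need >= 4 finite titration points, got %d", length(conc))
  if (any(diff(conc) <= 0)) .stopf("concentrations must be strictly ascending")
  if (any(conc <= 0)) .stopf("concentrations must be positive")

  blank <- function(flags) new("BindingFit",
    Kd = NA_real_, KdStderr = NA_real_, amplitude = NA_real_,
    amplitudeStderr = NA_real_, converged = FALSE, flags = flags,
    residualNorm = NA_real_, nPoints = length(conc),
    temperature = as.numeric(temperature))

  if (max(abs(signal)) < minSignal) return(blank("non_fluorogenic"))

  if (normalizeAtMax) {
    top <- signal[length(signal)]
    if (abs(top) < .Machine$double.eps) return(blank("undefined_normalization"))
    signal <- signal / top
  }

  kdLower <- 0.01 * min(conc); kdUpper <- 100 * max(conc)
  starts <- exp(seq(log(min(conc)), log(max(conc)), length.out = 3L))
  ampStart <- max(signal)
  if (ampStart <= 0) ampStart <- max(abs(signal))

  resid <- if (normalizeAtMax) {
    function(p) fractionBound(conc, exp(p[1])) - signal
  } else {
    function(p) exp(p[2]) * fractionBound(conc, exp(p[1])) - signal
  }

  best <- NULL
  for (k0 in starts) {
    p0 <- if (normalizeAtMax) log(k0) else c(log(k0), log(ampStart))
    lo <- if (normalizeAtMax) log(kdLower) else c(log(kdLower), log(1e-8))
    hi <- if (normalizeAtMax) log(kdUpper) else c(log(kdUpper), log(1e8))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lo, upper = hi, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(blank("non_converged"))

  p <- best$par
  Kd <- exp(p[1])
  amplitude <- if (normalizeAtMax) 1 else exp(p[2])
  ## standard errors via the delta method from the log-scale covariance
  np <- length(p)
  dof <- length(conc) - np
  se <- rep(NA_real_, np)
  if (dof > 0) {
    covLog <- tryCatch({
      s2 <- best$deviance / dof
      s2 * solve(best$hessian)
    }, error = function(e) NULL)
    if (!is.null(covLog)) se <- sqrt(pmax(diag(covLog), 0))
  }
  converged <- best$info %in% 1:4
  new("BindingFit",
      Kd = Kd, KdStderr = Kd * se[1],
      amplitude = amplitude,
      amplitudeStderr = if (normalizeAtMax) 0 else amplitude * se[2],
      converged = converged,
      flags = if (converged) character() else "non_converged",
      residualNorm = best$deviance, nPoints = length(conc),
      temperature = as.numeric(temperature))
}

#' Mutant-vs-wild-type binding free energy difference
#'
#' Computes the binding free energy change of a mutant relative to wild type
#' from the ratio of dissociation constants.  Under the default
#' `"favorable_negative"` convention a tighter-binding mutant (smaller Kd)
#' has negative ddG (`R T ln(Kd_m / Kd_wt)`); `"as_printed"` returns the
#' negation (positive for tighter binders).  Antisymmetric under swapping
#' the two Kd values.
#'
#' @param KdM,KdWt mutant and wild-type dissociation constants (same unit,
#'   both > 0; the unit cancels in the ratio).
#' @param temperature kelvin.
#' @param sign `"favorable_negative"` (default) or `"as_printed"`.
#' @return ddG in kcal/mol.
#' @export
#' @examples
#' deltaDeltaG(0.45, 1.18, 296.15)   # tighter binder, negative
deltaDeltaG <- function(KdM, KdWt, temperature,
                        sign = c("favorable_negative", "as_printed")) {
  sign <- match.arg(sign)
  if (any(KdM <= 0) || any(KdWt <= 0)) .stopf("Kd values must be > 0")
  if (any(temperature <= 0)) .stopf("temperature must be > 0 kelvin")
  v <- .R_KCAL * temperature * log(KdM / KdWt)
  if (sign == "as_printed") -v else v
}

#' Van't Hoff regression of Kd against temperature
#'
#' Ordinary least squares of `ln Kd` (molar) on `1/T`.  Under the default
#' `"binding"` convention the dissociation-direction identity
#' `ln Kd = dH/(R T) - dS/R` is used, so `dH = R * slope` and
#' `dS = -R * intercept` are the binding (association) enthalpy and entropy,
#' with `dH < 0` meaning exothermic binding (Kd rises with temperature).
#' The `"as_printed"` convention applies the association-form relation
#' `ln K = -dH/(R T) + dS/R` literally to Kd (`dH = -R * slope`,
#' `dS = R * intercept`), i.e. it reports the unfolding-direction signs;
#' the two conventions differ only by an overall sign on both coefficients.
#'
#' The standard-state unit of Kd affects only dS (by `R ln c` for a unit
#' rescaling by `c`), never dH; molar is used, fixed.
#'
#' @param temperature kelvin, >= 2 distinct values.
#' @param Kd dissociation constants, uM.
#' @param convention `"binding"` (default) or `"as_printed"`.
#' @return a [VantHoffFit] (dH kcal/mol, dS kcal/(mol K)).
#' @export
#' @examples
#' Tk <- celsiusToKelvin(c(19, 23, 28))
#' Kd <- kdAtTemperature(Tk, KdRef = 1.18, dH = -9, Tref = 296.15)
#' vantHoff(Tk, Kd)
vantHoff <- function(temperature, Kd,
                     convention = c("binding", "as_printed")) {
  convention <- match.arg(convention)
  keep <- is.finite(temperature) & is.finite(Kd)
  temperature <- temperature[keep]; Kd <- Kd[keep]
  if (length(unique(temperature)) < 2L)
    .stopf("Van't Hoff regression needs >= 2 distinct temperatures")
  if (any(Kd <= 0) || any(temperature <= 0))
    .stopf("temperatures and Kd must be positive")
  invT <- 1 / temperature
  lnK <- log(Kd * 1e-6)               # uM -> molar before logging
  fit <- lm(lnK ~ invT)
  cf <- coef(fit)
  ## suppressWarnings: summary.lm warns on numerically perfect fits, which
  ## are routine here (noiseless simulations)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  r2 <- if (length(lnK) > 2L)
    suppressWarnings(summary(fit)$r.squared) else 1
  if (convention == "binding") {
    dH <- .R_KCAL * cf[[2]]; dS <- -.R_KCAL * cf[[1]]
  } else {
    dH <- -.R_KCAL * cf[[2]]; dS <- .R_KCAL * cf[[1]]
  }
  new("VantHoffFit", dH = dH, dS = dS,
      dHStderr = .R_KCAL * se[[2]], dSStderr = .R_KCAL * se[[1]],
      rSquared = r2, n = length(lnK), convention = convention)
}

#' Dissociation constant at a temperature from (KdRef, dH)
#'
#' Evaluates the Van't Hoff temperature dependence under the `"binding"`
#' convention: `ln Kd(T) = ln Kd(Tref) + (dH/R) (1/T - 1/Tref)`.  Exothermic
#' binding (`dH < 0`) gives Kd increasing with temperature.
#'
#' @param temperature kelvin.
#' @param KdRef Kd at `Tref`, uM.
#' @param dH binding enthalpy, kcal/mol (negative = exothermic).
#' @param Tref reference temperature, kelvin (default 296.15 = 23 C).
#' @return Kd at `temperature`, uM.
#' @export
kdAtTemperature <- function(temperature, KdRef, dH, Tref = 296.15) {
  if (any(temperature <= 0) || Tref <= 0) .stopf("temperatures must be > 0")
  KdRef * exp((dH / .R_KCAL) * (1 / temperature - 1 / Tref))
}

#' The default DFHBI titration series
#'
#' Twelve concentrations log-spaced over 0.435-43.5 uM, the two-decade
#' window used for chip titrations.
#'
#' @param n number of points (default 12).
#' @param minConc,maxConc series end points, uM.
#' @return numeric vector, strictly ascending.
#' @export
#' @examples
#' dfhbiSeries()
dfhbiSeries <- function(n = 12L, minConc = 0.435, maxConc = 43.5) {
  exp(seq(log(minConc), log(maxConc), length.out = n))
}
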