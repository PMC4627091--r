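## Two-state unfolding of the aptamer-ligand complex.  The folded fraction
## follows 1 / (1 + exp((dH_T/R) (1/Tm - 1/T))) with apparent melting
## temperature Tm = dH_T/dS_T; the observed melt signal is amplitude times
## that fraction.  Note the model's high-temperature asymptote is
## 1 / (1 + exp(dH_T / (R Tm))), small but not exactly zero.

#' Fraction of folded complex at a temperature
#'
#' @param temperature kelvin (> 0).
#' @param Tm apparent melting temperature, kelvin (> 0).
#' @param dHT unfolding enthalpy, kcal/mol (> 0 for a cooperative melt).
#' @return folded fraction; equals 0.5 at `temperature = Tm`, strictly
#'   decreasing in temperature for `dHT > 0`.
#' @export
#' @examples
#' fractionFolded(315, 315, 50)   # 0.5
#' fractionFolded(325, 315, 50)
fractionFolded <- function(temperature, Tm, dHT) {
  if (any(temperature <= 0) || any(Tm <= 0))
    .stopf("temperatures must be > 0 kelvin")
  1 / (1 + exp((dHT / .R_KCAL) * (1 / Tm - 1 / temperature)))
}

#' Fit the two-state melting model to a melt curve
#'
#' Nonlinear least squares of `signal = amplitude * fractionFolded(T, Tm,
#' dHT)`.  By default the amplitude is a free parameter; `amplitudeMode =
#' "anchor"` fixes it to the lowest-temperature signal (the normalisation
#' the chip assay uses for monotone melts; the free mode is robust when the
#' first point is noisy).  Curves with no decreasing transition in range are
#' flagged `no_transition`; rise-then-fall profiles are additionally flagged
#' via [detectBimodal()].
#'
#' @param temperature kelvin, strictly ascending, >= 5 points.
#' @param signal normalised spot signals.
#' @param amplitudeMode `"free"` (default) or `"anchor"`.
#' @param minSignal non-fluorogenic threshold on `max(abs(signal))`.
#' @return a [MeltFit].
#' @export
#' @examples
#' Tk <- celsiusToKelvin(seq(23, 49, 2))
#' y <- 0.9 * fractionFolded(Tk, 312.15, 60)
#' fitMelting(Tk, y)
fitMelting <- function(temperature, signal,
                       amplitudeMode = c("free", "anchor"),
                       minSignal = 0.02) {
  amplitudeMode <- match.arg(amplitudeMode)
  temperature <- as.numeric(temperature); signal <- as.numeric(signal)
  if (length(temperature) != length(signal))
    .stopf("temperature and signal must have the same length")
  keep <- is.finite(temperature) & is.finite(signal)
  temperature <- temperature[keep]; signal <- signal[keep]
  if (length(temperature) < 5L)
    .stopf("need >= 5 finite melt points, got %d", length(temperature))
  if (any(diff(temperature) <= 0))
    .stopf("temperatures must be strictly ascending")
  if (any(temperature <= 0)) .stopf("temperatures must be > 0 kelvin")

  blank <- function(flags, bimodal = FALSE) new("MeltFit",
    Tm = NA_real_, TmStderr = NA_real_, dHT = NA_real_,
    dHTStderr = NA_real_, amplitude = NA_real_, converged = FALSE,
    bimodal = bimodal, flags = flags, residualNorm = NA_real_)

  if (max(abs(signal)) < minSignal) return(blank("non_fluorogenic"))

  bim <- detectBimodal(temperature, signal)
  ## transition check on lightly smoothed signal: the curve must decrease
  sm <- .runmean3(signal)
  drop <- sm[1] - sm[length(sm)]
  noise <- median(abs(diff(signal))) + .Machine$double.eps
  if (!bim$bimodal && drop < 2 * noise && drop < 0.1 * max(abs(signal)))
    return(blank("no_transition"))

  n <- length(temperature)
  ## initial Tm: temperature where the smoothed signal crosses half its range
  half <- (max(sm) + min(sm)) / 2
  below <- which(sm <= half)
  Tm0 <- if (length(below)) temperature[below[1]] else
    temperature[n] - 0.25 * diff(range(temperature))
  amp0 <- max(signal)
  if (amp0 <= 0) amp0 <- max(abs(signal))
  Tlo <- temperature[1] - 30; Thi <- temperature[n] + 30

  freeAmp <- amplitudeMode == "free"
  anchorAmp <- signal[1]
  if (!freeAmp && abs(anchorAmp) < .Machine$double.eps)
    return(blank("undefined_normalization"))
  resid <- if (freeAmp) {
    function(p) exp(p[3]) * fractionFolded(temperature, p[1], exp(p[2])) - signal
  } else {
    function(p) anchorAmp * fractionFolded(temperature, p[1], exp(p[2])) - signal
  }

  best <- NULL
  for (dH0 in c(20, 60, 150)) {
    p0 <- c(Tm0, log(dH0))
    lo <- c(Tlo, log(0.5)); hi <- c(Thi, log(1000))
    if (freeAmp) { p0 <- c(p0, log(amp0)); lo <- c(lo, log(1e-8))
                   hi <- c(hi, log(1e8)) }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lo, upper = hi, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(blank("non_converged", bim$bimodal))

  p <- best$par
  np <- length(p); dof <- n - np
  se <- rep(NA_real_, np)
  if (dof > 0) {
    covp <- tryCatch(best$deviance / dof * solve(best$hessian),
                     error = function(e) NULL)
    if (!is.null(covp)) se <- sqrt(pmax(diag(covp), 0))
  }
  converged <- best$info %in% 1:4
  dHT <- exp(p[2])
  flags <- character()
  if (!converged) flags <- "non_converged"
  if (bim$bimodal) flags <- c(flags, "bimodal")
  new("MeltFit",
      Tm = p[1], TmStderr = se[1],
      dHT = dHT, dHTStderr = dHT * se[2],
      amplitude = if (freeAmp) exp(p[3]) else anchorAmp,
      converged = converged, bimodal = bim$bimodal, flags = flags,
      residualNorm = best$deviance)
}

.runmean3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  c(mean(x[1:2]),
    (x[-c(n - 1L, n)] + x[-c(1L, n)] + x[-c(1L, 2L)]) / 3,
    mean(x[(n - 1L):n]))
}

#' Detect a bimodal (rise-then-fall) melting profile
#'
#' A misfolding mutant can show low fluorescence at both temperature
#' extremes with a moderate maximum in between (folding into the active
#' conformation only at intermediate temperature).  The detector smooths the
#' curve with a window-3 running mean and flags an interior maximum whose
#' prominence over both end points exceeds 3x the median absolute
#' point-to-point noise.
#'
#' @param temperature ascending temperatures (any unit), >= 7 points.
#' @param signal melt signals.
#' @param prominenceFactor threshold multiplier on the noise scale
#'   (default 3).
#' @return list with `bimodal` (logical), `peakTemperature`, `prominence`
#'   and `noiseScale`; `bimodal = FALSE` with diagnostics on ambiguous
#'   input.
#' @export
#' @examples
#' Tc <- seq(23, 49, 2)
#' hump <- exp(-(Tc - 35)^2 / 18)
#' detectBimodal(Tc, hump)$bimodal
detectBimodal <- function(temperature, signal, prominenceFactor = 3) {
  temperature <- as.numeric(temperature); signal <- as.numeric(signal)
  if (length(temperature) < 7L)
    .stopf("bimodality detection needs >= 7 points")
  if (any(diff(temperature) <= 0))
    .stopf("temperatures must be strictly ascending")
  sm <- .runmean3(signal)
  n <- length(sm)
  ## noise scale from second differences of the raw signal (removes the
  ## smooth trend, keeps point noise); MAD-like robust scale
  d2 <- diff(signal, differences = 2L)
  noise <- median(abs(d2)) / sqrt(6) * sqrt(2)  # sd-equivalent per point
  noise <- max(noise, .Machine$double.eps)
  pk <- which.max(sm)
  out <- list(bimodal = FALSE, peakTemperature = temperature[pk],
              prominence = NA_real_, noiseScale = noise)
  if (pk == 1L || pk == n) return(out)
  prominence <- min(sm[pk] - sm[1], sm[pk] - sm[n])
  out$prominence <- prominence
  out$bimodal <- prominence > prominenceFactor * noise
  out
}
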