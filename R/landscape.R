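## Landscape assembly: per-curve fits -> per-mutant ThermoRecords.
## Replicates are fitted independently and combined afterwards (mean across
## replicates, with the replicate/fit error propagation of
## propagateError()), matching the four-repeat error structure of the chip
## assay rather than a pooled fit.

.parsePositionFromId <- function(id) {
  m <- regmatches(id, regexec("^[ACGU]([0-9]+)[ACGU]$", id))
  vapply(m, function(x) if (length(x) == 2L) as.integer(x[2]) else
    NA_integer_, 0L)
}

.joinFlags <- function(...) {
  f <- unique(unlist(list(...)))
  f <- f[nzchar(f)]
  if (length(f)) paste(f, collapse = ";") else ""
}

#' Fit binding isotherms for a table of titration curves
#'
#' Applies [fitBinding()] to every (mutant, replicate, temperature) group
#' of a long-format titration table.
#'
#' @param curves data.frame with columns `mutant_id`, `replicate`,
#'   `temperature_C`, `conc_uM`, `signal`.
#' @param ... passed to [fitBinding()].
#' @return data.frame with one row per group: `mutant_id`, `replicate`,
#'   `temperature_C`, `Kd_uM`, `Kd_se`, `amplitude`, `amplitude_se`,
#'   `max_signal`, `converged`, `flags`.
#' @export
fitBindingCurves <- function(curves, ...) {
  need <- c("mutant_id", "replicate", "temperature_C", "conc_uM", "signal")
  .checkSchema(curves, need, "titration table")
  key <- interaction(curves$mutant_id, curves$replicate,
                     curves$temperature_C, drop = TRUE)
  out <- lapply(split(seq_len(nrow(curves)), key), function(idx) {
    cv <- curves[idx, ]
    cv <- cv[order(cv$conc_uM), ]
    fit <- tryCatch(
      fitBinding(cv$conc_uM, cv$signal,
                 temperature = celsiusToKelvin(cv$temperature_C[1]), ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(mutant_id = cv$mutant_id[1],
                        replicate = cv$replicate[1],
                        temperature_C = cv$temperature_C[1],
                        Kd_uM = NA_real_, Kd_se = NA_real_,
                        amplitude = NA_real_, amplitude_se = NA_real_,
                        max_signal = max(abs(cv$signal)),
                        converged = FALSE, flags = "fit_error",
                        stringsAsFactors = FALSE))
    }
    data.frame(mutant_id = cv$mutant_id[1], replicate = cv$replicate[1],
               temperature_C = cv$temperature_C[1],
               Kd_uM = fit@Kd, Kd_se = fit@KdStderr,
               amplitude = fit@amplitude,
               amplitude_se = fit@amplitudeStderr,
               max_signal = max(abs(cv$signal)),
               converged = fit@converged,
               flags = .joinFlags(fit@flags), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit melting curves for a table of melt series
#'
#' Applies [fitMelting()] to every (mutant, replicate) group.
#'
#' @param curves data.frame with columns `mutant_id`, `replicate`,
#'   `temperature_C`, `signal`.
#' @param ... passed to [fitMelting()].
#' @return data.frame with one row per group: `mutant_id`, `replicate`,
#'   `Tm_C`, `Tm_se`, `dHT`, `dHT_se`, `amplitude`, `converged`,
#'   `bimodal`, `flags`.
#' @export
fitMeltingCurves <- function(curves, ...) {
  need <- c("mutant_id", "replicate", "temperature_C", "signal")
  .checkSchema(curves, need, "melt table")
  key <- interaction(curves$mutant_id, curves$replicate, drop = TRUE)
  out <- lapply(split(seq_len(nrow(curves)), key), function(idx) {
    cv <- curves[idx, ]
    cv <- cv[order(cv$temperature_C), ]
    fit <- tryCatch(
      fitMelting(celsiusToKelvin(cv$temperature_C), cv$signal, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(mutant_id = cv$mutant_id[1],
                        replicate = cv$replicate[1],
                        Tm_C = NA_real_, Tm_se = NA_real_, dHT = NA_real_,
                        dHT_se = NA_real_, amplitude = NA_real_,
                        converged = FALSE, bimodal = FALSE,
                        flags = "fit_error", stringsAsFactors = FALSE))
    }
    data.frame(mutant_id = cv$mutant_id[1], replicate = cv$replicate[1],
               Tm_C = kelvinToCelsius(fit@Tm), Tm_se = fit@TmStderr,
               dHT = fit@dHT, dHT_se = fit@dHTStderr,
               amplitude = fit@amplitude, converged = fit@converged,
               bimodal = fit@bimodal, flags = .joinFlags(fit@flags),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Construct a ThermoLandscape from a per-mutant table
#'
#' Low-level constructor; [assembleLandscape()] builds the table from curve
#' fits.  Missing sigma/flag columns are filled with NA / "".
#'
#' @param df data.frame (or DataFrame) with at least `id`, `Sm`, `ddG`,
#'   `ddH`, `dTm`, `fluorogenic`; `position` is parsed from SPM-style ids
#'   when absent.
#' @param wtId wild-type id (must be a row of `df`).
#' @param refTemperature reference temperature in kelvin.
#' @return a [ThermoLandscape].
#' @export
newThermoLandscape <- function(df, wtId, refTemperature = 296.15) {
  df <- as.data.frame(df)
  if (!"position" %in% names(df))
    df$position <- .parsePositionFromId(df$id)
  for (s in c("Sm_sigma", "ddG_sigma", "ddH_sigma", "dTm_sigma"))
    if (!s %in% names(df)) df[[s]] <- NA_real_
  if (!"flags" %in% names(df)) df$flags <- ""
  cols <- c("id", "position", "Sm", "ddG", "ddH", "dTm",
            "Sm_sigma", "ddG_sigma", "ddH_sigma", "dTm_sigma",
            "fluorogenic", "flags")
  new("ThermoLandscape", records = DataFrame(df[, cols]),
      wtId = wtId, refTemperature = refTemperature)
}

#' Assemble the per-mutant thermodynamic landscape from curve fits
#'
#' Combines binding fits (per mutant, replicate and temperature) and
#' melting fits (per mutant and replicate) into one record per mutant:
#'
#' * `Sm` — fitted saturation amplitude at the reference temperature,
#'   relative to the wild-type amplitude;
#' * `ddG` — binding free energy change vs wild type at the reference
#'   temperature (see [deltaDeltaG()]; favorable-negative by default);
#' * `ddH` — Van't Hoff binding enthalpy change vs wild type, from a
#'   per-replicate regression over the temperature series;
#' * `dTm` — apparent melting temperature change vs wild type (degrees C).
#'
#' Each quantity is computed per replicate against the wild-type replicate
#' mean, averaged across replicates, and its error propagated with
#' [propagateError()].  A mutant is fluorogenic when its mean
#' top-concentration signal at the reference temperature exceeds the
#' non-fluorogenic threshold; the default threshold is 3x the standard
#' deviation of the negative-control signals when `controlIds` are given
#' (floored at `minThreshold`), else `minThreshold`.  Non-fluorogenic
#' mutants carry no thermodynamic parameters, only `Sm`.  Partial failures
#' (missing temperatures, non-converged fits) are carried as flags, never
#' dropped.
#'
#' @param bindingFits output of [fitBindingCurves()].
#' @param meltFits output of [fitMeltingCurves()] (optional; `dTm` is NA
#'   without it).
#' @param wtId wild-type mutant id.
#' @param controlIds ids of negative-control cells.
#' @param refTemperatureC reference temperature for Kd/ddG, Celsius.
#' @param sign ddG sign convention, see [deltaDeltaG()].
#' @param vhConvention Van't Hoff convention, see [vantHoff()].
#' @param errorMode see [propagateError()].
#' @param nonFluorThreshold explicit threshold on the top-concentration
#'   signal; overrides the control-derived default.
#' @param minThreshold floor for the control-derived threshold.
#' @return a [ThermoLandscape].
#' @export
assembleLandscape <- function(bindingFits, meltFits = NULL, wtId,
                              controlIds = character(),
                              refTemperatureC = 23,
                              sign = c("favorable_negative", "as_printed"),
                              vhConvention = c("binding", "as_printed"),
                              errorMode = c("as_printed", "quadrature"),
                              nonFluorThreshold = NULL,
                              minThreshold = 0.02) {
  sign <- match.arg(sign)
  vhConvention <- match.arg(vhConvention)
  errorMode <- match.arg(errorMode)
  refT <- celsiusToKelvin(refTemperatureC)
  b <- bindingFits
  if (!wtId %in% b$mutant_id)
    .stopf("wild-type id '%s' absent from binding fits", wtId)
  atRef <- abs(b$temperature_C - refTemperatureC) < 1e-9
  if (!any(atRef))
    .stopf("no binding fits at the reference temperature %g C",
           refTemperatureC)

  ## non-fluorogenic threshold from negative-control signal spread
  if (is.null(nonFluorThreshold)) {
    ctl <- b$max_signal[atRef & b$mutant_id %in% controlIds]
    nonFluorThreshold <- if (length(ctl) >= 2L)
      max(3 * sd(ctl), minThreshold) else minThreshold
  }

  perRep <- function(id) {
    rows <- b[b$mutant_id == id, , drop = FALSE]
    reps <- sort(unique(rows$replicate))
    lapply(reps, function(rp) {
      rr <- rows[rows$replicate == rp, , drop = FALSE]
      ref <- rr[abs(rr$temperature_C - refTemperatureC) < 1e-9 &
                  rr$converged, , drop = FALSE]
      vhRows <- rr[rr$converged & is.finite(rr$Kd_uM), , drop = FALSE]
      vh <- if (length(unique(vhRows$temperature_C)) >= 2L)
        vantHoff(celsiusToKelvin(vhRows$temperature_C), vhRows$Kd_uM,
                 convention = vhConvention) else NULL
      list(replicate = rp,
           Kd = if (nrow(ref)) ref$Kd_uM[1] else NA_real_,
           KdSe = if (nrow(ref)) ref$Kd_se[1] else NA_real_,
           amp = if (nrow(ref)) ref$amplitude[1] else NA_real_,
           ampSe = if (nrow(ref)) ref$amplitude_se[1] else NA_real_,
           maxSig = max(c(rr$max_signal[
             abs(rr$temperature_C - refTemperatureC) < 1e-9], 0)),
           dH = if (is.null(vh)) NA_real_ else vh@dH,
           dHSe = if (is.null(vh)) NA_real_ else vh@dHStderr)
    })
  }

  meanFinite <- function(x) if (any(is.finite(x))) mean(x[is.finite(x)])
    else NA_real_
  sigmaOf <- function(vals, errs) {
    ok <- is.finite(vals)
    if (sum(ok) < 2L) return(NA_real_)
    propagateError(vals[ok], errs[ok], mode = errorMode)
  }

  ## wild-type references (replicate means)
  wtReps <- perRep(wtId)
  wtKd <- meanFinite(vapply(wtReps, `[[`, 0, "Kd"))
  wtAmp <- meanFinite(vapply(wtReps, `[[`, 0, "amp"))
  wtDH <- meanFinite(vapply(wtReps, `[[`, 0, "dH"))
  if (!is.finite(wtKd) || !is.finite(wtAmp))
    .stopf("wild-type binding fit failed; cannot reference the landscape")

  m <- if (!is.null(meltFits)) meltFits else
    data.frame(mutant_id = character(), replicate = integer(),
               Tm_C = numeric(), Tm_se = numeric(), bimodal = logical(),
               flags = character())
  wtTm <- meanFinite(m$Tm_C[m$mutant_id == wtId & m$converged])

  ids <- unique(b$mutant_id)
  recs <- lapply(ids, function(id) {
    rl <- perRep(id)
    Kd <- vapply(rl, `[[`, 0, "Kd"); KdSe <- vapply(rl, `[[`, 0, "KdSe")
    amp <- vapply(rl, `[[`, 0, "amp"); ampSe <- vapply(rl, `[[`, 0, "ampSe")
    dH <- vapply(rl, `[[`, 0, "dH"); dHSe <- vapply(rl, `[[`, 0, "dHSe")
    maxSig <- vapply(rl, `[[`, 0, "maxSig")
    mm <- m[m$mutant_id == id & m$converged, , drop = FALSE]
    bim <- any(m$bimodal[m$mutant_id == id])
    fluor <- meanFinite(maxSig) > nonFluorThreshold &&
      !id %in% controlIds
    flags <- character()
    if (id %in% controlIds) flags <- c(flags, "control")
    if (bim) flags <- c(flags, "bimodal")
    if (!fluor) flags <- c(flags, "non_fluorogenic")
    isWT <- id == wtId
    if (fluor && !all(is.finite(Kd)))
      flags <- c(flags, "partial_binding_fit")
    if (fluor && !all(is.finite(dH)))
      flags <- c(flags, "partial_vant_hoff")
    if (!fluor) {
      return(data.frame(
        id = id, position = .parsePositionFromId(id),
        Sm = meanFinite(amp) / wtAmp,
        ddG = NA_real_, ddH = NA_real_, dTm = NA_real_,
        Sm_sigma = NA_real_, ddG_sigma = NA_real_, ddH_sigma = NA_real_,
        dTm_sigma = NA_real_, fluorogenic = FALSE,
        flags = .joinFlags(flags), stringsAsFactors = FALSE))
    }
    SmRep <- amp / wtAmp
    SmSeRep <- ampSe / wtAmp
    ddGRep <- ifelse(is.finite(Kd),
                     deltaDeltaG(Kd, wtKd, refT, sign = sign), NA_real_)
    ddGSeRep <- .R_KCAL * refT * KdSe / Kd
    ddHRep <- dH - wtDH
    TmRep <- mm$Tm_C[match(vapply(rl, `[[`, 0L, "replicate"),
                           mm$replicate)]
    TmSeRep <- mm$Tm_se[match(vapply(rl, `[[`, 0L, "replicate"),
                              mm$replicate)]
    dTmRep <- TmRep - wtTm
    data.frame(
      id = id, position = .parsePositionFromId(id),
      Sm = if (isWT) 1 else meanFinite(SmRep),
      ddG = if (isWT) 0 else meanFinite(ddGRep),
      ddH = if (isWT) 0 else meanFinite(ddHRep),
      dTm = if (isWT) 0 else meanFinite(dTmRep),
      Sm_sigma = sigmaOf(SmRep, SmSeRep),
      ddG_sigma = sigmaOf(ddGRep, ddGSeRep),
      ddH_sigma = sigmaOf(ddHRep, dHSe),
      dTm_sigma = sigmaOf(dTmRep, TmSeRep),
      fluorogenic = TRUE, flags = .joinFlags(flags),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  newThermoLandscape(df, wtId = wtId, refTemperature = refT)
}
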