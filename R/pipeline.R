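## End-to-end orchestration: titration + melt tables in, landscape, score
## track, candidate list and QC out, with machine-readable flags carried
## through and a run log.

#' Pipeline configuration
#'
#' @param wtId wild-type mutant id.
#' @param controlIds negative-control ids.
#' @param refTemperatureC reference temperature for Kd/ddG, Celsius.
#' @param sign ddG sign convention (see [deltaDeltaG()]).
#' @param vhConvention Van't Hoff convention (see [vantHoff()]).
#' @param errorMode error propagation mode (see [propagateError()]).
#' @param q candidate-selection quantile fraction.
#' @param selectParameters parameters intersected for candidate selection.
#' @param cvThreshold replicate-CV QC flag threshold.
#' @param nonFluorThreshold explicit non-fluorogenic threshold (NULL =
#'   derive from controls).
#' @return named list.
#' @export
pipelineConfig <- function(wtId = "WT", controlIds = "NEG",
                           refTemperatureC = 23,
                           sign = "favorable_negative",
                           vhConvention = "binding",
                           errorMode = "as_printed", q = 0.10,
                           selectParameters = c("Sm", "ddG", "dTm"),
                           cvThreshold = 0.05,
                           nonFluorThreshold = NULL) {
  as.list(environment())
}

#' Run the landscape pipeline on curve tables
#'
#' Validates the input schemas, fits every titration and melt curve,
#' assembles the [ThermoLandscape], scores it per position (when the SPM
#' set covers contiguous positions), selects engineering candidates by
#' quantile intersection, and computes replicate QC on the
#' top-concentration signals.  Mutants with partial fit failures are
#' carried with flags, never dropped.  Identical inputs and configuration
#' give identical outputs.
#'
#' @param titrations titration table (data.frame or path; see
#'   [readTitrationCurves()]).
#' @param melts melt table (data.frame or path), optional.
#' @param config a [pipelineConfig()].
#' @return list with `landscape`, `scoreTrack` (or NULL), `candidates`,
#'   `qc`, `bindingFits`, `meltFits`, `log` (character vector).
#' @export
#' @examples
#' chip <- simulateChip(syntheticReference(6), seed = 3,
#'                      noise = noiseModel(0, 0))
#' res <- runPipeline(titrations(chip), melts(chip))
#' res$landscape
runPipeline <- function(titrations, melts = NULL,
                        config = pipelineConfig()) {
  logLines <- character()
  note <- function(fmt, ...) {
    logLines <<- c(logLines, sprintf(fmt, ...))
  }
  if (is.character(titrations)) titrations <- readTitrationCurves(titrations)
  if (is.character(melts)) melts <- readMeltCurves(melts)
  .checkSchema(titrations, c("mutant_id", "replicate", "temperature_C",
                             "conc_uM", "signal"), "titration table")
  if (!is.null(melts))
    .checkSchema(melts, c("mutant_id", "replicate", "temperature_C",
                          "signal"), "melt table")
  note("pipeline start: %d titration rows, %d melt rows, wt='%s'",
       nrow(titrations), if (is.null(melts)) 0L else nrow(melts),
       config$wtId)

  bindingFits <- fitBindingCurves(titrations)
  note("binding fits: %d curves, %d converged, %d non-fluorogenic",
       nrow(bindingFits), sum(bindingFits$converged),
       sum(grepl("non_fluorogenic", bindingFits$flags)))
  meltFits <- NULL
  if (!is.null(melts)) {
    meltFits <- fitMeltingCurves(melts)
    note("melt fits: %d curves, %d converged, %d bimodal",
         nrow(meltFits), sum(meltFits$converged), sum(meltFits$bimodal))
  }

  landscape <- assembleLandscape(
    bindingFits, meltFits, wtId = config$wtId,
    controlIds = config$controlIds,
    refTemperatureC = config$refTemperatureC, sign = config$sign,
    vhConvention = config$vhConvention, errorMode = config$errorMode,
    nonFluorThreshold = config$nonFluorThreshold)
  note("landscape: %d mutants, %d non-fluorogenic",
       nrow(records(landscape)), sum(!records(landscape)$fluorogenic))

  scoreTrack <- tryCatch(scoreLandscape(landscape),
                         error = function(e) {
                           note("score track skipped: %s",
                                conditionMessage(e))
                           NULL
                         })
  candidates <- tryCatch(
    selectQuantiles(landscape, parameters = config$selectParameters,
                    q = config$q),
    error = function(e) {
      note("candidate selection skipped: %s", conditionMessage(e))
      character()
    })
  note("candidates (top %.0f%% in %s): %d", 100 * config$q,
       paste(config$selectParameters, collapse = " & "),
       length(candidates))

  ## QC on top-concentration signals at the reference temperature
  topConc <- max(titrations$conc_uM)
  qcRows <- titrations[titrations$conc_uM == topConc &
    abs(titrations$temperature_C - config$refTemperatureC) < 1e-9, ]
  qc <- if (nrow(qcRows) && length(unique(qcRows$replicate)) >= 2L)
    replicateQC(data.frame(mutant_id = qcRows$mutant_id,
                           replicate = qcRows$replicate,
                           Sm = qcRows$signal),
                cvThreshold = config$cvThreshold) else NULL

  list(landscape = landscape, scoreTrack = scoreTrack,
       candidates = candidates, qc = qc, bindingFits = bindingFits,
       meltFits = meltFits, log = logLines)
}
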