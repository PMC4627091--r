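#' Accessors for aptascan classes
#'
#' Standard accessor generics: `refSequence` returns the reference
#' [Biostrings::RNAString] of a [MutantLibrary]; `mutants` its specification
#' table; `mutantIds` the ids; `records` the per-mutant table of a
#' [ThermoLandscape]; `wtId` its wild-type id; `assignment` the cell table of
#' a [ChipLayout]; `chipCapacity` the mutant capacity; `truthTable`,
#' `titrations`, `melts` the components of a [SyntheticChip].
#'
#' @param x an aptascan object.
#' @return the slot value (see each method).
#' @name aptascan-accessors
NULL

#' @rdname aptascan-accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))
#' @rdname aptascan-accessors
#' @export
setGeneric("mutants", function(x) standardGeneric("mutants"))
#' @rdname aptascan-accessors
#' @export
setGeneric("mutantIds", function(x) standardGeneric("mutantIds"))
#' @rdname aptascan-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname aptascan-accessors
#' @export
setGeneric("wtId", function(x) standardGeneric("wtId"))
#' @rdname aptascan-accessors
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))
#' @rdname aptascan-accessors
#' @export
setGeneric("chipCapacity", function(x) standardGeneric("chipCapacity"))
#' @rdname aptascan-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname aptascan-accessors
#' @export
setGeneric("titrations", function(x) standardGeneric("titrations"))
#' @rdname aptascan-accessors
#' @export
setGeneric("melts", function(x) standardGeneric("melts"))

#' @rdname aptascan-accessors
#' @export
setMethod("refSequence", "MutantLibrary", function(x) x@refSeq)
#' @rdname aptascan-accessors
#' @export
setMethod("mutants", "MutantLibrary", function(x) x@mutants)
#' @rdname aptascan-accessors
#' @export
setMethod("mutantIds", "MutantLibrary", function(x) x@mutants$id)
#' @rdname aptascan-accessors
#' @export
setMethod("records", "ThermoLandscape", function(x) x@records)
#' @rdname aptascan-accessors
#' @export
setMethod("wtId", "ThermoLandscape", function(x) x@wtId)
#' @rdname aptascan-accessors
#' @export
setMethod("assignment", "ChipLayout", function(x) x@assignment)
#' @rdname aptascan-accessors
#' @export
setMethod("chipCapacity", "ChipLayout",
          function(x) x@nCells %/% x@replicates)
#' @rdname aptascan-accessors
#' @export
setMethod("truthTable", "SyntheticChip", function(x) x@truth)
#' @rdname aptascan-accessors
#' @export
setMethod("titrations", "SyntheticChip", function(x) x@titrations)
#' @rdname aptascan-accessors
#' @export
setMethod("melts", "SyntheticChip", function(x) x@melts)

#' @rdname aptascan-accessors
#' @param object an aptascan object (show methods).
#' @export
setMethod("show", "MutantLibrary", function(object) {
  m <- object@mutants
  cat(sprintf("MutantLibrary: %d mutants on a %d-nt reference\n",
              nrow(m), length(object@refSeq)))
  nsub <- lengths(m$pos)
  cat(sprintf("  SPMs: %d  DPMs: %d  with deletions: %d  controls: %d\n",
              sum(nsub == 1L & lengths(m$deletions) == 0L),
              sum(nsub == 2L & lengths(m$deletions) == 0L),
              sum(lengths(m$deletions) > 0L), sum(m$isControl)))
  invisible(NULL)
})

#' @rdname aptascan-accessors
#' @export
setMethod("show", "ChipLayout", function(object) {
  cat(sprintf(
    "ChipLayout: %d unit cells, %d replicates (capacity %d mutants), %d assigned\n",
    object@nCells, object@replicates, chipCapacity(object),
    nrow(object@assignment)))
  invisible(NULL)
})

#' @rdname aptascan-accessors
#' @export
setMethod("show", "BindingFit", function(object) {
  if ("non_fluorogenic" %in% object@flags) {
    cat("BindingFit: non-fluorogenic (no Kd)\n")
  } else {
    cat(sprintf("BindingFit: Kd = %.4g uM (se %.3g), amplitude = %.4g%s\n",
                object@Kd, object@KdStderr, object@amplitude,
                if (object@converged) "" else " [not converged]"))
  }
  invisible(NULL)
})

#' @rdname aptascan-accessors
#' @export
setMethod("show", "MeltFit", function(object) {
  if (length(object@flags) && any(object@flags != "")) {
    cat(sprintf("MeltFit: flagged (%s)\n",
                paste(setdiff(object@flags, ""), collapse = ", ")))
  }
  if (object@converged) {
    cat(sprintf("MeltFit: Tm = %.2f C, dH_T = %.3g kcal/mol%s\n",
                kelvinToCelsius(object@Tm), object@dHT,
                if (object@bimodal) " [bimodal]" else ""))
  }
  invisible(NULL)
})

#' @rdname aptascan-accessors
#' @export
setMethod("show", "VantHoffFit", function(object) {
  cat(sprintf(
    "VantHoffFit (%s): dH = %.4g kcal/mol, dS = %.4g kcal/(mol K), R2 = %.4f, n = %d\n",
    object@convention, object@dH, object@dS, object@rSquared, object@n))
  invisible(NULL)
})

#' @rdname aptascan-accessors
#' @export
setMethod("show", "ThermoLandscape", function(object) {
  r <- object@records
  cat(sprintf(
    "ThermoLandscape: %d mutants (wt = '%s', ref T = %.2f K); %d non-fluorogenic\n",
    nrow(r), object@wtId, object@refTemperature, sum(!r$fluorogenic)))
  invisible(NULL)
})

#' @rdname aptascan-accessors
#' @export
setMethod("show", "ScoreTrack", function(object) {
  cat(sprintf("ScoreTrack over %d positions; Score range [%.3g, %.3g]\n",
              length(object@position), min(object@score), max(object@score)))
  invisible(NULL)
})

#' @rdname aptascan-accessors
#' @export
setMethod("show", "SyntheticChip", function(object) {
  cat(sprintf(
    "SyntheticChip (seed %d): %d mutants, %d titration rows, %d melt rows\n",
    object@seed, nrow(object@truth), nrow(object@titrations),
    nrow(object@melts)))
  invisible(NULL)
})
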