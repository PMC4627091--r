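#' @importFrom S4Vectors DataFrame metadata metadata<- isEmpty
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom Biostrings RNAString
#' @importFrom IRanges IntegerList CharacterList
#' @importFrom Biostrings RNAString DNAString readRNAStringSet
#'   writeXStringSet RNAStringSet complement subseq
NULL

setClassUnion("DataFrameOrNULL", c("DFrame", "NULL"))

#' MutantLibrary: a set of mutants of one reference RNA
#'
#' Holds the reference sequence together with a table of mutant
#' specifications: point substitutions (with transition/transversion class),
#' deletions, and control flags.  Coordinates are 1-based on the reference.
#'
#' @slot refSeq the reference [Biostrings::RNAString].
#' @slot mutants a [S4Vectors::DataFrame] with columns `id`, `pos`
#'   (IntegerList), `wt`, `alt`, `mutClass` (CharacterList, one entry per
#'   substitution), `deletions` (IntegerList), `isWT`, `isControl`.
#'
#' @aliases MutantLibrary-class
#' @export
setClass("MutantLibrary",
  representation(refSeq = "RNAString", mutants = "DFrame"))

setValidity("MutantLibrary", function(object) {
  m <- object@mutants
  need <- c("id", "pos", "wt", "alt", "mutClass", "deletions",
            "isWT", "isControl")
  if (!all(need %in% colnames(m)))
    return(paste("mutants table must have columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(m$id)) return("mutant ids must be unique")
  n <- length(object@refSeq)
  ref <- strsplit(as.character(object@refSeq), "")[[1]]
  np <- lengths(m$pos)
  if (any(np != lengths(m$wt)) || any(np != lengths(m$alt)))
    return("ragged substitution fields (pos/wt/alt lengths differ)")
  up <- unlist(m$pos, use.names = FALSE)
  ud <- unlist(m$deletions, use.names = FALSE)
  if (length(up) && (any(up < 1L) || any(up > n)))
    return("substitution position out of bounds")
  if (length(ud) && (any(ud < 1L) || any(ud > n)))
    return("deletion position out of bounds")
  uw <- unlist(m$wt, use.names = FALSE)
  if (length(up) && !all(ref[up] == uw)) {
    bad <- which(ref[up] != uw)[1L]
    return(sprintf(
      "wt base disagrees with reference at position %d ('%s' vs '%s')",
      up[bad], uw[bad], ref[up[bad]]))
  }
  grp <- c(rep.int(seq_len(nrow(m)), np),
           rep.int(seq_len(nrow(m)), lengths(m$deletions)))
  if (anyDuplicated(paste(grp, c(up, ud))))
    return("overlapping substitution/deletion sites within a mutant")
  TRUE
})

#' FragmentDesign: two-oligo assembly of one mutant
#'
#' A mutant sequence split into a 5' and a 3' fragment sharing an exact
#' overlap (default 19 nt), mirroring two-oligonucleotide stitch PCR
#' assembly.  The 5' fragment additionally carries opaque tag sequences
#' (promoter, pull-down anchor, probe).
#'
#' @slot fragment5,fragment3 character; template regions of the two
#'   fragments (RNA sense).
#' @slot tags named list of tag strings prepended to the 5' fragment.
#' @slot overlapLen integer overlap length in nt.
#' @slot splitAt integer; last reference position covered by fragment5.
#' @slot placement one of `"5prime"`, `"3prime"`, `"both"`, `"none"`.
#'
#' @aliases FragmentDesign-class
#' @export
setClass("FragmentDesign",
  representation(fragment5 = "character", fragment3 = "character",
                 tags = "list", overlapLen = "integer",
                 splitAt = "integer", placement = "character"))

setValidity("FragmentDesign", function(object) {
  if (object@overlapLen < 1L) return("overlapLen must be >= 1")
  o5 <- substring(object@fragment5,
                  nchar(object@fragment5) - object@overlapLen + 1L)
  o3 <- substring(object@fragment3, 1L, object@overlapLen)
  if (o5 != o3) return("fragment overlap regions disagree")
  if (!object@placement %in% c("5prime", "3prime", "both", "none"))
    return("invalid placement")
  TRUE
})

#' ChipLayout: assignment of mutants to chip unit cells
#'
#' @slot nCells total number of functional unit cells (default 640).
#' @slot replicates repeats per mutant (default 4).
#' @slot assignment data.frame with columns `cell`, `row`, `col`,
#'   `mutant_id`, `replicate`, `control`.
#'
#' @aliases ChipLayout-class
#' @export
setClass("ChipLayout",
  representation(nCells = "integer", replicates = "integer",
                 assignment = "data.frame"))

setValidity("ChipLayout", function(object) {
  a <- object@assignment
  if (nrow(a) > object@nCells) return("more assigned cells than unit cells")
  tab <- table(a$mutant_id)
  if (length(tab) && !all(tab == object@replicates))
    return("every mutant must occupy exactly 'replicates' cells")
  if (anyDuplicated(a$cell)) return("duplicate cell assignment")
  TRUE
})

#' SpotGeometry: fitted pull-down spot footprint
#'
#' @slot center numeric length-2 (row, col), sub-pixel.
#' @slot radius foreground radius in pixels.
#' @slot annulusOuter outer radius of the background annulus
#'   (1.5 x radius by construction).
#' @slot sigma fitted Gaussian widths (sx, sy).
#' @slot theta fitted rotation (radians).
#' @slot amplitude,offset fitted peak height above offset, and offset.
#' @slot converged logical.
#'
#' @aliases SpotGeometry-class
#' @export
setClass("SpotGeometry",
  representation(center = "numeric", radius = "numeric",
                 annulusOuter = "numeric", sigma = "numeric",
                 theta = "numeric", amplitude = "numeric",
                 offset = "numeric", converged = "logical"))

setValidity("SpotGeometry", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (object@converged && object@radius <= 0) return("radius must be > 0")
  if (object@converged &&
      abs(object@annulusOuter - 1.5 * object@radius) > 1e-8)
    return("annulusOuter must equal 1.5 * radius")
  TRUE
})

#' BindingFit: two-state binding isotherm fit result
#'
#' @slot Kd dissociation constant (uM).
#' @slot KdStderr standard error of Kd (uM).
#' @slot amplitude fitted saturation plateau (signal units).
#' @slot amplitudeStderr its standard error.
#' @slot converged logical.
#' @slot flags character vector of machine-readable flags
#'   (e.g. `"non_fluorogenic"`, `"non_converged"`).
#' @slot residualNorm residual sum of squares.
#' @slot nPoints number of titration points used.
#' @slot temperature kelvin (NA if not annotated).
#'
#' @aliases BindingFit-class
#' @export
setClass("BindingFit",
  representation(Kd = "numeric", KdStderr = "numeric",
                 amplitude = "numeric", amplitudeStderr = "numeric",
                 converged = "logical", flags = "character",
                 residualNorm = "numeric", nPoints = "integer",
                 temperature = "numeric"))

#' VantHoffFit: linear Van't Hoff regression result
#'
#' Regression of ln Kd (molar) on 1/T.  Under the default `"binding"`
#' convention the reported enthalpy is the binding (association) enthalpy,
#' negative for exothermic binding; see [vantHoff()].
#'
#' @slot dH enthalpy (kcal/mol).
#' @slot dS entropy (kcal/(mol K)).
#' @slot dHStderr,dSStderr coefficient standard errors.
#' @slot rSquared coefficient of determination.
#' @slot n number of (T, Kd) points.
#' @slot convention `"binding"` or `"as_printed"`.
#'
#' @aliases VantHoffFit-class
#' @export
setClass("VantHoffFit",
  representation(dH = "numeric", dS = "numeric", dHStderr = "numeric",
                 dSStderr = "numeric", rSquared = "numeric", n = "integer",
                 convention = "character"))

#' MeltFit: two-state melting curve fit result
#'
#' @slot Tm apparent melting temperature (kelvin).
#' @slot TmStderr its standard error.
#' @slot dHT unfolding enthalpy (kcal/mol, > 0 for cooperative melts).
#' @slot dHTStderr its standard error.
#' @slot amplitude fitted low-temperature amplitude.
#' @slot converged logical.
#' @slot bimodal logical: rise-then-fall melting profile detected.
#' @slot flags character flags (e.g. `"no_transition"`).
#' @slot residualNorm residual sum of squares.
#'
#' @aliases MeltFit-class
#' @export
setClass("MeltFit",
  representation(Tm = "numeric", TmStderr = "numeric", dHT = "numeric",
                 dHTStderr = "numeric", amplitude = "numeric",
                 converged = "logical", bimodal = "logical",
                 flags = "character", residualNorm = "numeric"))

#' ThermoLandscape: per-mutant landscape parameter table
#'
#' The central result container: one row per mutant with the four landscape
#' parameters (relative fluorescence Sm, ddG, ddH, dTm), their propagated
#' errors, and the fluorogenic flag, all relative to the designated wild
#' type.
#'
#' @slot records [S4Vectors::DataFrame] with columns `id`, `position`,
#'   `Sm`, `ddG`, `ddH`, `dTm`, `Sm_sigma`, `ddG_sigma`, `ddH_sigma`,
#'   `dTm_sigma`, `fluorogenic`, `flags`.
#' @slot wtId id of the wild-type record.
#' @slot refTemperature reference temperature (kelvin) at which ddG is
#'   evaluated.
#'
#' @aliases ThermoLandscape-class
#' @export
setClass("ThermoLandscape",
  representation(records = "DFrame", wtId = "character",
                 refTemperature = "numeric"))

setValidity("ThermoLandscape", function(object) {
  r <- object@records
  need <- c("id", "position", "Sm", "ddG", "ddH", "dTm", "fluorogenic")
  if (!all(need %in% colnames(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$id)) return("mutant ids must be unique")
  if (!object@wtId %in% r$id)
    return(sprintf("wild-type id '%s' absent from records", object@wtId))
  w <- r[r$id == object@wtId, ]
  ok <- function(x) is.na(x) || abs(x) < 1e-9
  if (!(ok(w$ddG) && ok(w$ddH) && ok(w$dTm)))
    return("wild-type record must have ddG = ddH = dTm = 0")
  TRUE
})

#' ScoreTrack: per-position composite landscape score
#'
#' Min-max normalised scores of the four landscape parameters summed per
#' single-point mutant (S_j in [-4, 4]; non-fluorogenic mutants contribute
#' -1 per parameter), aggregated per position and smoothed with a
#' window-3 moving average.
#'
#' @slot position integer positions 1..n.
#' @slot positionSj per-position aggregated S_j (pre-smoothing).
#' @slot score smoothed Score(n).
#' @slot perSPM [S4Vectors::DataFrame] with per-mutant `id`, `position`,
#'   `X_Sm`, `X_ddG`, `X_ddH`, `X_dTm`, `Sj`.
#'
#' @aliases ScoreTrack-class
#' @export
setClass("ScoreTrack",
  representation(position = "integer", positionSj = "numeric",
                 score = "numeric", perSPM = "DFrame"))

setValidity("ScoreTrack", function(object) {
  if (length(object@position) != length(object@score) ||
      length(object@position) != length(object@positionSj))
    return("position, positionSj and score must be parallel")
  sj <- object@perSPM$Sj
  if (length(sj) && any(sj < -4 - 1e-9 | sj > 4 + 1e-9))
    return("per-SPM scores must lie in [-4, 4]")
  TRUE
})

#' SyntheticChip: one simulated chip experiment with ground truth
#'
#' @slot truth data.frame of generating parameters, one row per mutant.
#' @slot titrations data.frame of simulated titration measurements.
#' @slot melts data.frame of simulated melting measurements.
#' @slot layout a [ChipLayout].
#' @slot seed integer seed the dataset was generated from.
#' @slot config named list of generator settings.
#'
#' @aliases SyntheticChip-class
#' @export
setClass("SyntheticChip",
  representation(truth = "data.frame", titrations = "data.frame",
                 melts = "data.frame", layout = "ChipLayout",
                 seed = "integer", config = "list"))
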