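## Composite landscape scoring.  Each of the four per-SPM landscape
## parameters (relative fluorescence Sm, ddG, ddH, dTm) is oriented so that
## larger means more beneficial, min-max normalised to X in [0, 1] over all
## fluorogenic SPMs (non-fluorogenic SPMs are set to -1), summed to a
## per-SPM score S_j in [-4, 4], aggregated per position and smoothed with
## a window-3 moving average to give Score(n).

#' Default parameter orientation for scoring
#'
#' Direction in which each landscape parameter is beneficial: higher
#' relative fluorescence (`Sm`), more favourable (more negative,
#' favorable-negative convention) binding free energy (`ddG`) and enthalpy
#' (`ddH`) changes, and higher melting-temperature change (`dTm`).
#'
#' @return named numeric vector of +/- 1.
#' @export
defaultOrientation <- function() {
  c(Sm = 1, ddG = -1, ddH = -1, dTm = 1)
}

#' Min-max normalise one landscape parameter across SPMs
#'
#' Maps the minimum observed value (among fluorogenic SPMs) to 0 and the
#' maximum to 1, affinely in between; non-fluorogenic SPMs are assigned -1.
#' Invariant under positive affine transforms of the input.
#'
#' @param values numeric parameter values, one per SPM.
#' @param fluorogenic logical vector (default: all fluorogenic).
#' @return numeric vector of X scores.
#' @export
#' @examples
#' normalizeParameter(c(1, 2, 3), c(TRUE, TRUE, TRUE))
normalizeParameter <- function(values,
                               fluorogenic = rep(TRUE, length(values))) {
  stopifnot(length(values) == length(fluorogenic))
  v <- values[fluorogenic & is.finite(values)]
  if (length(v) < 2L)
    .stopf("need >= 2 finite values among fluorogenic SPMs")
  rng <- range(v)
  if (diff(rng) <= 0)
    .stopf("degenerate range: all fluorogenic values identical")
  out <- (values - rng[1]) / diff(rng)
  out[!fluorogenic] <- -1
  out
}

#' Window-3 moving average of per-position scores
#'
#' `Score(n) = mean(S_j, j in {n-1, n, n+1})`, with truncated windows at
#' the two terminal positions (positions 1 and n average over their two
#' available neighbours).
#'
#' @param Sj numeric per-position scores on contiguous positions 1..n.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' positionScore(c(0, 3, 0))   # 1.5, 1, 1.5
positionScore <- function(Sj) {
  .runmean3(as.numeric(Sj))
}

#' Score a landscape into a per-position track
#'
#' Computes the four normalised X scores per SPM (via
#' [normalizeParameter()], after orienting each parameter so larger is
#' beneficial), sums them to S_j, aggregates the (typically three) SPM
#' scores at each position, and smooths with the window-3 moving average.
#' A fluorogenic SPM missing one of the four parameters is an error
#' (incomplete record); non-fluorogenic SPMs score -1 on every parameter.
#'
#' @param landscape a [ThermoLandscape] whose SPM records cover contiguous
#'   positions 1..n (records without a position, e.g. DPMs or the wild
#'   type, are ignored).
#' @param orientation named vector of +/-1 per parameter
#'   (see [defaultOrientation()]).
#' @param aggregate how to combine the SPM scores at one position:
#'   `"mean"` (default, robust) or `"max"`.
#' @return a [ScoreTrack].
#' @export
scoreLandscape <- function(landscape, orientation = defaultOrientation(),
                           aggregate = c("mean", "max")) {
  stopifnot(is(landscape, "ThermoLandscape"))
  aggregate <- match.arg(aggregate)
  r <- records(landscape)
  spm <- r[!is.na(r$position) & r$id != wtId(landscape), , drop = FALSE]
  if (nrow(spm) == 0L) .stopf("no positioned SPM records to score")
  pars <- c("Sm", "ddG", "ddH", "dTm")
  fl <- spm$fluorogenic
  for (p in pars) {
    bad <- fl & !is.finite(spm[[p]])
    if (any(bad))
      .stopf("incomplete record: fluorogenic SPM '%s' lacks %s",
             spm$id[bad][1], p)
  }
  X <- vapply(pars, function(p) {
    normalizeParameter(orientation[[p]] * spm[[p]], fl)
  }, numeric(nrow(spm)))
  X <- matrix(X, nrow = nrow(spm),
              dimnames = list(NULL, paste0("X_", pars)))
  Sj <- rowSums(X)
  positions <- sort(unique(spm$position))
  n <- max(positions)
  if (!identical(positions, seq_len(n)))
    .stopf("SPM positions must cover a contiguous 1..n range")
  aggFun <- if (aggregate == "mean") mean else max
  posSj <- vapply(seq_len(n),
                  function(p) aggFun(Sj[spm$position == p]), 0)
  perSPM <- DataFrame(id = spm$id, position = spm$position, X, Sj = Sj)
  new("ScoreTrack", position = seq_len(n), positionSj = posSj,
      score = positionScore(posSj), perSPM = perSPM)
}

#' Propagate replicate and fit errors for a landscape parameter
#'
#' The default `"as_printed"` mode evaluates
#' `sigma = sqrt( (sum((X_j - mean)^2) / ((N-1) N))^2 + (mean(sigma_j^2))^2 )`
#' — note both addends are squared variances, so the result carries units of
#' sigma^2; it reproduces the error recipe used with this assay family.
#' The `"quadrature"` mode is the conventional alternative
#' `sqrt( SEM^2 + mean(sigma_j^2) )` combining the squared standard error
#' of the replicate mean with the mean squared fit error.
#'
#' @param values per-replicate fit results X_j (N >= 2).
#' @param fitErrors per-replicate fit standard errors sigma_j.
#' @param mode `"as_printed"` (default) or `"quadrature"`.
#' @return the propagated error (scalar).
#' @export
#' @examples
#' propagateError(c(0, 2), c(0, 0))   # 1
propagateError <- function(values, fitErrors,
                           mode = c("as_printed", "quadrature")) {
  mode <- match.arg(mode)
  ok <- is.finite(values)
  values <- values[ok]
  fitErrors <- fitErrors[ok]
  fitErrors[!is.finite(fitErrors)] <- 0
  N <- length(values)
  if (N < 2L) .stopf("error propagation needs >= 2 replicates")
  semSq <- sum((values - mean(values))^2) / ((N - 1) * N)
  meanFitVar <- sum(fitErrors^2) / N
  if (mode == "as_printed") sqrt(semSq^2 + meanFitVar^2)
  else sqrt(semSq + meanFitVar)
}

#' Select engineering candidates beyond a quantile
#'
#' Returns the fluorogenic mutants whose oriented parameter value lies
#' strictly above the empirical `1 - q` quantile (type 7), i.e. the
#' top-`q` fraction in the beneficial direction.  With several parameters,
#' the intersection of the per-parameter top sets is returned — the mutants
#' beneficial in all of them.  Results are ordered by decreasing benefit in
#' the first parameter, ties by mutant id.
#'
#' @param landscape a [ThermoLandscape].
#' @param parameters parameter name(s): subset of `Sm`, `ddG`, `ddH`,
#'   `dTm`.
#' @param q quantile fraction (default 0.10).
#' @param orientation named +/-1 vector (see [defaultOrientation()]).
#' @param includeWT keep the wild-type record in the candidate pool
#'   (default FALSE).
#' @return character vector of selected mutant ids.
#' @export
selectQuantiles <- function(landscape, parameters = "Sm", q = 0.10,
                            orientation = defaultOrientation(),
                            includeWT = FALSE) {
  stopifnot(is(landscape, "ThermoLandscape"))
  if (q < 0 || q > 1) .stopf("q must be in [0, 1]")
  r <- records(landscape)
  r <- r[r$fluorogenic, , drop = FALSE]
  if (!includeWT) r <- r[r$id != wtId(landscape), , drop = FALSE]
  if (nrow(r) < 10L)
    .stopf("quantile selection needs >= 10 fluorogenic records, got %d",
           nrow(r))
  sets <- lapply(parameters, function(p) {
    if (!p %in% colnames(r)) .stopf("unknown parameter '%s'", p)
    v <- orientation[[p]] * r[[p]]
    ok <- is.finite(v)
    thr <- quantile(v[ok], probs = 1 - q, type = 7, names = FALSE)
    ids <- r$id[ok][v[ok] > thr]
    ord <- order(-v[ok][match(ids, r$id[ok])], ids)
    ids[ord]
  })
  Reduce(function(a, b) a[a %in% b], sets)
}

#' Compensatory rescue analysis of double-point mutants
#'
#' For each DPM, compares its signal with the signals of its two
#' constituent SPMs and the wild type.  The rescue index is
#' `(S_dpm - S_spm) / (S_wt - S_spm)` computed against the more deleterious
#' SPM (the one farther from the wild-type signal): 1 = full rescue back to
#' wild type, 0 = no rescue, negative = aggravation.  Indices are clipped
#' to [-1, 2] for reporting (raw values retained).  Pairs whose worst SPM
#' signal equals the wild type carry `undefined = TRUE`.
#'
#' @param spmSignals named numeric vector of SPM signals (names = SPM ids).
#' @param dpmSignals named numeric vector of DPM signals (names = DPM ids
#'   of the form `"<spm1>+<spm2>"`).
#' @param wtSignal wild-type signal (scalar).
#' @param elements optional named character vector labelling each DPM with
#'   a structural element (e.g. `S1`, `S2`, `S3`, `K`, `control`).
#' @return data.frame with one row per DPM: the two SPM ids, their signals,
#'   the DPM signal, raw and clipped rescue index, `undefined`, `element`.
#' @export
#' @examples
#' rescueAnalysis(c(A1G = 0.2, C2U = 0.8), c(`A1G+C2U` = 0.6), 1.0)
rescueAnalysis <- function(spmSignals, dpmSignals, wtSignal,
                           elements = NULL) {
  if (is.null(names(spmSignals)) || is.null(names(dpmSignals)))
    .stopf("spmSignals and dpmSignals must be named by mutant id")
  out <- do.call(rbind, lapply(names(dpmSignals), function(did) {
    parts <- strsplit(did, "+", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      .stopf("DPM id '%s' does not split into two SPM ids", did)
    if (!all(parts %in% names(spmSignals)))
      .stopf("DPM '%s': constituent SPM signal missing", did)
    s <- spmSignals[parts]
    worst <- parts[which.max(abs(wtSignal - s))]
    sSpm <- spmSignals[[worst]]
    denom <- wtSignal - sSpm
    undefined <- abs(denom) < .Machine$double.eps^0.5
    raw <- if (undefined) NA_real_ else
      (dpmSignals[[did]] - sSpm) / denom
    data.frame(dpm_id = did, spm1 = parts[1], spm2 = parts[2],
               S_spm1 = spmSignals[[parts[1]]],
               S_spm2 = spmSignals[[parts[2]]],
               S_spm_worst = sSpm, S_dpm = dpmSignals[[did]],
               S_wt = wtSignal,
               rescueRaw = raw,
               rescue = if (is.na(raw)) NA_real_ else
                 min(max(raw, -1), 2),
               undefined = undefined,
               stringsAsFactors = FALSE)
  }))
  out$element <- if (is.null(elements)) NA_character_
    else unname(elements[out$dpm_id])
  rownames(out) <- NULL
  out
}

#' Correlate two landscape parameters
#'
#' Ordinary least-squares line and Pearson correlation between two
#' landscape parameters over fluorogenic mutants, the relation used to
#' trade fluorescence against binding or stability when selecting
#' engineering candidates.
#'
#' @param landscape a [ThermoLandscape].
#' @param xParam,yParam parameter column names.
#' @param fluorogenicOnly restrict to fluorogenic records (default TRUE).
#' @return list with `slope`, `intercept`, `r`, `n`.
#' @export
correlateLandscapes <- function(landscape, xParam, yParam,
                                fluorogenicOnly = TRUE) {
  stopifnot(is(landscape, "ThermoLandscape"))
  r <- records(landscape)
  if (fluorogenicOnly) r <- r[r$fluorogenic, , drop = FALSE]
  x <- r[[xParam]]; y <- r[[yParam]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) .stopf("need >= 3 paired finite values")
  if (sd(x) <= 0) .stopf("undefined slope: x has no variance")
  fit <- lm(y ~ x)
  pearson <- if (sd(y) > 0) cor(x, y) else 0
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = pearson, n = length(x))
}
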