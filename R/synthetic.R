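## Synthetic chip-data generator.  Produces ground-truth mutant ensembles
## anchored at the assay's wild-type values (Kd 1.18 uM at 23 C, exothermic
## binding enthalpy -9 kcal/mol, melt midpoint inside the 23-49 C scan
## window) and simulated measurements with the designs the chip uses:
## 12-point DFHBI titrations over 0.435-43.5 uM at 19/23/28 C, 2 C-step
## melts at saturating ligand, 4 replicates, ~29% non-fluorogenic mutants
## and a negative control.  Everything is seeded; identical (config, seed)
## reproduces identical data.

#' Default generator configuration
#'
#' Anchors and perturbation scales for [makeTruth()].  The wild-type
#' anchors are the assay's printed values; per-mutant perturbation scales
#' are normal with the stated standard deviations, chosen to bracket the
#' printed landscape extremes (a maximal melting-temperature gain of a few
#' degrees C, a ~1.3-fold maximal fluorescence gain, Kd spread over
#' 1-2 orders of magnitude).
#'
#' @param wtKd wild-type Kd at `TrefC`, uM.
#' @param wtDH wild-type binding enthalpy, kcal/mol (negative =
#'   exothermic).
#' @param wtTmC wild-type apparent melting temperature, Celsius.
#' @param wtDHT wild-type unfolding enthalpy, kcal/mol.
#' @param TrefC reference temperature, Celsius.
#' @param ddGSd per-SPM binding free energy perturbation sd, kcal/mol.
#' @param ddHSd per-SPM binding enthalpy perturbation sd, kcal/mol.
#' @param dTmSd per-SPM melting temperature perturbation sd, degrees C.
#' @param dHTSd per-SPM unfolding enthalpy perturbation sd, kcal/mol.
#' @param amplitudeSdLog lognormal sd of the relative fluorescence
#'   amplitude.
#' @param nonFluorFraction fraction of SPMs losing fluorogenicity
#'   (default 0.29, matching 76 of 261).
#' @param stemPenalty amplitude factor applied to SPMs at planted stem
#'   positions (strongly deleterious, as stem-disrupting mutations are).
#' @return named list.
#' @export
truthConfig <- function(wtKd = 1.18, wtDH = -9, wtTmC = 36, wtDHT = 60,
                        TrefC = 23, ddGSd = 0.3, ddHSd = 1.5, dTmSd = 2,
                        dHTSd = 5, amplitudeSdLog = 0.1,
                        nonFluorFraction = 0.29, stemPenalty = 0.25) {
  as.list(environment())
}

#' Generate a ground-truth mutant table
#'
#' One row per mutant: the wild type, every SPM of `seq` (three per
#' position), and a negative control with no aptamer core.  Per-SPM
#' perturbations are drawn from the configured distributions;
#' fluorogenicity is Bernoulli.  When `stemPairs` lists base-paired
#' positions, the three SPMs at a partner position reuse the perturbation
#' draws of the class-matched SPMs at the first position (paired residues
#' carry the same structural burden), and both positions are penalised by
#' `stemPenalty` on amplitude — this plants the score-track symmetry that
#' stem elements produce in real landscapes.
#'
#' @param seq reference sequence (default: [syntheticReference()]).
#' @param config see [truthConfig()].
#' @param seed integer seed.
#' @param stemPairs optional 2-column matrix of paired positions.
#' @return data.frame with columns `id`, `position`, `Kd_uM`, `dH`, `dS`,
#'   `Tm_C`, `dHT`, `amplitude`, `fluorogenic`, `isControl`, plus the true
#'   landscape values `Sm_true`, `ddG_true`, `ddH_true`, `dTm_true`.
#' @export
#' @examples
#' truth <- makeTruth(syntheticReference(12), seed = 1)
#' nrow(truth)   # 3 * 12 SPMs + WT + negative control
makeTruth <- function(seq = syntheticReference(), config = truthConfig(),
                      seed = 1L, stemPairs = NULL) {
  need <- names(truthConfig())
  missing <- setdiff(need, names(config))
  if (length(missing))
    .stopf("invalid config: missing entries %s",
           paste(missing, collapse = ", "))
  lib <- enumerateSPMs(seq)
  m <- mutants(lib)
  nspm <- nrow(m)
  Tref <- celsiusToKelvin(config$TrefC)
  withLocalSeed(seed, {
    ddG <- rnorm(nspm, 0, config$ddGSd)
    ddH <- rnorm(nspm, 0, config$ddHSd)
    dTm <- rnorm(nspm, 0, config$dTmSd)
    dHT <- pmax(config$wtDHT + rnorm(nspm, 0, config$dHTSd), 20)
    amp <- exp(rnorm(nspm, 0, config$amplitudeSdLog))
    fluor <- runif(nspm) >= config$nonFluorFraction
    pos <- unlist(m$pos, use.names = FALSE)
    if (!is.null(stemPairs)) {
      stemPairs <- matrix(as.integer(stemPairs), ncol = 2L)
      for (k in seq_len(nrow(stemPairs))) {
        i <- stemPairs[k, 1L]; j <- stemPairs[k, 2L]
        src <- which(pos == i); dst <- which(pos == j)
        ## class-matched copy: SPM order within a position is fixed
        ddG[dst] <- ddG[src]; ddH[dst] <- ddH[src]
        dTm[dst] <- dTm[src]; dHT[dst] <- dHT[src]
        fluor[dst] <- fluor[src]
        amp[dst] <- amp[src]
        amp[c(src, dst)] <- amp[c(src, dst)] * config$stemPenalty
      }
    }
  })
  ## favorable-negative ddG: Kd_m = Kd_wt * exp(ddG / (R Tref))
  KdSpm <- config$wtKd * exp(ddG / (.R_KCAL * Tref))
  spm <- data.frame(
    id = m$id, position = pos,
    Kd_uM = KdSpm, dH = config$wtDH + ddH,
    Tm_C = config$wtTmC + dTm, dHT = dHT,
    amplitude = ifelse(fluor, amp, 0),
    fluorogenic = fluor, isControl = FALSE,
    Sm_true = ifelse(fluor, amp, 0), ddG_true = ddG, ddH_true = ddH,
    dTm_true = dTm, stringsAsFactors = FALSE)
  wt <- data.frame(
    id = "WT", position = NA_integer_, Kd_uM = config$wtKd,
    dH = config$wtDH, Tm_C = config$wtTmC, dHT = config$wtDHT,
    amplitude = 1, fluorogenic = TRUE, isControl = FALSE,
    Sm_true = 1, ddG_true = 0, ddH_true = 0, dTm_true = 0,
    stringsAsFactors = FALSE)
  neg <- data.frame(
    id = "NEG", position = NA_integer_, Kd_uM = NA_real_, dH = NA_real_,
    Tm_C = NA_real_, dHT = NA_real_, amplitude = 0, fluorogenic = FALSE,
    isControl = TRUE, Sm_true = 0, ddG_true = NA_real_,
    ddH_true = NA_real_, dTm_true = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(wt, spm, neg)
  ## entropy consistent with (Kd_ref, dH) at Tref (binding convention)
  out$dS <- ifelse(is.finite(out$Kd_uM),
                   out$dH / Tref - .R_KCAL * log(out$Kd_uM * 1e-6),
                   NA_real_)
  rownames(out) <- NULL
  out
}

#' Noise model for simulated measurements
#'
#' Signals are perturbed as `y * (1 + N(0, multiplicative)) +
#' N(0, additive)`.  The defaults give a replicate coefficient of
#' variation of about 2% on saturated signals, inside the assay's <5% QC
#' bound.
#'
#' @param multiplicative fractional sd.
#' @param additive sd in signal units.
#' @return named list.
#' @export
noiseModel <- function(multiplicative = 0.02, additive = 0.005) {
  if (multiplicative < 0 || additive < 0) .stopf("noise sds must be >= 0")
  list(multiplicative = multiplicative, additive = additive)
}

.applyNoise <- function(y, noise) {
  y * (1 + rnorm(length(y), 0, noise$multiplicative)) +
    rnorm(length(y), 0, noise$additive)
}

#' Simulate titration curves from a truth table
#'
#' `signal = amplitude * fractionBound(D, Kd(T))`, with the temperature
#' dependence of Kd from the truth's (Kd_ref, dH) pair via
#' [kdAtTemperature()], noise applied per measurement, replicated.
#' Non-fluorogenic mutants produce additive noise only.
#'
#' @param truth a [makeTruth()] table.
#' @param tempsC titration temperatures, Celsius (default 19, 23, 28).
#' @param concs ligand series, uM (default [dfhbiSeries()]).
#' @param replicates repeats per mutant (default 4).
#' @param noise a [noiseModel()]; use `noiseModel(0, 0)` for noiseless.
#' @param seed integer seed.
#' @param TrefC reference temperature the truth's Kd is anchored at.
#' @return long data.frame: `mutant_id`, `replicate`, `temperature_C`,
#'   `conc_uM`, `signal`.
#' @export
simulateTitration <- function(truth, tempsC = c(19, 23, 28),
                              concs = dfhbiSeries(), replicates = 4L,
                              noise = noiseModel(), seed = 1L,
                              TrefC = 23) {
  grid <- expand.grid(conc_uM = concs, temperature_C = tempsC,
                      replicate = seq_len(replicates),
                      mutant_id = truth$id, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  idx <- match(grid$mutant_id, truth$id)
  hasKd <- is.finite(truth$Kd_uM[idx]) & is.finite(truth$dH[idx])
  clean <- numeric(nrow(grid))
  if (any(hasKd)) {
    KdT <- kdAtTemperature(celsiusToKelvin(grid$temperature_C[hasKd]),
                           truth$Kd_uM[idx][hasKd], truth$dH[idx][hasKd],
                           Tref = celsiusToKelvin(TrefC))
    clean[hasKd] <- truth$amplitude[idx][hasKd] *
      fractionBound(grid$conc_uM[hasKd], pmax(KdT, 1e-12))
  }
  grid$signal <- withLocalSeed(subSeed(seed, "titration"),
                               .applyNoise(clean, noise))
  grid[, c("mutant_id", "replicate", "temperature_C", "conc_uM", "signal")]
}

#' Simulate melting curves from a truth table
#'
#' `signal = amplitude * fractionFolded(T, Tm, dHT)` plus noise, on the
#' default 23-49 C grid in 2 C steps at saturating ligand.  Ids listed in
#' `bimodalIds` instead produce a misfolding low-high-low profile (no
#' signal at either temperature extreme, a moderate maximum near 35 C):
#' the product of a rising activation sigmoid and a falling melt sigmoid.
#'
#' @param truth a [makeTruth()] table.
#' @param tempsC melt temperatures, Celsius.
#' @param ligandConc saturating ligand concentration, uM (annotation
#'   only).
#' @param replicates repeats per mutant.
#' @param noise a [noiseModel()].
#' @param seed integer seed.
#' @param bimodalIds mutant ids given the bimodal misfolding profile.
#' @return long data.frame: `mutant_id`, `replicate`, `temperature_C`,
#'   `ligand_uM`, `signal`.
#' @export
simulateMelting <- function(truth, tempsC = seq(23, 49, by = 2),
                            ligandConc = 43.5, replicates = 4L,
                            noise = noiseModel(), seed = 1L,
                            bimodalIds = character()) {
  grid <- expand.grid(temperature_C = tempsC,
                      replicate = seq_len(replicates),
                      mutant_id = truth$id, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  idx <- match(grid$mutant_id, truth$id)
  Tk <- celsiusToKelvin(grid$temperature_C)
  ok <- is.finite(truth$Tm_C[idx]) & truth$amplitude[idx] > 0
  clean <- numeric(nrow(grid))
  clean[ok] <- truth$amplitude[idx][ok] *
    fractionFolded(Tk[ok], celsiusToKelvin(truth$Tm_C[idx][ok]),
                   truth$dHT[idx][ok])
  bi <- grid$mutant_id %in% bimodalIds
  if (any(bi)) {
    amp <- ifelse(is.finite(truth$amplitude[idx][bi]) &
                    truth$amplitude[idx][bi] > 0,
                  truth$amplitude[idx][bi], 1)
    rise <- 1 / (1 + exp((60 / .R_KCAL) *
                           (1 / Tk[bi] - 1 / celsiusToKelvin(31))))
    fall <- fractionFolded(Tk[bi], celsiusToKelvin(39), 60)
    clean[bi] <- amp * rise * fall / 0.25   # renormalised to peak ~amp
  }
  grid$signal <- withLocalSeed(subSeed(seed, "melting"),
                               .applyNoise(clean, noise))
  grid$ligand_uM <- ligandConc
  grid[, c("mutant_id", "replicate", "temperature_C", "ligand_uM",
           "signal")]
}

#' Simulate a single pull-down spot image
#'
#' A rotated elliptical Gaussian spot on a constant background with
#' Gaussian pixel noise; the building block of [simulateChipImages()] and
#' of segmentation tests.
#'
#' @param size image side length (pixels; square).
#' @param center spot centre (row, col).
#' @param sigma Gaussian width(s); length 1 or 2.
#' @param amplitude peak height above offset.
#' @param offset background level.
#' @param theta rotation, radians.
#' @param noiseSd Gaussian pixel noise sd.
#' @param seed optional integer seed.
#' @return numeric `size x size` matrix (non-negative).
#' @export
simulateSpotImage <- function(size = 64L, center = c(size / 2, size / 2),
                              sigma = 6, amplitude = 100, offset = 10,
                              theta = 0, noiseSd = 0, seed = NULL) {
  sigma <- rep(sigma, length.out = 2L)
  rr <- row(matrix(0, size, size)) - center[1]
  cc <- col(matrix(0, size, size)) - center[2]
  a <- cos(theta)^2 / (2 * sigma[1]^2) + sin(theta)^2 / (2 * sigma[2]^2)
  b <- sin(2 * theta) / 4 * (1 / sigma[2]^2 - 1 / sigma[1]^2)
  cq <- sin(theta)^2 / (2 * sigma[1]^2) + cos(theta)^2 / (2 * sigma[2]^2)
  img <- amplitude * exp(-(a * rr^2 + 2 * b * rr * cc + cq * cc^2)) + offset
  if (noiseSd > 0)
    img <- withLocalSeed(seed, img + matrix(rnorm(size^2, 0, noiseSd),
                                            size, size))
  pmax(img, 0)
}

#' Simulate three-channel unit-cell images for a chip layout
#'
#' For every assigned cell, draws the anchor and probe channels with
#' constant spot amplitude (the pull-down area and RNA amount) and the
#' complex channel with amplitude proportional to the cell's normalised
#' signal.  A cell with zero signal still shows its anchor spot.
#' Generation parameters are recorded per cell for recovery tests.
#'
#' @param layout a [ChipLayout].
#' @param signals named numeric vector: normalised signal per mutant id
#'   (or per cell when named by cell number).
#' @param size image side, pixels.
#' @param sigma spot Gaussian width, pixels.
#' @param probeAmplitude probe (and anchor) spot peak height.
#' @param offset background level.
#' @param snr signal-to-noise ratio: pixel noise sd =
#'   `probeAmplitude / snr`.
#' @param seed integer seed.
#' @return named list (one element per cell) of lists with matrices
#'   `complex`, `anchor`, `probe` and the generation record `truth`.
#' @export
simulateChipImages <- function(layout, signals, size = 48L, sigma = 5,
                               probeAmplitude = 100, offset = 10,
                               snr = 20, seed = 1L) {
  stopifnot(is(layout, "ChipLayout"))
  a <- assignment(layout)
  bySignal <- if (!is.null(names(signals))) signals else
    setNames(signals, a$mutant_id)
  if (!all(a$mutant_id %in% names(bySignal)))
    .stopf("every layout cell needs a signal (missing: %s)",
           setdiff(a$mutant_id, names(bySignal))[1])
  noiseSd <- probeAmplitude / snr
  withLocalSeed(subSeed(seed, "images"), {
    out <- lapply(seq_len(nrow(a)), function(k) {
      ctr <- size / 2 + runif(2, -2, 2)
      sm <- bySignal[[a$mutant_id[k]]]
      mk <- function(ampl) {
        img <- simulateSpotImage(size, ctr, sigma, ampl, offset,
                                 noiseSd = 0)
        pmax(img + matrix(rnorm(size^2, 0, noiseSd), size, size), 0)
      }
      list(complex = mk(sm * probeAmplitude),
           anchor = mk(probeAmplitude),
           probe = mk(probeAmplitude),
           truth = list(cell = a$cell[k], mutant_id = a$mutant_id[k],
                        replicate = a$replicate[k], center = ctr,
                        sigma = sigma, Sm = sm))
    })
    names(out) <- paste0("cell", a$cell)
    out
  })
}

#' Simulate a complete chip experiment
#'
#' Truth table, layout, titration and melt series in one seeded object.
#' The chip is auto-sized to hold the whole library when it exceeds the
#' default 640-cell capacity (a real run would split it across chips).
#'
#' @param seq reference sequence.
#' @param config see [truthConfig()].
#' @param seed integer seed.
#' @param replicates repeats per mutant.
#' @param noise a [noiseModel()].
#' @param tempsC titration temperatures, Celsius.
#' @param meltTempsC melt temperatures, Celsius.
#' @param stemPairs optional planted stem pairs (see [makeTruth()]).
#' @param nCells unit cells; default auto-sizes to fit the library.
#' @return a [SyntheticChip].
#' @export
#' @examples
#' chip <- simulateChip(syntheticReference(8), seed = 7)
simulateChip <- function(seq = syntheticReference(),
                         config = truthConfig(), seed = 1L,
                         replicates = 4L, noise = noiseModel(),
                         tempsC = c(19, 23, 28),
                         meltTempsC = seq(23, 49, by = 2),
                         stemPairs = NULL, nCells = NULL) {
  truth <- makeTruth(seq, config, seed = subSeed(seed, "truth"),
                     stemPairs = stemPairs)
  if (is.null(nCells))
    nCells <- max(640L, as.integer(replicates * nrow(truth)))
  layout <- planChipLayout(truth$id, nCells = nCells,
                           replicates = replicates,
                           controls = truth$id[truth$isControl])
  titr <- simulateTitration(truth, tempsC = tempsC,
                            replicates = replicates, noise = noise,
                            seed = seed, TrefC = config$TrefC)
  melt <- simulateMelting(truth, tempsC = meltTempsC,
                          replicates = replicates, noise = noise,
                          seed = seed)
  new("SyntheticChip", truth = truth, titrations = titr, melts = melt,
      layout = layout, seed = as.integer(seed),
      config = c(config, list(replicates = replicates, noise = noise,
                              tempsC = tempsC, meltTempsC = meltTempsC)))
}

#' Simulate a compensatory double-mutant rescue screen
#'
#' Emulates the signal pattern of a stem rescue experiment: a single
#' mutation inside a stem disrupts pairing and collapses the fluorescence,
#' and the joint mutation of its partner base restores pairing and most of
#' the signal, whereas a double mutation across two *unpaired* positions
#' (a mismatched control pair) rescues nothing.  Returns normalised
#' saturating-ligand signals for the wild type, the disrupting SPMs, the
#' pairing-restoring DPMs at `stemPairs`, and non-rescuing DPMs at
#' `controlPairs`.
#'
#' @param seq reference sequence.
#' @param stemPairs 2-column matrix of truly base-paired positions.
#' @param controlPairs 2-column matrix of unpaired (mismatched control)
#'   position pairs.
#' @param spmLevel mean SPM signal relative to wild type (structure
#'   disrupted).
#' @param rescueLevel mean stem-DPM signal relative to wild type
#'   (structure restored).
#' @param noise a [noiseModel()].
#' @param seed integer seed.
#' @return list with `wtSignal`, named vectors `spmSignals` and
#'   `dpmSignals`, and `elements` labelling each DPM `"stem"` or
#'   `"control"`.
#' @export
simulateCompensation <- function(seq = syntheticReference(30),
                                 stemPairs, controlPairs,
                                 spmLevel = 0.2, rescueLevel = 0.9,
                                 noise = noiseModel(), seed = 1L) {
  ref <- .checkAlphabet(.asRNAString(seq))
  stemPairs <- matrix(as.integer(stemPairs), ncol = 2L)
  controlPairs <- matrix(as.integer(controlPairs), ncol = 2L)
  spmId <- function(p) paste0(ref[p], p, .BASE_ALTERNATIVES[[ref[p]]][1])
  mkPairs <- function(pairs) {
    vapply(seq_len(nrow(pairs)),
           function(k) paste(spmId(pairs[k, 1]), spmId(pairs[k, 2]),
                             sep = "+"), "")
  }
  spmPos <- unique(c(stemPairs, controlPairs))
  spmIds <- vapply(spmPos, spmId, "")
  stemIds <- mkPairs(stemPairs)
  ctlIds <- mkPairs(controlPairs)
  withLocalSeed(subSeed(seed, "compensation"), {
    spmSignals <- setNames(.applyNoise(rep(spmLevel, length(spmIds)),
                                       noise), spmIds)
    dpmSignals <- setNames(
      .applyNoise(c(rep(rescueLevel, length(stemIds)),
                    rep(spmLevel, length(ctlIds))), noise),
      c(stemIds, ctlIds))
    wtSignal <- .applyNoise(1, noise)
  })
  list(wtSignal = wtSignal, spmSignals = spmSignals,
       dpmSignals = dpmSignals,
       elements = setNames(rep(c("stem", "control"),
                               c(length(stemIds), length(ctlIds))),
                           c(stemIds, ctlIds)))
}

#' Deterministic synthetic reference sequence
#'
#' A reproducible stand-in reference for examples, tests and simulations:
#' none of the package's machinery depends on the identity of the bases,
#' only on length and alphabet, so a fixed-seed uniform draw over
#' {A,C,G,U} serves as a synthetic reference.  Real analyses should pass
#' their own aptamer sequence (see [readReferenceSequence()]).
#'
#' @param n sequence length (default 87).
#' @param seed integer seed (default 87).
#' @return an [Biostrings::RNAString].
#' @export
#' @examples
#' syntheticReference(12)
syntheticReference <- function(n = 87L, seed = 87L) {
  ch <- withLocalSeed(seed, sample(.RNA_BASES, n, replace = TRUE))
  RNAString(paste(ch, collapse = ""))
}
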