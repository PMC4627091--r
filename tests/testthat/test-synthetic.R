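test_that("truth tables anchor the wild type and cover the full SPM scan", {
  truth <- makeTruth(syntheticReference(87), seed = 1)
  expect_equal(nrow(truth), 261L + 2L)   # SPMs + WT + negative control
  wt <- truth[truth$id == "WT", ]
  expect_equal(wt$Kd_uM, 1.18)
  expect_equal(wt$dH, -9)
  expect_true(wt$Tm_C > 23 && wt$Tm_C < 49)
  expect_true(truth$isControl[truth$id == "NEG"])
  expect_equal(truth$amplitude[truth$id == "NEG"], 0)

  # ~29% of SPMs lose fluorogenicity under the default config
  spm <- truth[!truth$id %in% c("WT", "NEG"), ]
  expect_gt(mean(!spm$fluorogenic), 0.20)
  expect_lt(mean(!spm$fluorogenic), 0.40)

  # derived entropy is consistent: Kd rebuilt from (dH, dS) at the
  # reference temperature equals the tabulated Kd
  ok <- is.finite(truth$Kd_uM)
  lnKdM <- truth$dH[ok] / (gasConstantKcal() * 296.15) -
    truth$dS[ok] / gasConstantKcal()
  expect_equal(exp(lnKdM) * 1e6, truth$Kd_uM[ok], tolerance = 1e-9)

  expect_identical(makeTruth(syntheticReference(10), seed = 7),
                   makeTruth(syntheticReference(10), seed = 7))
  allFluor <- makeTruth(syntheticReference(10), seed = 7,
                        config = truthConfig(nonFluorFraction = 0))
  expect_true(all(allFluor$fluorogenic[allFluor$id != "NEG"]))
  expect_error(makeTruth(syntheticReference(5), config = list(wtKd = 1)),
               "config")
})

test_that("simulated titrations follow the isotherm with Van't Hoff Kd(T)", {
  truth <- makeTruth(syntheticReference(4), seed = 3)
  concs <- sort(unique(c(dfhbiSeries(), 1.18)))
  ti <- simulateTitration(truth, concs = concs, noise = noiseModel(0, 0),
                          seed = 3)
  wt <- ti[ti$mutant_id == "WT" & ti$replicate == 1 &
           ti$temperature_C == 23, ]
  expect_equal(wt$signal[wt$conc_uM == 1.18], 0.5)   # amplitude 1, D = Kd

  # non-fluorogenic rows carry no signal in the noiseless limit
  nf <- truth$id[!truth$fluorogenic][1]
  expect_true(all(ti$signal[ti$mutant_id == nf] == 0))

  # exothermic wild type: weaker binding when warmer
  kd19 <- fitBinding(wt$conc_uM,
                     ti$signal[ti$mutant_id == "WT" & ti$replicate == 1 &
                               ti$temperature_C == 19])@Kd
  kd28 <- fitBinding(wt$conc_uM,
                     ti$signal[ti$mutant_id == "WT" & ti$replicate == 1 &
                               ti$temperature_C == 28])@Kd
  expect_lt(kd19, kd28)
})

test_that("simulated melts use the 2-degree grid and the two-state profile", {
  truth <- makeTruth(syntheticReference(4), seed = 4)
  mel <- simulateMelting(truth, noise = noiseModel(0, 0), seed = 4)
  wt1 <- mel[mel$mutant_id == "WT" & mel$replicate == 1, ]
  expect_equal(nrow(wt1), 14L)                      # 23..49 step 2
  expect_equal(wt1$temperature_C, seq(23, 49, 2))
  expect_equal(unique(mel$ligand_uM), 43.5)
  TmC <- truth$Tm_C[truth$id == "WT"]
  sigAtTm <- approx(wt1$temperature_C, wt1$signal, xout = TmC)$y
  expect_equal(sigAtTm, 0.5, tolerance = 0.02)      # half the amplitude
})

test_that("simulation is deterministic in (config, seed)", {
  t1 <- simulateTitration(makeTruth(syntheticReference(5), seed = 9),
                          seed = 9)
  t2 <- simulateTitration(makeTruth(syntheticReference(5), seed = 9),
                          seed = 9)
  expect_identical(t1, t2)
  c1 <- simulateChip(syntheticReference(5), seed = 9)
  c2 <- simulateChip(syntheticReference(5), seed = 9)
  expect_identical(truthTable(c1), truthTable(c2))
  expect_identical(titrations(c1), titrations(c2))
  expect_identical(melts(c1), melts(c2))

  lay <- planChipLayout(c("A1G", "C2U"), nCells = 4, replicates = 2)
  i1 <- simulateChipImages(lay, c(A1G = 0.5, C2U = 1), seed = 5)
  i2 <- simulateChipImages(lay, c(A1G = 0.5, C2U = 1), seed = 5)
  expect_identical(i1[[1]]$complex, i2[[1]]$complex)
})

test_that("zero-signal cells still show anchor spots but a flat complex channel", {
  lay <- planChipLayout("NEG", nCells = 1, replicates = 1)
  imgs <- simulateChipImages(lay, c(NEG = 0), size = 48, seed = 2,
                             probeAmplitude = 100, offset = 10, snr = 20)
  cell <- imgs[[1]]
  expect_gt(max(cell$anchor), 60)                  # spot present
  expect_lt(max(cell$complex), 40)                 # background + noise only
  expect_true(fitSpot(cell$anchor)@converged)
  expect_false(fitSpot(cell$complex)@converged)
})

test_that("default noise keeps replicate CV inside the assay's QC bound", {
  chip <- simulateChip(syntheticReference(15), seed = 6)
  ti <- titrations(chip)
  top <- ti[ti$conc_uM == max(ti$conc_uM) & ti$temperature_C == 23, ]
  qc <- replicateQC(data.frame(mutant_id = top$mutant_id,
                               replicate = top$replicate,
                               Sm = top$signal))
  tr <- truthTable(chip)
  fluor <- qc$perMutant$mutant_id %in% tr$id[tr$fluorogenic]
  expect_lt(median(qc$perMutant$cv[fluor], na.rm = TRUE), 0.05)
})
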