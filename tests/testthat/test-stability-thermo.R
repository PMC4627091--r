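test_that("folded fraction is half at Tm and follows the two-state form", {
  set.seed(2)
  for (i in 1:20) {
    Tm <- runif(1, 290, 330); dHT <- runif(1, 10, 200)
    expect_equal(fractionFolded(Tm, Tm, dHT), 0.5)
  }
  expect_equal(fractionFolded(325, 315, 50), 0.0789, tolerance = 1e-3)
  expect_equal(fractionFolded(1e-6, 315, 50), 1)
  # strictly decreasing in T for positive unfolding enthalpy
  Tk <- seq(280, 340, 2)
  expect_true(all(diff(fractionFolded(Tk, 310, 60)) < 0))
  expect_error(fractionFolded(-1, 310, 60), "> 0")

  # the hot-side asymptote is 1/(1 + exp(dHT/(R Tm))), not zero
  asym <- 1 / (1 + exp(60 / (gasConstantKcal() * 312.15)))
  expect_equal(fractionFolded(1e9, 312.15, 60), asym, tolerance = 1e-12)
})

test_that("melting fits recover noiseless generating parameters", {
  Tk <- celsiusToKelvin(seq(23, 49, 2))
  for (TmC in c(30, 36, 42)) {
    for (dHT in c(40, 60, 90)) {
      y <- 0.9 * fractionFolded(Tk, celsiusToKelvin(TmC), dHT)
      f <- fitMelting(Tk, y)
      expect_true(f@converged)
      expect_lt(abs(kelvinToCelsius(f@Tm) - TmC), 1e-5)
      expect_lt(abs(f@dHT - dHT) / dHT, 1e-5)
      expect_lt(abs(f@amplitude - 0.9), 1e-5)
    }
  }
  # residuals at the hottest points honour the model's non-zero asymptote
  y <- fractionFolded(Tk, 305, 80)
  f <- fitMelting(Tk, y)
  expect_equal(f@amplitude * fractionFolded(Tk[14], f@Tm, f@dHT), y[14],
               tolerance = 1e-6)
})

test_that("anchored-amplitude mode reproduces the low-temperature normalisation", {
  Tk <- celsiusToKelvin(seq(23, 49, 2))
  y <- 0.8 * fractionFolded(Tk, 312.15, 60)
  f <- fitMelting(Tk, y, amplitudeMode = "anchor")
  expect_true(f@converged)
  expect_equal(f@amplitude, y[1])
  expect_lt(abs(kelvinToCelsius(f@Tm) - 39), 1)
})

test_that("noisy melting fits keep the median Tm error under half a degree", {
  Tk <- celsiusToKelvin(seq(23, 49, 2))
  clean <- 0.9 * fractionFolded(Tk, 312.15, 60)
  set.seed(23)
  errs <- vapply(1:100, function(i) {
    y <- clean * (1 + rnorm(14, 0, 0.02))
    abs(kelvinToCelsius(fitMelting(Tk, y)@Tm) - 39)
  }, 0)
  expect_lt(median(errs), 0.5)
})

test_that("degenerate melt curves are flagged, not fitted", {
  Tk <- celsiusToKelvin(seq(23, 49, 2))
  f0 <- fitMelting(Tk, rep(0, 14))
  expect_false(f0@converged)
  expect_true("non_fluorogenic" %in% f0@flags)

  rising <- fitMelting(Tk, seq(0.1, 1, length.out = 14))
  expect_false(rising@converged)
  expect_true("no_transition" %in% rising@flags)
})

test_that("bimodal melts are detected and ordinary ones are not", {
  Tc <- seq(23, 49, 2)
  hump <- exp(-(Tc - 35)^2 / 18)
  expect_true(detectBimodal(Tc, hump)$bimodal)
  expect_lt(abs(detectBimodal(Tc, hump)$peakTemperature - 35), 2.1)

  sigmoid <- fractionFolded(celsiusToKelvin(Tc), 312.15, 60)
  expect_false(detectBimodal(Tc, sigmoid)$bimodal)
  expect_false(detectBimodal(Tc, rep(0.5, 14))$bimodal)
  expect_error(detectBimodal(Tc[1:5], hump[1:5]), ">= 7")

  # end to end: a simulated misfolding mutant trips the detector and flag
  truth <- makeTruth(syntheticReference(4), seed = 2)
  mel <- simulateMelting(truth, noise = noiseModel(0, 0), seed = 2,
                         bimodalIds = "WT")
  wt1 <- mel[mel$mutant_id == "WT" & mel$replicate == 1, ]
  expect_true(detectBimodal(wt1$temperature_C, wt1$signal)$bimodal)
  f <- fitMelting(celsiusToKelvin(wt1$temperature_C), wt1$signal)
  expect_true(f@bimodal)
})
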