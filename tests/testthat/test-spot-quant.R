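test_that("spot segmentation recovers the generating geometry", {
  for (case in list(list(center = c(32, 32), sigma = 6),
                    list(center = c(28.5, 35.2), sigma = c(5, 7)))) {
    img <- simulateSpotImage(64, case$center, case$sigma, amplitude = 100,
                             offset = 10, noiseSd = 5, seed = 11)
    g <- fitSpot(img)
    expect_true(g@converged)
    expect_lt(max(abs(g@center - case$center)), 0.2)
    expect_equal(g@annulusOuter, 1.5 * g@radius)
  }
})

test_that("flat images are flagged as segmentation failures", {
  expect_false(fitSpot(matrix(5, 64, 64))@converged)
  noiseOnly <- simulateSpotImage(64, amplitude = 0, offset = 10,
                                 noiseSd = 2, seed = 1)
  expect_false(fitSpot(noiseOnly)@converged)
})

test_that("spot fits are translation-equivariant", {
  base <- c(30, 34)
  g0 <- fitSpot(simulateSpotImage(64, base, 6, 100, 10, noiseSd = 3,
                                  seed = 5))
  g1 <- fitSpot(simulateSpotImage(64, base + c(3, -2), 6, 100, 10,
                                  noiseSd = 3, seed = 5))
  expect_lt(max(abs((g1@center - g0@center) - c(3, -2))), 0.3)
})

test_that("signal extraction computes (Si - Sb) / Sp from medians", {
  fx <- flatSpotImages(fg = 10, bg = 2, probe = 4)
  s <- extractSignals(fx$complexImg, probeImg = fx$probeImg,
                      geometry = fx$geometry)
  expect_equal(s$Sm, 2.0)
  expect_equal(s$Si, 10); expect_equal(s$Sb, 2); expect_equal(s$Sp, 4)

  # complex channel flat at the annulus level -> Sm = 0
  flat <- flatSpotImages(fg = 2, bg = 2, probe = 4)
  expect_equal(extractSignals(flat$complexImg, probeImg = flat$probeImg,
                              geometry = flat$geometry)$Sm, 0)

  # linearity: scaling the complex channel scales Sm
  expect_equal(extractSignals(3 * fx$complexImg, probeImg = fx$probeImg,
                              geometry = fx$geometry)$Sm, 6.0)

  # constant offset on the complex channel cancels via the annulus median
  expect_equal(extractSignals(fx$complexImg + 7, probeImg = fx$probeImg,
                              geometry = fx$geometry)$Sm, 2.0)

  # zero probe -> undefined normalisation, flagged not dropped
  s0 <- extractSignals(fx$complexImg, probeImg = 0 * fx$probeImg,
                       geometry = fx$geometry)
  expect_true("undefined_normalization" %in% s0$flags)
  expect_true(is.na(s0$Sm))
})

test_that("median extraction tolerates salt-and-pepper outliers", {
  fx <- flatSpotImages(fg = 10, bg = 2, probe = 4)
  img <- fx$complexImg
  fgIdx <- which(img == 10)
  set.seed(8)
  hit <- sample(fgIdx, floor(0.1 * length(fgIdx)))
  img[hit] <- ifelse(seq_along(hit) %% 2 == 0, 0, 1e4)
  s <- extractSignals(img, probeImg = fx$probeImg, geometry = fx$geometry)
  expect_equal(s$Sm, 2.0)
})

test_that("replicate QC reports CV and inter-replicate correlation", {
  sig <- data.frame(mutant_id = rep(c("A", "B", "C"), each = 2),
                    replicate = rep(1:2, 3),
                    Sm = c(1, 1, 2, 2, 3, 3))
  qc <- replicateQC(sig)
  expect_equal(qc$perMutant$cv, c(0, 0, 0))
  expect_equal(unname(qc$replicateCor["rep1", "rep2"]), 1)

  qc2 <- replicateQC(data.frame(mutant_id = c("A", "A", "B", "B"),
                                replicate = c(1, 2, 1, 2),
                                Sm = c(9, 11, 5, 1)))
  expect_equal(qc2$perMutant$cv[1], sd(c(9, 11)) / 10)

  anti <- data.frame(mutant_id = rep(c("A", "B", "C"), each = 2),
                     replicate = rep(1:2, 3),
                     Sm = c(1, 3, 2, 2, 3, 1))
  expect_equal(unname(replicateQC(anti)$replicateCor["rep1", "rep2"]), -1)

  # near-zero mean -> CV undefined rather than exploding
  z <- data.frame(mutant_id = rep("A", 2), replicate = 1:2,
                  Sm = c(1e-12, -1e-12))
  expect_error(replicateQC(z[1, ]), "replicates")
  qc3 <- replicateQC(rbind(z, data.frame(mutant_id = "B",
                                         replicate = 1:2, Sm = c(1, 1))))
  expect_true(is.na(qc3$perMutant$cv[qc3$perMutant$mutant_id == "A"]))
})

test_that("quantified synthetic chips preserve the generated signal ranking", {
  ids <- sprintf("M%02d", 1:12)
  lay <- planChipLayout(ids, nCells = 12, replicates = 1)
  sm <- setNames(seq(0.05, 1.5, length.out = 12), ids)
  imgs <- simulateChipImages(lay, sm, size = 48, sigma = 5,
                             probeAmplitude = 100, snr = 10, seed = 21)
  rec <- vapply(imgs, function(cell) {
    g <- fitSpot(cell$anchor)
    extractSignals(cell$complex, probeImg = cell$probe, geometry = g)$Sm
  }, 0)
  truthSm <- vapply(imgs, function(cell) cell$truth$Sm, 0)
  expect_gt(cor(rec, truthSm, method = "spearman"), 0.95)
})
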