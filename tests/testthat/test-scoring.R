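test_that("min-max normalisation maps the range onto [0,1] and flags by -1", {
  x <- c(2, 6, 10)
  expect_equal(normalizeParameter(x), c(0, 0.5, 1))
  expect_equal(normalizeParameter(c(2, 6, 10, 99),
                                  c(TRUE, TRUE, TRUE, FALSE)),
               c(0, 0.5, 1, -1))
  expect_error(normalizeParameter(c(3, 3, 3)), "degenerate")

  # invariant under positive affine transforms
  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(15); a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(normalizeParameter(a * v + b), normalizeParameter(v),
                 tolerance = 1e-12)
  }
})

test_that("per-SPM scores sum the four normalised parameters with bounds", {
  truth <- makeTruth(syntheticReference(12), seed = 5)
  ls <- truthLandscape(truth)
  st <- scoreLandscape(ls)
  per <- as.data.frame(st@perSPM)
  X <- as.matrix(per[, c("X_Sm", "X_ddG", "X_ddH", "X_dTm")])
  expect_equal(per$Sj, rowSums(X))
  expect_true(all(per$Sj >= -4 & per$Sj <= 4))
  # non-fluorogenic SPMs sit at -1 on every parameter, hence S_j = -4:
  # always the bottom of every parameter ranking
  nf <- !truth$fluorogenic[match(per$id, truth$id)]
  expect_true(all(per$Sj[nf] == -4))
  expect_true(all(X[nf, ] == -1))
  expect_true(all(X[!nf, ] >= 0 & X[!nf, ] <= 1))
  # the smoothed track stays inside the per-position score range
  expect_true(all(st@score >= min(st@positionSj) - 1e-12 &
                  st@score <= max(st@positionSj) + 1e-12))
})

test_that("a fluorogenic SPM lacking a parameter is an incomplete record", {
  truth <- makeTruth(syntheticReference(6), seed = 5,
                     config = truthConfig(nonFluorFraction = 0))
  truth$dTm_true[3] <- NA
  expect_error(scoreLandscape(truthLandscape(truth)), "incomplete record")
})

test_that("the window-3 moving average truncates at the termini", {
  expect_equal(positionScore(c(0, 3, 0)), c(1.5, 1, 1.5))
  expect_equal(positionScore(rep(2.5, 9)), rep(2.5, 9))
  expect_equal(positionScore(4), 4)
  set.seed(6)
  for (i in 1:10) {
    s <- rnorm(20)
    sc <- positionScore(s)
    expect_true(all(sc >= min(s) & sc <= max(s)))
  }
})

test_that("error propagation evaluates both the as-printed and quadrature modes", {
  expect_equal(propagateError(c(1, 1, 1), c(0, 0, 0)), 0)
  expect_equal(propagateError(c(0, 2), c(0, 0)), 1)
  # identical values, constant fit error s: the as-printed formula returns
  # s^2 (a squared quantity), the quadrature mode returns s
  s <- 0.3
  expect_equal(propagateError(c(1, 1, 1), rep(s, 3)), s^2)
  expect_equal(propagateError(c(1, 1, 1), rep(s, 3), mode = "quadrature"),
               s)
  # quadrature mode equals sqrt(SEM^2 + mean sigma_j^2)
  x <- c(0.9, 1.1, 1.3, 0.8); e <- c(0.05, 0.07, 0.04, 0.06)
  expect_equal(propagateError(x, e, mode = "quadrature"),
               sqrt(sum((x - mean(x))^2) / (3 * 4) + mean(e^2)))
  expect_error(propagateError(1, 0.1), ">= 2")
})

test_that("quantile selection takes the beneficial tail and intersects", {
  df <- data.frame(id = c("WT", sprintf("M%02d", 1:10)),
                   Sm = c(1, seq(0.1, 1.0, 0.1)),
                   ddG = c(0, seq(0.45, -0.45, length.out = 10)),
                   ddH = 0, dTm = c(0, seq(-2, 2.5, length.out = 10)),
                   fluorogenic = TRUE)
  df$ddH <- c(0, rnorm(10, 0, 0.1))
  ls <- newThermoLandscape(df, "WT")
  expect_equal(selectQuantiles(ls, "Sm", q = 0.1), "M10")
  expect_equal(selectQuantiles(ls, "ddG", q = 0.1), "M10")  # most negative
  expect_length(selectQuantiles(ls, "Sm", q = 0), 0)
  # intersection over parameters that agree on the top mutant
  expect_equal(selectQuantiles(ls, c("Sm", "ddG", "dTm"), q = 0.1), "M10")
  # disjoint top sets intersect to nothing
  df2 <- df; df2$dTm <- c(0, seq(2.5, -2, length.out = 10))
  expect_length(selectQuantiles(newThermoLandscape(df2, "WT"),
                                c("Sm", "dTm"), q = 0.1), 0)
  expect_error(selectQuantiles(newThermoLandscape(df[1:6, ], "WT"), "Sm"),
               ">= 10")
})

test_that("rescue indices interpolate between perturbed and wild-type signals", {
  ra <- rescueAnalysis(c(A1G = 0.2, C2U = 0.8), c(`A1G+C2U` = 0.6), 1.0)
  expect_equal(ra$rescue, 0.5)
  expect_equal(ra$S_spm_worst, 0.2)  # the more deleterious SPM anchors it
  expect_equal(rescueAnalysis(c(A1G = 0.2, C2U = 0.8),
                              c(`A1G+C2U` = 1.0), 1.0)$rescue, 1)
  expect_equal(rescueAnalysis(c(A1G = 0.2, C2U = 0.8),
                              c(`A1G+C2U` = 0.2), 1.0)$rescue, 0)
  # aggravation clips at -1 for reporting, raw value kept
  worse <- rescueAnalysis(c(A1G = 0.5, C2U = 0.9), c(`A1G+C2U` = -1), 1.0)
  expect_equal(worse$rescue, -1)
  expect_lt(worse$rescueRaw, -1)
  und <- rescueAnalysis(c(A1G = 1.0, C2U = 1.0), c(`A1G+C2U` = 0.5), 1.0)
  expect_true(und$undefined)
})

test_that("landscape correlations recover planted linear relations", {
  df <- data.frame(id = c("WT", sprintf("M%02d", 1:20)),
                   Sm = 1, ddG = c(0, seq(-1, 1, length.out = 20)),
                   ddH = 0, dTm = 0, fluorogenic = TRUE)
  df$Sm <- 2 * df$ddG          # exact line through every record
  ls <- newThermoLandscape(df, "WT")
  cl <- correlateLandscapes(ls, "ddG", "Sm")
  expect_equal(cl$slope, 2, tolerance = 1e-9)
  expect_equal(cl$r, 1, tolerance = 1e-9)

  flat <- df; flat$Sm <- rep(1, 21)
  expect_equal(correlateLandscapes(newThermoLandscape(flat, "WT"),
                                   "ddG", "Sm")$slope, 0, tolerance = 1e-9)

  set.seed(31)
  noisy <- df
  noisy$Sm <- 0.67 * df$ddG + rnorm(21, 0, 0.05)
  cl2 <- correlateLandscapes(newThermoLandscape(noisy, "WT"), "ddG", "Sm")
  se <- 0.05 / (sd(df$ddG) * sqrt(20))
  expect_lt(abs(cl2$slope - 0.67), 3 * se)
})
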