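test_that("bound fraction follows the two-state isotherm", {
  expect_equal(fractionBound(1.18, 1.18), 0.5)
  expect_equal(fractionBound(0, 2.5), 0)
  expect_equal(fractionBound(43.5, 1.18), 0.9736, tolerance = 1e-4)
  expect_error(fractionBound(1, 0), "Kd")

  # monotone in D and in 1/Kd over random grids
  set.seed(1)
  for (i in 1:20) {
    D <- sort(runif(10, 0, 100))
    Kd <- runif(1, 0.01, 50)
    expect_true(all(diff(fractionBound(D, Kd)) > 0))
    Kds <- sort(runif(10, 0.01, 50))
    expect_true(all(diff(fractionBound(5, Kds)) < 0))
  }
})

test_that("binding fits recover noiseless generating parameters", {
  D <- dfhbiSeries()
  for (Kd in c(0.3, 1.18, 12)) {
    for (amp in c(0.4, 1, 2.5)) {
      f <- fitBinding(D, amp * fractionBound(D, Kd))
      expect_true(f@converged)
      expect_lt(abs(f@Kd - Kd) / Kd, 1e-6)
      expect_lt(abs(f@amplitude - amp) / amp, 1e-6)
    }
  }
})

test_that("binding fits flag degenerate curves instead of inventing a Kd", {
  D <- dfhbiSeries()
  f <- fitBinding(D, rep(0, 12))
  expect_true("non_fluorogenic" %in% f@flags)
  expect_true(is.na(f@Kd))
  expect_error(fitBinding(D[1:3], rep(1, 3)), ">= 4")
  expect_error(fitBinding(rev(D), fractionBound(D, 1)), "ascending")
})

test_that("normalise-at-max compatibility mode pins the plateau to the top point", {
  D <- dfhbiSeries()
  y <- 0.7 * fractionBound(D, 1.18)
  f <- fitBinding(D, y, normalizeAtMax = TRUE)
  expect_true(f@converged)
  expect_equal(f@amplitude, 1)
  # normalising by a sub-saturating top point biases the apparent Kd low
  expect_lt(f@Kd, 1.18)
})

test_that("noisy binding fits recover Kd within 10% in the median", {
  D <- dfhbiSeries()
  clean <- fractionBound(D, 1.18)
  set.seed(17)
  errs <- vapply(1:100, function(i) {
    y <- clean * (1 + rnorm(12, 0, 0.02))
    abs(fitBinding(D, y)@Kd - 1.18) / 1.18
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("ddG has the documented sign conventions and antisymmetry", {
  expect_equal(deltaDeltaG(1.18, 1.18, 296.15), 0)
  v <- deltaDeltaG(0.45, 1.18, 296.15)
  expect_equal(abs(v), 0.567, tolerance = 1e-3)
  expect_lt(v, 0)   # tighter binder is favourable-negative by default
  expect_equal(deltaDeltaG(0.45, 1.18, 296.15, sign = "as_printed"), -v)
  expect_equal(deltaDeltaG(1.18, 0.45, 296.15), -v)
  expect_error(deltaDeltaG(-1, 1, 296.15), "> 0")
})

test_that("Van't Hoff regression recovers generating enthalpy and entropy exactly", {
  Tk <- celsiusToKelvin(c(19, 23, 28))
  Kd <- kdAtTemperature(Tk, KdRef = 1.18, dH = -9)
  vh <- vantHoff(Tk, Kd)
  expect_equal(vh@dH, -9, tolerance = 1e-9)
  # dS consistent with the anchor: Kd rebuilt from (dH, dS) matches
  lnKdM <- vh@dH / (gasConstantKcal() * 296.15) - vh@dS / gasConstantKcal()
  expect_equal(exp(lnKdM) * 1e6, 1.18, tolerance = 1e-9)
  expect_equal(vh@rSquared, 1, tolerance = 1e-9)

  # exothermic binding: Kd rises with temperature
  expect_lt(Kd[1], Kd[3])

  # flat Kd -> zero enthalpy
  expect_equal(vantHoff(Tk, rep(2, 3))@dH, 0, tolerance = 1e-12)

  expect_error(vantHoff(c(296.15, 296.15), c(1, 2)), "distinct")
})

test_that("Kd unit rescaling shifts only the entropy term", {
  Tk <- celsiusToKelvin(c(19, 23, 28))
  Kd <- kdAtTemperature(Tk, KdRef = 1.18, dH = -9)
  a <- vantHoff(Tk, Kd, convention = "as_printed")
  b <- vantHoff(Tk, 10 * Kd, convention = "as_printed")
  expect_equal(b@dH, a@dH, tolerance = 1e-9)
  expect_equal(b@dS - a@dS, gasConstantKcal() * log(10), tolerance = 1e-9)
  # the two conventions differ by an overall sign on both coefficients
  bb <- vantHoff(Tk, Kd, convention = "binding")
  expect_equal(bb@dH, -a@dH)
  expect_equal(bb@dS, -a@dS)
})
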