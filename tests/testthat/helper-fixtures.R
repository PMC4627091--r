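# Shared fixtures, built in code at test time.

# A ThermoLandscape holding the generator's true parameter values (no
# fitting involved), for scoring/selection tests.
truthLandscape <- function(truth, refT = 296.15) {
  newThermoLandscape(
    data.frame(id = truth$id, position = truth$position,
               Sm = truth$Sm_true, ddG = truth$ddG_true,
               ddH = truth$ddH_true, dTm = truth$dTm_true,
               fluorogenic = truth$fluorogenic,
               stringsAsFactors = FALSE),
    wtId = "WT", refTemperature = refT)
}

# Uniform-disk three-channel spot images with exactly known medians.
flatSpotImages <- function(size = 41, center = c(21, 21), radius = 6,
                           fg = 10, bg = 2, probe = 4) {
  d2 <- (row(matrix(0, size, size)) - center[1])^2 +
        (col(matrix(0, size, size)) - center[2])^2
  complexImg <- matrix(bg, size, size)
  complexImg[d2 <= radius^2] <- fg
  probeImg <- matrix(probe, size, size)
  list(complexImg = complexImg, probeImg = probeImg,
       geometry = new("SpotGeometry", center = center, radius = radius,
                      annulusOuter = 1.5 * radius, sigma = c(3, 3),
                      theta = 0, amplitude = fg - bg, offset = bg,
                      converged = TRUE))
}
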