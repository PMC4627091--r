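## Pull-down spot quantification.  Images are plain numeric matrices
## (row = y, col = x), one per excitation channel: "complex" (aptamer-ligand
## fluorescence), "anchor" (pull-down oligo, used for segmentation) and
## "probe" (total-RNA probe, used for normalisation).  Spots are segmented
## by fitting a generalized (elliptical, rotated) 2D Gaussian with constant
## offset to the anchor channel; signals are medians over the fitted
## foreground disk and a background annulus of outer radius 1.5x the
## foreground radius.

#' Fit a generalized 2D Gaussian to a spot image
#'
#' Seven-parameter model: amplitude, sub-pixel centre (row, col), widths
#' (sigma_r, sigma_c), rotation and constant offset; least squares via
#' Levenberg-Marquardt with moment-based initialisation.  The foreground
#' radius is `2 * max(sigma_r, sigma_c)` (a circle capturing >= 95% of the
#' Gaussian energy), the background annulus extends to 1.5x that radius.
#'
#' Flat or amplitude-less images yield `converged = FALSE` (segmentation
#' failure) rather than an error, so failing spots stay visible downstream.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param snrFloor minimum fitted amplitude, in units of the robust noise
#'   scale (mad) of the image, below which the fit is declared a failure.
#' @return a [SpotGeometry].
#' @export
#' @examples
#' img <- simulateSpotImage(64, center = c(32, 32), sigma = 6,
#'                          amplitude = 100, offset = 10, noiseSd = 0)
#' fitSpot(img)@center
fitSpot <- function(image, snrFloor = 3) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image)) || any(image < 0))
    .stopf("image intensities must be finite and non-negative")
  nr <- nrow(image); nc <- ncol(image)
  rr <- row(image); cc <- col(image)
  y <- as.vector(image)

  fail <- function() new("SpotGeometry",
    center = c(NA_real_, NA_real_), radius = NA_real_,
    annulusOuter = NA_real_, sigma = c(NA_real_, NA_real_),
    theta = NA_real_, amplitude = NA_real_, offset = NA_real_,
    converged = FALSE)

  off0 <- median(y)
  amp0 <- max(y) - off0
  noise <- max(mad(y), .Machine$double.eps)
  if (amp0 <= snrFloor * noise) return(fail())

  ## moment initialisation over above-half-max pixels
  w <- pmax(y - off0, 0)
  top <- w >= 0.5 * amp0
  wt <- w * top
  r0 <- sum(as.vector(rr) * wt) / sum(wt)
  c0 <- sum(as.vector(cc) * wt) / sum(wt)
  s0 <- sqrt(sum(((as.vector(rr) - r0)^2 + (as.vector(cc) - c0)^2) * wt) /
             (2 * sum(wt)))
  s0 <- min(max(s0, 1), min(nr, nc) / 4)

  model <- function(p) {
    # p: amp, r0, c0, log sr, log sc, theta, offset
    sr <- exp(p[4]); sc <- exp(p[5]); th <- p[6]
    a <- cos(th)^2 / (2 * sr^2) + sin(th)^2 / (2 * sc^2)
    b <- sin(2 * th) / 4 * (1 / sc^2 - 1 / sr^2)
    cq <- sin(th)^2 / (2 * sr^2) + cos(th)^2 / (2 * sc^2)
    dr <- as.vector(rr) - p[2]; dc <- as.vector(cc) - p[3]
    p[1] * exp(-(a * dr^2 + 2 * b * dr * dc + cq * dc^2)) + p[7]
  }
  p0 <- c(amp0, r0, c0, log(s0), log(s0), 0, off0)
  lo <- c(0, 1, 1, log(0.5), log(0.5), -pi / 2, 0)
  hi <- c(Inf, nr, nc, log(min(nr, nc)), log(min(nr, nc)), pi / 2, max(y))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lo, upper = hi,
                       fn = function(p) model(p) - y,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(fail())
  p <- fit$par
  if (p[1] <= snrFloor * noise) return(fail())
  sig <- exp(p[4:5])
  radius <- min(2 * max(sig), min(nr, nc) / 3)
  new("SpotGeometry",
      center = c(p[2], p[3]), radius = radius,
      annulusOuter = 1.5 * radius, sigma = sig, theta = p[6],
      amplitude = p[1], offset = p[7], converged = TRUE)
}

.diskMask <- function(dim, center, rInner, rOuter = NULL) {
  d2 <- (row(matrix(0, dim[1], dim[2])) - center[1])^2 +
        (col(matrix(0, dim[1], dim[2])) - center[2])^2
  if (is.null(rOuter)) d2 <= rInner^2 else (d2 > rInner^2) & (d2 <= rOuter^2)
}

#' Extract background-corrected, RNA-normalised spot signals
#'
#' Medians of the complex channel over the foreground disk (`Si`) and the
#' background annulus (`Sb`), and of the probe channel over the foreground
#' (`Sp`, raw — no background correction on the probe channel); the
#' normalised signal is `Sm = (Si - Sb) / Sp`.  `Sm` may be negative for
#' spots dimmer than their local background.
#'
#' @param complexImg,anchorImg,probeImg channel matrices of equal dimension
#'   (`anchorImg` accepted for interface symmetry; not used numerically).
#' @param geometry a converged [SpotGeometry].
#' @param probeFloor positive floor on `Sp` below which normalisation is
#'   undefined (flag `undefined_normalization`, `Sm = NA`).
#' @return list with `Si`, `Sb`, `Sp`, `Sm`, `flags`.
#' @export
extractSignals <- function(complexImg, anchorImg = NULL, probeImg,
                           geometry, probeFloor = .Machine$double.eps) {
  stopifnot(is(geometry, "SpotGeometry"))
  if (!geometry@converged)
    .stopf("cannot extract signals from a failed spot fit")
  if (!all(dim(complexImg) == dim(probeImg)))
    .stopf("channel images must share dimensions")
  dm <- dim(complexImg)
  if (geometry@center[1] < 1 || geometry@center[1] > dm[1] ||
      geometry@center[2] < 1 || geometry@center[2] > dm[2])
    .stopf("spot geometry outside image bounds")
  fg <- .diskMask(dm, geometry@center, geometry@radius)
  an <- .diskMask(dm, geometry@center, geometry@radius,
                  geometry@annulusOuter)
  Si <- median(complexImg[fg])
  Sb <- median(complexImg[an])
  Sp <- median(probeImg[fg])
  flags <- character()
  if (!is.finite(Sp) || Sp <= probeFloor) {
    flags <- "undefined_normalization"
    Sm <- NA_real_
  } else {
    Sm <- (Si - Sb) / Sp
  }
  list(Si = Si, Sb = Sb, Sp = Sp, Sm = Sm, flags = flags)
}

#' Replicate quality control for normalised spot signals
#'
#' Per-mutant coefficient of variation (sample sd / mean) across replicates
#' and pairwise inter-replicate Pearson correlations across mutants.
#' Mutants whose mean signal is near zero get `cv = NA` (undefined) rather
#' than an inflated value; mutants above `cvThreshold` are flagged.
#'
#' @param signals data.frame with columns `mutant_id`, `replicate`, `Sm`.
#' @param cvThreshold flag threshold on CV (default 0.05, the assay's
#'   replicate-CV bound).
#' @param meanFloor |mean| below which CV is reported as undefined.
#' @return list with `perMutant` (mutant_id, mean, sd, cv, flagged) and
#'   `replicateCor` (matrix of pairwise Pearson correlations).
#' @export
replicateQC <- function(signals, cvThreshold = 0.05, meanFloor = 1e-8) {
  need <- c("mutant_id", "replicate", "Sm")
  if (!all(need %in% names(signals)))
    .stopf("signals must have columns: %s", paste(need, collapse = ", "))
  reps <- sort(unique(signals$replicate))
  if (length(reps) < 2L) .stopf("replicate QC needs >= 2 replicates")
  ids <- unique(signals$mutant_id)
  wide <- matrix(NA_real_, length(ids), length(reps),
                 dimnames = list(ids, paste0("rep", reps)))
  idx <- cbind(match(signals$mutant_id, ids),
               match(signals$replicate, reps))
  wide[idx] <- signals$Sm
  mu <- rowMeans(wide, na.rm = TRUE)
  sdv <- apply(wide, 1L, sd, na.rm = TRUE)
  cv <- ifelse(abs(mu) > meanFloor, sdv / abs(mu), NA_real_)
  perMutant <- data.frame(
    mutant_id = ids, mean = mu, sd = sdv, cv = cv,
    flagged = !is.na(cv) & cv > cvThreshold,
    row.names = NULL, stringsAsFactors = FALSE)
  replicateCor <- suppressWarnings(
    cor(wide, use = "pairwise.complete.obs"))
  list(perMutant = perMutant, replicateCor = replicateCor)
}
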