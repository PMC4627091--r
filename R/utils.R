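#' @import methods
#' @importFrom stats coef cor lm median quantile sd setNames mad rnorm runif
#'   complete.cases
#' @importFrom utils head read.delim write.table combn
NULL

## Molar gas constant in kcal/(mol K); all energies in this package are
## kcal/mol and all model math runs in kelvin.
.R_KCAL <- 1.987e-3

#' Gas constant used throughout (kcal mol-1 K-1)
#'
#' @return The molar gas constant, 1.987e-3 kcal/(mol K).
#' @export
#' @examples
#' gasConstantKcal()
gasConstantKcal <- function() .R_KCAL

#' Convert between Celsius and kelvin
#'
#' Temperature I/O in this package is in degrees Celsius (as chip controllers
#' report it); all thermodynamic expressions are evaluated in kelvin.
#' Conversion happens once, at the interface.
#'
#' @param x numeric temperature(s).
#' @return numeric of the same length.
#' @export
#' @examples
#' celsiusToKelvin(23)   # 296.15
#' kelvinToCelsius(296.15)
celsiusToKelvin <- function(x) x + 273.15

#' @rdname celsiusToKelvin
#' @export
kelvinToCelsius <- function(x) x - 273.15

## Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
## A NULL seed leaves the global stream untouched.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive a distinct 31-bit sub-seed from a master seed and a stream label.
subSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
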